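# Rate-law conventions ("mol reactant" velocities):
#  unary S -> P            rate = v [S] / (K + [S])
#  hetero A + B -> ...     event rate = v [A][B] / (K + [A][B]);
#                          each substrate consumed / product formed at it
#  homodimer 2S -> C + D   S consumed at v [S]^2 / (K + [S]^2);
#                          each product formed at half that rate
# The homodimer convention is what makes the fructose/sucrose flux balances
# close at the published steady states (e.g. basic scheme: fructose supply
# 0.5 = 0.25 back-conversion + 0.25 into sucrose).

.checkState <- function(network, state) {
  ids <- network@species$id
  if (is.null(names(state))) {
    if (length(state) != length(ids))
      stop("state must be named or have one entry per species")
    names(state) <- ids
  }
  if (!all(ids %in% names(state)))
    stop("state is missing species: ",
         paste(setdiff(ids, names(state)), collapse = ", "))
  state <- state[ids]
  if (any(!is.finite(state))) stop("non-finite concentration in state")
  if (any(state < 0)) stop("negative concentration in state")
  state
}

# Precompiled evaluator: returns function(state) -> list(events, deriv).
# Used by the integrator, so everything index-based is hoisted out.
.makeEvaluator <- function(network) {
  rx <- network@reactions
  sp <- network@species
  nR <- nrow(rx); nS <- nrow(sp)
  v <- rx$vmax; K <- rx$K
  homo <- rx$homodimeric

  i1 <- integer(nR); i2 <- integer(nR)  # substrate indices; 0 = none
  N <- matrix(0, nS, nR, dimnames = list(sp$id, rx$id))
  for (r in seq_len(nR)) {
    subs <- rx$substrates[[r]]
    mols <- rep(match(names(subs), sp$id), times = subs)
    i1[r] <- mols[1]
    i2[r] <- if (length(mols) > 1) mols[2] else 0L
    for (s in names(subs)) N[s, r] <- N[s, r] - subs[[s]]
    for (p in names(rx$products[[r]])) {
      N[p, r] <- N[p, r] + rx$products[[r]][[p]]
    }
  }
  # event-rate stoichiometry: homodimer consumes 2 S and forms products at
  # half the S-consumption rate, i.e. N-columns already count S twice and
  # products once, so scaling events by c/2 gives both conventions at once
  unclamped <- !sp$clamped
  hasSecond <- i2 > 0L

  function(state) {
    conc <- pmax(state, 0)
    P <- conc[i1]
    P[hasSecond] <- P[hasSecond] * conc[i2[hasSecond]]
    e <- v * P / (K + P)
    e[v == 0 | P == 0] <- 0
    e[homo] <- e[homo] / 2
    d <- drop(N %*% e)
    d[!unclamped] <- 0
    list(events = e, deriv = d)
  }
}

#' Evaluate a single reaction rate
#'
#' Computes the Michaelis-Menten rate of one reaction at a given state,
#' under the model's "mol reactant" velocity convention: for a unary
#' reaction, `v [S]/(K + [S])`; for a two-substrate reaction between
#' distinct species, the per-event rate `v [A][B]/(K + [A][B])` (each
#' substrate consumed, and each product formed, at this rate); for a
#' homodimeric reaction `2S -> C + D`, the consumption rate of S,
#' `v [S]^2/(K + [S]^2)`, with each product formed at half this rate.
#'
#' @param network a [FructanNetwork-class].
#' @param reactionId a reaction id (see [reactionIds()]).
#' @param state named concentration vector, mol/L.
#' @return rate in mol/L/d (substrate-consumption convention).
#' @examples
#' net <- fructanNetwork()
#' st <- initialState(net)
#' reactionRate(net, "v_glc_fru", st)  # 0.1/(0.1+0.1) = 0.5
#' @export
reactionRate <- function(network, reactionId, state) {
  stopifnot(is(network, "FructanNetwork"))
  r <- match(reactionId, network@reactions$id)
  if (is.na(r)) stop("unknown reaction id: ", reactionId)
  state <- .checkState(network, state)
  ev <- .makeEvaluator(network)(state)
  e <- unname(ev$events[r])
  if (network@reactions$homodimeric[r]) 2 * e else e
}

#' ODE right-hand side of the reaction network
#'
#' Returns the time derivative of every species concentration (mol/L/d) at
#' the given state: the stoichiometry-weighted sum of all reaction rates,
#' with clamped species (glucose by default) forced to zero derivative.
#'
#' @inheritParams reactionRate
#' @return named numeric vector of derivatives, canonical species order.
#' @export
rhsFructan <- function(network, state) {
  stopifnot(is(network, "FructanNetwork"))
  state <- .checkState(network, state)
  stats::setNames(.makeEvaluator(network)(state)$deriv, network@species$id)
}

#' Per-species and per-reaction flux report
#'
#' Itemizes, at a given state, each species' total production rate, total
#' consumption rate, net rate (production minus consumption) and ODE
#' derivative (net, zeroed for clamped species), plus each reaction's event
#' rate and substrate-consumption rate. The derivative column reconciles
#' exactly with [rhsFructan()]. At a steady state, production and
#' consumption balance for every unclamped non-sink species, which is the
#' diagnostic this report exists for.
#'
#' @inheritParams reactionRate
#' @return list with data.frames `species` (production, consumption, net,
#'   derivative, clamped) and `reactions` (eventRate, consumptionRate).
#' @export
fluxReport <- function(network, state) {
  stopifnot(is(network, "FructanNetwork"))
  state <- .checkState(network, state)
  rx <- network@reactions
  sp <- network@species
  ev <- .makeEvaluator(network)(state)
  e <- ev$events

  prod <- cons <- stats::setNames(numeric(nrow(sp)), sp$id)
  for (r in seq_len(nrow(rx))) {
    for (s in names(rx$substrates[[r]]))
      cons[s] <- cons[s] + e[r] * rx$substrates[[r]][[s]]
    for (p in names(rx$products[[r]]))
      prod[p] <- prod[p] + e[r] * rx$products[[r]][[p]]
  }
  species <- data.frame(
    id = sp$id, production = prod, consumption = cons,
    net = prod - cons, derivative = ev$deriv, clamped = sp$clamped,
    row.names = NULL, stringsAsFactors = FALSE
  )
  consumptionRate <- ifelse(rx$homodimeric, 2 * e, e)
  reactions <- data.frame(
    id = rx$id, eventRate = e, consumptionRate = consumptionRate,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(species = species, reactions = reactions)
}

#' Export a flux report as delimited text
#'
#' @param report a list as returned by [fluxReport()].
#' @param path output file path (tab-separated, two stacked tables).
#' @return `path`, invisibly.
#' @export
writeFluxReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$species, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  utils::write.table(report$reactions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
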