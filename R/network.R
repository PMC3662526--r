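#' Build the canonical fructan biosynthesis network
#'
#' Constructs the full 14-species, 22-reaction network with default kinetic
#' parameters. The species are glucose (`glc`, clamped at `glcClamp`),
#' fructose (`fru`), sucrose (`gf1`), the fructans `gf2`..`gf10` (glucose
#' with n fructose units) and the fructose-only oligomers `f2`, `f3`. The
#' reactions are:
#'
#' * `v_glc_fru`, `v_fru_glc`: reversible glucose/fructose interconversion
#'   (two irreversible Michaelis-Menten reactions, K = 0.1 mol/L, v = 1);
#' * `v_glcfru_gf1`: sucrose synthesis glc + fru -> gf1;
#' * `v_11_02`: kestose synthesis 2 gf1 -> glc + gf2 (1-SST);
#' * `v_22_13`: 2 gf2 -> gf1 + gf3 (1-FFT);
#' * `v_2n_1(n+1)`, n = 3..9: chain elongation gf2 + gfn -> gf1 + gf(n+1)
#'   with kestose as the fructose donor;
#' * `v_3n_2(n+1)`, n = 3..9: elongation with gf3 as donor (default v = 0);
#' * `v_2f1_1f2`, `v_2f2_1f3`: fructose transfer from kestose to fructose /
#'   difructose (default v = 0);
#' * `v_2f3_5`: gf2 + f3 -> gf5, a single product (default v = 0).
#'
#' Binary reactions use K = 0.01 (mol/L)^2; all default velocities of the
#' basic scheme are 1 mol reactant/L/d. `gf10` is a terminal sink: produced
#' by the n = 9 transfers but never consumed (the chain is truncated there).
#'
#' @param glcClamp constant glucose concentration, mol/L (default 0.1).
#' @return a [FructanNetwork-class] object.
#' @examples
#' net <- fructanNetwork()
#' net
#' @export
fructanNetwork <- function(glcClamp = 0.1) {
  sp <- data.frame(
    id = .speciesOrder,
    hexoseUnits = c(1L, 1L, 2:11, 2L, 3L),
    clamped = c(TRUE, rep(FALSE, 13)),
    init = c(glcClamp, rep(0, 13)),
    stringsAsFactors = FALSE
  )

  rx <- list()
  add <- function(id, substrates, products, vmax, K, homodimeric = FALSE) {
    rx[[length(rx) + 1L]] <<- list(id = id, substrates = substrates,
                                   products = products, vmax = vmax, K = K,
                                   homodimeric = homodimeric)
  }

  add("v_glc_fru", c(glc = 1L), c(fru = 1L), 1, 0.1)
  add("v_fru_glc", c(fru = 1L), c(glc = 1L), 1, 0.1)
  add("v_glcfru_gf1", c(glc = 1L, fru = 1L), c(gf1 = 1L), 1, 0.01)
  add("v_11_02", c(gf1 = 2L), c(glc = 1L, gf2 = 1L), 1, 0.01,
      homodimeric = TRUE)
  add("v_22_13", c(gf2 = 2L), c(gf1 = 1L, gf3 = 1L), 1, 0.01,
      homodimeric = TRUE)
  for (n in 3:9) {
    subs <- c(1L, 1L); names(subs) <- c("gf2", paste0("gf", n))
    prods <- c(1L, 1L); names(prods) <- c("gf1", paste0("gf", n + 1L))
    add(sprintf("v_2%d_1%d", n, n + 1L), subs, prods, 1, 0.01)
  }
  for (n in 3:9) {
    if (n == 3L) {
      add("v_33_24", c(gf3 = 2L), c(gf2 = 1L, gf4 = 1L), 0, 0.01,
          homodimeric = TRUE)
    } else {
      subs <- c(1L, 1L); names(subs) <- c("gf3", paste0("gf", n))
      prods <- c(1L, 1L); names(prods) <- c("gf2", paste0("gf", n + 1L))
      add(sprintf("v_3%d_2%d", n, n + 1L), subs, prods, 0, 0.01)
    }
  }
  add("v_2f1_1f2", c(gf2 = 1L, fru = 1L), c(gf1 = 1L, f2 = 1L), 0, 0.01)
  add("v_2f2_1f3", c(gf2 = 1L, f2 = 1L), c(gf1 = 1L, f3 = 1L), 0, 0.01)
  add("v_2f3_5", c(gf2 = 1L, f3 = 1L), c(gf5 = 1L), 0, 0.01)

  reactions <- data.frame(
    id = vapply(rx, `[[`, character(1), "id"),
    vmax = vapply(rx, `[[`, numeric(1), "vmax"),
    K = vapply(rx, `[[`, numeric(1), "K"),
    homodimeric = vapply(rx, `[[`, logical(1), "homodimeric"),
    stringsAsFactors = FALSE
  )
  reactions$substrates <- lapply(rx, `[[`, "substrates")
  reactions$products <- lapply(rx, `[[`, "products")

  new("FructanNetwork", species = sp, reactions = reactions)
}

#' Velocity presets for the published simulation schemes
#'
#' Returns the maximum-velocity overrides defining schemes (a)-(e) on top of
#' the default network. All schemes share one topology; they differ only in
#' which reactions are switched on and how fast they run:
#'
#' * `a` — the basic 1-SST/1-FFT scheme: defaults, gf3-donor and
#'   fructose-polymer reactions off;
#' * `b` — `a` plus gf3 as an additional fructose donor
#'   (`v_3n_2(n+1) = 1`, n = 3..9);
#' * `c` — `b` with one fast reaction, `v_34_25 = 10`;
#' * `d` — gf3 synthesis switched off (`v_22_13 = 0`) and fructose-polymer
#'   transfers on (`v_2f1_1f2 = v_2f2_1f3 = v_2f3_5 = 1`);
#' * `e` — the data-matching parameterization: `v_22_13 = 2`,
#'   `v_24_15..v_27_18 = 2`, `v_28_19 = 10`, `v_29_110 = 4`.
#'
#' @return named list of named numeric override vectors (scheme `a` is empty).
#' @seealso [applyScheme()]
#' @export
schemePresets <- function() {
  list(
    a = c(),
    b = stats::setNames(rep(1, 7), sprintf("v_3%d_2%d", 3:9, 4:10)),
    c = c(stats::setNames(rep(1, 7), sprintf("v_3%d_2%d", 3:9, 4:10)),
          v_34_25 = 10),
    d = c(v_22_13 = 0, v_2f1_1f2 = 1, v_2f2_1f3 = 1, v_2f3_5 = 1),
    e = c(v_22_13 = 2, v_24_15 = 2, v_25_16 = 2, v_26_17 = 2, v_27_18 = 2,
          v_28_19 = 10, v_29_110 = 4)
  )
}

#' Apply a scheme preset or velocity overrides to a network
#'
#' Returns a copy of the network with maximum velocities replaced according
#' to a named preset (`"a"`..`"e"`, see [schemePresets()]) or an explicit
#' named vector of `reaction id = velocity` overrides. Topology and
#' Michaelis constants are never changed; the input network is not modified.
#'
#' @param network a [FructanNetwork-class].
#' @param scheme a single preset name or a named numeric vector of velocity
#'   overrides (possibly empty).
#' @return a new [FructanNetwork-class].
#' @examples
#' net <- applyScheme(fructanNetwork(), "c")
#' velocities(net)["v_34_25"]
#' @export
applyScheme <- function(network, scheme) {
  stopifnot(is(network, "FructanNetwork"))
  if (is.character(scheme) && length(scheme) == 1 && is.null(names(scheme))) {
    presets <- schemePresets()
    if (!scheme %in% names(presets))
      stop("unknown scheme preset: '", scheme, "' (use one of ",
           paste(names(presets), collapse = ", "), ")")
    overrides <- presets[[scheme]]
  } else {
    overrides <- scheme
  }
  if (length(overrides) == 0) return(network)
  overrides <- unlist(overrides)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("velocity overrides must be a named vector")
  unknown <- setdiff(names(overrides), network@reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  if (any(overrides < 0))
    stop("maximum velocities must be non-negative")
  idx <- match(names(overrides), network@reactions$id)
  network@reactions$vmax[idx] <- as.numeric(overrides)
  validObject(network)
  network
}

#' Check network invariants
#'
#' Verifies the structural invariants of a fructan network and returns a
#' character vector of violation descriptions (empty if the network is
#' valid): unique species and reaction ids, positive Michaelis constants,
#' non-negative velocities, at most two substrate molecules per reaction,
#' hexose-unit conservation for every reaction (the single-product reaction
#' gf2 + f3 -> gf5 conserves 3 + 3 = 6 units), and gf10 acting as a pure
#' product sink.
#'
#' @param network a [FructanNetwork-class].
#' @return character vector of violations (length 0 if valid).
#' @export
validateNetwork <- function(network) {
  sp <- network@species
  rx <- network@reactions
  bad <- character()

  if (anyDuplicated(sp$id)) bad <- c(bad, "duplicate species ids")
  if (anyDuplicated(rx$id)) bad <- c(bad, "duplicate reaction ids")
  if (any(sp$hexoseUnits < 1))
    bad <- c(bad, "species with hexoseUnits < 1")
  if (any(sp$init < 0)) bad <- c(bad, "negative initial concentration")

  hx <- stats::setNames(sp$hexoseUnits, sp$id)
  for (i in seq_len(nrow(rx))) {
    subs <- rx$substrates[[i]]
    prods <- rx$products[[i]]
    if (!all(names(c(subs, prods)) %in% sp$id)) {
      bad <- c(bad, sprintf("reaction %s references unknown species",
                            rx$id[i]))
      next
    }
    if (sum(subs) > 2)
      bad <- c(bad, sprintf("reaction %s has more than 2 substrate molecules",
                            rx$id[i]))
    nIn <- sum(hx[names(subs)] * subs)
    nOut <- sum(hx[names(prods)] * prods)
    if (nIn != nOut)
      bad <- c(bad, sprintf(
        "reaction %s violates hexose-unit conservation (%d in, %d out)",
        rx$id[i], nIn, nOut))
    if (rx$homodimeric[i] && !(length(subs) == 1 && subs == 2L))
      bad <- c(bad, sprintf("reaction %s marked homodimeric but is not 2S",
                            rx$id[i]))
    if (rx$K[i] <= 0)
      bad <- c(bad, sprintf("reaction %s has non-positive K", rx$id[i]))
    if (rx$vmax[i] < 0)
      bad <- c(bad, sprintf("reaction %s has negative vmax", rx$id[i]))
  }

  if ("gf10" %in% sp$id) {
    asSub <- vapply(rx$substrates, function(s) "gf10" %in% names(s),
                    logical(1))
    if (any(asSub))
      bad <- c(bad, "gf10 must be a pure sink (never a substrate)")
  }
  bad
}

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))

#' @rdname accessors
#' @export
setGeneric("velocities<-",
           function(object, value) standardGeneric("velocities<-"))

#' @rdname accessors
#' @export
setGeneric("initialState", function(object) standardGeneric("initialState"))

#' Accessors for FructanNetwork objects
#'
#' `speciesIds()` and `reactionIds()` return the canonical id orders;
#' `velocities()` returns the named vector of maximum velocities (mol
#' reactant/L/d) and `velocities<-` replaces a subset by name;
#' `initialState()` returns the named initial-concentration vector (mol/L).
#'
#' @param object a [FructanNetwork-class].
#' @param value named numeric vector of velocities to set.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("speciesIds", "FructanNetwork", function(object) object@species$id)

#' @rdname accessors
#' @export
setMethod("reactionIds", "FructanNetwork",
          function(object) object@reactions$id)

#' @rdname accessors
#' @export
setMethod("velocities", "FructanNetwork", function(object)
  stats::setNames(object@reactions$vmax, object@reactions$id))

#' @rdname accessors
#' @export
setMethod("velocities<-", "FructanNetwork", function(object, value) {
  applyScheme(object, value)
})

#' @rdname accessors
#' @export
setMethod("initialState", "FructanNetwork", function(object)
  stats::setNames(object@species$init, object@species$id))

#' Write / read a network configuration as plain key = value text
#'
#' The configuration lists one `key = value` pair per line: bare reaction ids
#' carry maximum velocities, `K.<reaction id>` the Michaelis constants and
#' `init.<species id>` the initial (for clamped species, held) concentrations.
#' `readNetworkConfig()` starts from the canonical network and applies each
#' key, so a config only needs the entries that differ from the defaults.
#'
#' @param network a [FructanNetwork-class].
#' @param path file path.
#' @return `writeNetworkConfig()` returns `path` invisibly;
#'   `readNetworkConfig()` returns a [FructanNetwork-class].
#' @export
writeNetworkConfig <- function(network, path) {
  stopifnot(is(network, "FructanNetwork"))
  rx <- network@reactions
  sp <- network@species
  lines <- c(
    sprintf("%s = %.15g", rx$id, rx$vmax),
    sprintf("K.%s = %.15g", rx$id, rx$K),
    sprintf("init.%s = %.15g", sp$id, sp$init)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  net <- fructanNetwork()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value in config line: '", ln, "'")
    if (startsWith(key, "K.")) {
      id <- substring(key, 3)
      i <- match(id, net@reactions$id)
      if (is.na(i)) stop("unknown reaction id in config: ", id)
      if (val <= 0) stop("K must be positive for ", id)
      net@reactions$K[i] <- val
    } else if (startsWith(key, "init.")) {
      id <- substring(key, 6)
      i <- match(id, net@species$id)
      if (is.na(i)) stop("unknown species id in config: ", id)
      if (val < 0) stop("initial concentration must be non-negative for ", id)
      net@species$init[i] <- val
    } else {
      i <- match(key, net@reactions$id)
      if (is.na(i)) stop("unknown reaction id in config: ", key)
      if (val < 0) stop("velocity must be non-negative for ", key)
      net@reactions$vmax[i] <- val
    }
  }
  validObject(net)
  net
}
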