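#' @import methods
NULL

# canonical species order used everywhere: glc, fru, gf1..gf10, f2, f3
.speciesOrder <- c("glc", "fru", paste0("gf", 1:10), "f2", "f3")

#' FructanNetwork: the fructan biosynthesis reaction network
#'
#' Container for the 14-species, 22-reaction Michaelis-Menten network of
#' fructan biosynthesis: reversible glucose/fructose interconversion, sucrose
#' synthesis, kestose (gf2) synthesis by 1-SST, chain elongation by
#' fructosyltransferases using gf2 or gf3 as fructose donor, and transfers to
#' fructose-only oligomers (f2, f3). Glucose is clamped at a constant supply
#' concentration; gf10 is a terminal sink (produced but never consumed).
#'
#' @slot species data.frame with columns `id` (character), `hexoseUnits`
#'   (integer count of hexose monomers), `clamped` (logical), `init`
#'   (initial concentration, mol/L).
#' @slot reactions data.frame with columns `id` (character reaction name),
#'   `vmax` (maximum velocity, mol reactant per litre per day), `K`
#'   (Michaelis constant; mol/L for unary reactions, (mol/L)^2 for binary),
#'   `homodimeric` (logical, two identical substrate molecules), and
#'   list-columns `substrates` / `products` (named integer vectors of
#'   stoichiometric counts).
#'
#' @seealso [fructanNetwork()], [applyScheme()], [validateNetwork()]
#' @export
setClass("FructanNetwork",
  representation(species = "data.frame", reactions = "data.frame"))

#' KineticTrajectory: a simulated time course
#'
#' @slot times numeric time grid (days).
#' @slot conc numeric matrix, time points x species (mol/L), columns in
#'   canonical species order.
#' @slot converged logical; TRUE if a steady state was reached.
#' @slot steadyState named numeric vector of steady-state concentrations
#'   (the final state when not converged).
#' @slot convergenceTime numeric, first time (days) at which the steady-state
#'   criterion held (NA if not converged).
#'
#' @seealso [simulateNetwork()], [findSteadyState()], [overshootMetrics()]
#' @export
setClass("KineticTrajectory",
  representation(times = "numeric", conc = "matrix", converged = "logical",
                 steadyState = "numeric", convergenceTime = "numeric"))

#' DPDistribution: intensity or concentration per polymer-length class
#'
#' Holds one value per degree-of-polymerization class DP3..DP10. In the
#' kinetic model these map to the fructans gf2..gf9 (a DP-n fructan carries
#' n - 1 fructose units plus one glucose).
#'
#' @slot dp integer vector, 3:10.
#' @slot values numeric, one value per DP class (>= 0).
#' @slot mode normalization mode: "raw", "sum" (values sum to 1) or "max"
#'   (maximum value is 1).
#'
#' @seealso [dpDistribution()], [aggregatePeaks()]
#' @export
setClass("DPDistribution",
  representation(dp = "integer", values = "numeric", mode = "character"))

#' DPSeries: the [M-H]- m/z series of singly charged fructan oligomers
#'
#' Negative-mode electrospray of fructan oligomers DP 3-10 yields
#' predominantly singly charged deprotonated ions whose m/z values form an
#' arithmetic series: an anchor at DP3 plus a fixed increment per additional
#' fructose residue.
#'
#' @slot anchorMz m/z of the DP3 ion (default 503.3 Th).
#' @slot increment m/z spacing per fructose residue (default 162.0 Th).
#' @slot dpRange integer range of annotatable DP classes (default 3:10).
#' @slot tolerance match tolerance in Th for peak assignment (default 0.5).
#'
#' @seealso [dpToMz()], [mzToDp()]
#' @export
setClass("DPSeries",
  representation(anchorMz = "numeric", increment = "numeric",
                 dpRange = "integer", tolerance = "numeric"))

#' VelocityFit: result of fitting reaction velocities to a DP distribution
#'
#' @slot velocities named numeric vector of fitted maximum velocities.
#' @slot objective sum of squared differences between the sum-normalized
#'   model and target DP distributions at the optimum.
#' @slot evaluations number of objective evaluations used.
#' @slot converged logical, optimizer convergence flag.
#' @slot distribution the fitted model's [DPDistribution-class]
#'   (sum-normalized).
#'
#' @seealso [fitVelocities()]
#' @export
setClass("VelocityFit",
  representation(velocities = "numeric", objective = "numeric",
                 evaluations = "integer", converged = "logical",
                 distribution = "DPDistribution"))

setValidity("FructanNetwork", function(object) {
  v <- validateNetwork(object)
  if (length(v) == 0) TRUE else v
})

setValidity("DPDistribution", function(object) {
  msg <- character()
  if (length(object@dp) != length(object@values))
    msg <- c(msg, "dp and values must have equal length")
  if (any(object@values < 0))
    msg <- c(msg, "DP values must be non-negative")
  if (!object@mode %in% c("raw", "sum", "max"))
    msg <- c(msg, "mode must be one of 'raw', 'sum', 'max'")
  if (object@mode == "sum" && length(object@values) &&
      abs(sum(object@values) - 1) > 1e-12)
    msg <- c(msg, "sum-normalized values must sum to 1")
  if (length(msg)) msg else TRUE
})

setValidity("DPSeries", function(object) {
  msg <- character()
  if (object@increment <= 0) msg <- c(msg, "increment must be positive")
  if (object@anchorMz <= 0) msg <- c(msg, "anchor m/z must be positive")
  if (object@tolerance <= 0) msg <- c(msg, "tolerance must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn FructanNetwork-class compact summary of species and reactions
#' @param object a `FructanNetwork`
#' @export
setMethod("show", "FructanNetwork", function(object) {
  cat(sprintf("FructanNetwork: %d species, %d reactions\n",
              nrow(object@species), nrow(object@reactions)))
  cl <- object@species$id[object@species$clamped]
  cat(sprintf("  clamped: %s (at %s mol/L)\n", paste(cl, collapse = ", "),
              paste(signif(object@species$init[object@species$clamped], 3),
                    collapse = ", ")))
  nz <- object@reactions[object@reactions$vmax > 0, ]
  cat(sprintf("  active reactions (vmax > 0): %d\n", nrow(nz)))
  invisible(object)
})

#' @describeIn KineticTrajectory-class summary with convergence status
#' @param object a `KineticTrajectory`
#' @export
setMethod("show", "KineticTrajectory", function(object) {
  cat(sprintf("KineticTrajectory: %d time points over %.4g d, %s\n",
              length(object@times), max(object@times),
              if (object@converged)
                sprintf("converged at t = %.4g d", object@convergenceTime)
              else "not converged"))
  invisible(object)
})

#' @describeIn DPDistribution-class prints the per-DP values
#' @param object a `DPDistribution`
#' @export
setMethod("show", "DPDistribution", function(object) {
  cat(sprintf("DPDistribution (%s):\n", object@mode))
  print(stats::setNames(signif(object@values, 4),
                        paste0("DP", object@dp)))
  invisible(object)
})

#' @describeIn DPSeries-class prints the expected m/z table
#' @param object a `DPSeries`
#' @export
setMethod("show", "DPSeries", function(object) {
  cat(sprintf("DPSeries: [M-H]- anchor %.1f Th at DP%d, +%.1f Th/residue, tol +/-%.2f\n",
              object@anchorMz, min(object@dpRange), object@increment,
              object@tolerance))
  invisible(object)
})

#' @describeIn VelocityFit-class prints fitted velocities and objective
#' @param object a `VelocityFit`
#' @export
setMethod("show", "VelocityFit", function(object) {
  cat(sprintf("VelocityFit: objective %.3g after %d evaluations (%s)\n",
              object@objective, object@evaluations,
              if (object@converged) "converged" else "not converged"))
  print(signif(object@velocities, 4))
  invisible(object)
})
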