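#' Construct the fructan [M-H]- m/z series
#'
#' Negative-mode electrospray of fructan oligomers yields predominantly
#' singly charged deprotonated ions. On a unit-resolution ion trap the
#' observed series is arithmetic: 503.3 Th at DP3 plus 162.0 Th per
#' additional fructose residue, up to 1637.3 Th at DP10. The increment is
#' fixed at the observed inter-DP spacing rather than computed from atomic
#' masses, because the one-decimal instrument values match neither exact
#' monoisotopic nor average residue masses.
#'
#' @param anchorMz m/z of the DP3 ion (Th).
#' @param increment spacing per fructose residue (Th).
#' @param dpRange annotatable DP range.
#' @param tolerance peak-match tolerance (Th).
#' @return a [DPSeries-class].
#' @export
dpSeries <- function(anchorMz = 503.3, increment = 162.0, dpRange = 3:10,
                     tolerance = 0.5) {
  new("DPSeries", anchorMz = anchorMz, increment = increment,
      dpRange = as.integer(dpRange), tolerance = tolerance)
}

#' Expected m/z of a fructan oligomer
#'
#' @param dp degree of polymerization (vectorized; must lie in the series'
#'   DP range, 3..10 by default).
#' @param series a [DPSeries-class].
#' @return expected [M-H]- m/z (Th), one decimal place.
#' @examples
#' dpToMz(3:10)  # 503.3 665.3 ... 1637.3
#' @export
dpToMz <- function(dp, series = dpSeries()) {
  stopifnot(is(series, "DPSeries"))
  dp <- as.integer(dp)
  if (any(is.na(dp)) || any(dp < min(series@dpRange)) ||
      any(dp > max(series@dpRange)))
    stop("dp must lie in ", min(series@dpRange), "..", max(series@dpRange))
  round(series@anchorMz + series@increment * (dp - min(series@dpRange)), 1)
}

#' Assign a DP class to an observed m/z
#'
#' Returns the DP whose expected series m/z is nearest to the observed
#' value, provided it lies within the series tolerance; `NA` otherwise.
#' Ties cannot occur since the residue increment far exceeds the tolerance.
#'
#' @param mz observed m/z values (vectorized, > 0).
#' @param series a [DPSeries-class].
#' @return integer DP per input (NA = no match).
#' @examples
#' mzToDp(c(827.5, 900))  # 5, NA
#' @export
mzToDp <- function(mz, series = dpSeries()) {
  stopifnot(is(series, "DPSeries"))
  if (any(mz <= 0)) stop("m/z must be positive")
  expected <- dpToMz(series@dpRange, series)
  vapply(mz, function(m) {
    i <- which.min(abs(expected - m))
    if (abs(expected[i] - m) <= series@tolerance) series@dpRange[i]
    else NA_integer_
  }, integer(1))
}

#' Read / write LC-MS peak tables
#'
#' Peak tables are delimited text with a header and columns `mz`,
#' `intensity` and optionally `label` (an identity such as `1-kestose` or
#' `raffinose`). Malformed rows (non-numeric mz/intensity, negative
#' intensity) are skipped with a message listing their line numbers.
#'
#' @param path file path.
#' @param sep field separator (default tab; `","` for CSV).
#' @return data.frame with columns `mz`, `intensity`, `label`.
#' @export
readPeakTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fill = TRUE,
                          comment.char = "#")
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak table must have columns mz, intensity")
  if (!"label" %in% names(df)) df$label <- ""
  df$label[is.na(df$label)] <- ""
  mz <- suppressWarnings(as.numeric(df$mz))
  int <- suppressWarnings(as.numeric(df$intensity))
  bad <- is.na(mz) | is.na(int) | mz <= 0 | int < 0
  if (any(bad)) {
    message("skipping ", sum(bad), " malformed peak-table row(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    if (all(bad)) stop("all peak-table rows are malformed")
  }
  data.frame(mz = mz[!bad], intensity = int[!bad],
             label = as.character(df$label)[!bad],
             stringsAsFactors = FALSE)
}

#' @rdname readPeakTable
#' @param peaks data.frame with columns `mz`, `intensity` and optionally
#'   `label`.
#' @export
writePeakTable <- function(peaks, path, sep = "\t") {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  utils::write.table(peaks, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate peak intensities into a DP distribution
#'
#' Assigns each peak a DP class via [mzToDp()], drops peaks whose identity
#' label is in the exclusion set (by default the non-fructan
#' sucrosyl-galactosides raffinose and loliose, which co-occur at the DP3
#' m/z) and peaks matching no DP class, and sums the remaining intensities
#' per DP. Several isomeric peaks per DP (e.g. 1-, 6- and 6G-kestose at
#' 503.3) are summed, as the instrument cannot distinguish them by mass.
#' Unlabeled peaks at the DP3 m/z are kept with a warning, since possible
#' contaminants can only be recognized by label.
#'
#' @param peaks data.frame with columns `mz`, `intensity`, optional `label`.
#' @param series a [DPSeries-class].
#' @param exclusions character vector of labels to drop.
#' @return a raw-mode [DPDistribution-class] with attribute `summary`
#'   (data.frame: nPeaks, nExcluded, nUnmatched, totalIntensity).
#' @export
aggregatePeaks <- function(peaks, series = dpSeries(),
                           exclusions = c("raffinose", "loliose")) {
  if (!"label" %in% names(peaks)) peaks$label <- rep("", nrow(peaks))
  peaks$label[is.na(peaks$label)] <- ""
  vals <- stats::setNames(numeric(8), 3:10)
  nExcluded <- 0L; nUnmatched <- 0L
  if (nrow(peaks)) {
    dp <- mzToDp(peaks$mz, series)
    excluded <- peaks$label %in% exclusions
    nExcluded <- sum(excluded)
    nUnmatched <- sum(is.na(dp) & !excluded)
    keep <- !excluded & !is.na(dp)
    if (any(keep & dp == 3 & !nzchar(peaks$label)))
      warning("unlabeled peak(s) at the DP3 m/z included; raffinose/",
              "loliose contaminants cannot be recognized without labels")
    if (any(keep)) {
      sums <- tapply(peaks$intensity[keep], dp[keep], sum)
      vals[names(sums)] <- sums
    }
  }
  out <- new("DPDistribution", dp = 3:10, values = as.numeric(vals),
             mode = "raw")
  attr(out, "summary") <- data.frame(
    nPeaks = nrow(peaks), nExcluded = nExcluded, nUnmatched = nUnmatched,
    totalIntensity = sum(vals))
  out
}

# Observed isomer multiplicities per DP class on the ion trap: three kestose
# isomers at DP3 (plus two non-fructan contaminants), four isomeric peaks
# each for DP4-7, three for DP8, one for DP9 and two for DP10.
.defaultMultiplicities <- c(`3` = 3L, `4` = 4L, `5` = 4L, `6` = 4L,
                            `7` = 4L, `8` = 3L, `9` = 1L, `10` = 2L)

#' Generate a synthetic LC-MS peak table from a DP distribution
#'
#' Emulates an ion-trap peak list for fructan oligomers DP3-10: each DP
#' class's total intensity is split across its isomeric peaks by a seeded
#' Dirichlet draw, m/z values are jittered uniformly within half the match
#' tolerance, and intensities get multiplicative log-normal noise of
#' relative scale `noiseSd`. With the default multiplicities, two labelled
#' contaminant peaks (raffinose, loliose) are added at the DP3 m/z and the
#' three DP3 fructan peaks carry the kestose isomer labels. At
#' `noiseSd = 0` the table aggregates back to the input distribution
#' exactly (after contaminant exclusion).
#'
#' @param distribution a raw- or normalized-mode [DPDistribution-class];
#'   its values are the per-DP total intensities.
#' @param multiplicities named integer vector, fructan peaks per DP class.
#' @param noiseSd relative intensity noise scale (>= 0).
#' @param seed integer seed for reproducible draws.
#' @param series a [DPSeries-class].
#' @param contaminantRel intensity of each contaminant peak relative to the
#'   mean DP3 fructan peak.
#' @return data.frame peak table (`mz`, `intensity`, `label`).
#' @examples
#' d <- dpDistribution(findSteadyState(fructanNetwork()))
#' pk <- synthesizePeakTable(d, seed = 1)
#' all.equal(dpValues(aggregatePeaks(pk)), dpValues(d))
#' @export
synthesizePeakTable <- function(distribution,
                                multiplicities = .defaultMultiplicities,
                                noiseSd = 0, seed = 1,
                                series = dpSeries(),
                                contaminantRel = 0.5) {
  stopifnot(is(distribution, "DPDistribution"), noiseSd >= 0)
  if (any(distribution@values < 0))
    stop("distribution values must be non-negative")
  multiplicities <- multiplicities[as.character(3:10)]
  if (any(is.na(multiplicities) | multiplicities < 1))
    stop("multiplicities must give >= 1 peak for every DP 3..10")

  kestoseLabels <- c("1-kestose", "6-kestose", "6G-kestose")
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)

  rows <- list()
  for (i in seq_along(distribution@dp)) {
    dp <- distribution@dp[i]
    total <- distribution@values[i]
    m <- multiplicities[[as.character(dp)]]
    w <- stats::rgamma(m, shape = 2, rate = 1)
    w <- w / sum(w)
    base <- dpToMz(dp, series)
    mz <- base + stats::runif(m, -series@tolerance / 2, series@tolerance / 2)
    int <- total * w
    if (noiseSd > 0) int <- int * exp(stats::rnorm(m, 0, noiseSd))
    lab <- if (dp == 3L && m == 3L) kestoseLabels else rep("", m)
    rows[[length(rows) + 1L]] <- data.frame(
      mz = round(mz, 2), intensity = int, label = lab,
      stringsAsFactors = FALSE)
    if (dp == 3L) {
      cint <- contaminantRel * mean(int)
      if (noiseSd > 0) cint <- cint * exp(stats::rnorm(2, 0, noiseSd))
      else cint <- rep(cint, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        mz = round(base + stats::runif(2, -series@tolerance / 2,
                                       series@tolerance / 2), 2),
        intensity = cint, label = c("raffinose", "loliose"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
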