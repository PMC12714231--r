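#' Construct a GutFrame
#'
#' @param start,end (row, col) pixel coordinates of the manual gut start and
#'   end markers.
#' @return A validated [GutFrame-class].
#' @export
gutFrame <- function(start, end) {
  new("GutFrame", start = as.numeric(start), end = as.numeric(end))
}

setMethod("show", "GutFrame", function(object) {
  cat(sprintf("GutFrame: start (%.1f, %.1f) -> end (%.1f, %.1f), chord %.1f px\n",
              object@start[1L], object@start[2L],
              object@end[1L], object@end[2L],
              sqrt(sum((object@end - object@start)^2))))
})

#' Normalized axial position along the gut
#'
#' Projects a point onto the chord from the gut start marker to the end
#' marker and expresses the projection as a fraction of the chord length,
#' clamped to [0, 1]: s = 0 at the start marker, s = 1 at the end.
#' Displacement perpendicular to the chord does not change s, and s is
#' invariant under rigid transformations applied to point and markers
#' together. With \code{method = "x"} only the column (x) coordinate is
#' used, normalized between the markers' columns.
#'
#' The chord is an approximation to arc length along the (near-straight)
#' larval gut; only the two manual markers are recorded, so a curved
#' midline is not recoverable. Curved synthetic guts quantify the
#' approximation error.
#'
#' @param points numeric matrix or data.frame of (row, col) positions, or a
#'   single (row, col) pair.
#' @param frame a [GutFrame-class].
#' @param method \code{"chord"} (default) or \code{"x"}.
#' @return Numeric vector of s values in [0, 1].
#' @export
normalizePosition <- function(points, frame, method = c("chord", "x")) {
  method <- match.arg(method)
  validObject(frame)
  if (is.data.frame(points)) points <- cbind(points$row, points$col)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  s <- if (method == "chord") {
    v <- frame@end - frame@start
    dp <- sweep(points, 2L, frame@start)
    as.numeric(dp %*% v) / sum(v^2)
  } else {
    dx <- frame@end[2L] - frame@start[2L]
    if (dx == 0) stopf("markers share a column; x-projection undefined")
    (points[, 2L] - frame@start[2L]) / dx
  }
  pmin(1, pmax(0, s))
}

#' Assign evenly divided bins along the gut
#'
#' Bin k (1-based) covers [(k-1)/n, k/n), with the last bin closed at 1.
#' Four bins give the gut quarters (qrt1 proximal to qrt4 distal); 100 bins
#' give the percentile positions used for density profiles.
#'
#' @param s numeric vector of normalized positions in [0, 1].
#' @param nBins number of bins (4 or 100 in practice).
#' @return Integer vector of bin labels in 1..nBins.
#' @export
assignBins <- function(s, nBins) {
  if (any(s < 0 | s > 1)) stopf("positions outside [0, 1]")
  pmin(as.integer(floor(s * nBins)) + 1L, as.integer(nBins))
}

#' Per-bin weighted counts
#'
#' @param s normalized positions in [0, 1].
#' @param nBins number of bins.
#' @param weights object multiplicities (default 1 per record); a merged
#'   object of weight w contributes w cells at its own coordinates.
#' @return Integer vector of length \code{nBins}; its sum equals the summed
#'   weights.
#' @export
binPositions <- function(s, nBins, weights = NULL) {
  if (is.null(weights)) weights <- rep(1L, length(s))
  bins <- assignBins(s, nBins)
  counts <- vapply(seq_len(nBins), function(k) sum(weights[bins == k]), 0)
  as.integer(counts)
}

#' Smooth a percentile-bin density profile
#'
#' Gaussian kernel smoothing of 100-bin counts for visualization, with
#' reflection at the edges and rescaling so the smoothed curve sums to the
#' original total. Purely cosmetic: never feeds the statistics.
#'
#' @param counts non-negative bin counts (typically length 100).
#' @param bandwidth kernel standard deviation in bins (default 3).
#' @return Numeric vector of the same length, summing to
#'   \code{sum(counts)}.
#' @export
smoothDensity <- function(counts, bandwidth = 3) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  n <- length(counts)
  total <- sum(counts)
  if (total == 0) return(numeric(n))
  half <- ceiling(4 * bandwidth)
  kern <- stats::dnorm(-half:half, sd = bandwidth)
  kern <- kern / sum(kern)
  padded <- c(rev(counts[seq_len(half)]), counts,
              rev(counts[(n - half + 1L):n]))
  sm <- stats::filter(padded, kern, sides = 2)[(half + 1L):(half + n)]
  sm <- as.numeric(sm)
  sm * total / sum(sm)
}

#' Drop records from an excluded gut region
#'
#' Ablation is inefficient in the distal-most quarter, so several
#' comparisons are run both with and without qrt4; this drops the records
#' of the excluded quarter so totals can be recomputed downstream.
#'
#' @param records data.frame with a \code{quarter} column.
#' @param excludedQuarter quarter to drop (default 4).
#' @return The subset of \code{records} outside the excluded quarter.
#' @export
excludeRegion <- function(records, excludedQuarter = 4L) {
  records[records$quarter != excludedQuarter, , drop = FALSE]
}

#' Attach axial positions and bins to counted cells
#'
#' Convenience wrapper running [normalizePosition()] and [assignBins()] on
#' an object table, adding \code{s}, \code{quarter} and
#' \code{percentile_bin} columns.
#'
#' @param objects data.frame with \code{row}, \code{col} (and optionally
#'   \code{weight}) columns.
#' @param frame a [GutFrame-class].
#' @param method passed to [normalizePosition()].
#' @return The data.frame with the three position columns added.
#' @export
localizeCells <- function(objects, frame, method = "chord") {
  s <- normalizePosition(objects, frame, method = method)
  objects$s <- s
  objects$quarter <- assignBins(s, 4L)
  objects$percentile_bin <- assignBins(s, 100L)
  objects
}
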