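#' Median-area weighting for merged objects
#'
#' Touching cells are often segmented as a single object. The correction
#' assigns each object a positive integer multiplicity from its area
#' relative to the median object area in the image: weight =
#' \code{max(1, round(area / median))}, so objects about twice the median
#' count as 2, three times the median as 3, and so on. Midpoints round half
#' up (an object 2.5x the median counts as 3). The operation is idempotent
#' and leaves all other columns untouched.
#'
#' @param objects data.frame from [segmentObjects()] (needs an \code{area}
#'   column). An empty table is returned as-is.
#' @return The same data.frame with the \code{weight} column filled.
#' @examples
#' assignWeights(data.frame(area = c(20, 20, 40)))$weight  # 1 1 2
#' @export
assignWeights <- function(objects) {
  if (!nrow(objects)) {
    objects$weight <- integer(0)
    return(objects)
  }
  m <- stats::median(objects$area)
  if (m <= 0) stopf("median object area is zero")
  objects$weight <- pmax(1L, as.integer(roundHalfUp(objects$area / m)))
  objects
}

#' Weighted cell count of an image
#'
#' @param objects data.frame with a \code{weight} column (see
#'   [assignWeights()]).
#' @return Integer: the sum of object weights, the corrected total number
#'   of cells in the image; 0 for an empty table.
#' @export
weightedTotal <- function(objects) {
  if (!nrow(objects)) return(0L)
  as.integer(sum(objects$weight))
}

#' Classify objects by dual-channel intensity ratio
#'
#' For objects detected on a composite of two reporter channels, the ratio
#' r = mean(A) / mean(B) assigns each object to a class: r > \code{tHigh}
#' is A-positive only, r < \code{tLow} is B-positive only, and ratios in
#' the closed interval [\code{tLow}, \code{tHigh}] are double positive
#' (values exactly at a boundary are double). A zero B mean with positive A
#' gives r = +Inf, hence A-only; an object with both means zero should not
#' exist above threshold and raises an error. Labels are invariant under
#' rescaling both channels by the same positive constant. An object's full
#' weight goes to its single class.
#'
#' @param objects data.frame of detected objects.
#' @param aChannel,bChannel names of the numerator / denominator mean
#'   intensity columns (defaults \code{mean_ch0} / \code{mean_ch1}).
#' @param tHigh,tLow the ratio decision boundaries (defaults 2 and 0.5).
#' @return The data.frame with added \code{ratio} and \code{class} columns
#'   (\code{class} one of \code{"A_only"}, \code{"B_only"},
#'   \code{"double"}).
#' @export
classifyDual <- function(objects, aChannel = "mean_ch0",
                         bChannel = "mean_ch1", tHigh = 2, tLow = 0.5) {
  if (!nrow(objects)) {
    objects$ratio <- numeric(0)
    objects$class <- character(0)
    return(objects)
  }
  a <- objects[[aChannel]]
  b <- objects[[bChannel]]
  if (any(a == 0 & b == 0))
    stopf("object(s) %s have zero mean in both channels",
          paste(objects$object_id[a == 0 & b == 0], collapse = ", "))
  r <- ifelse(b == 0, Inf, a / b)
  objects$ratio <- r
  objects$class <- ifelse(r > tHigh, "A_only",
                          ifelse(r < tLow, "B_only", "double"))
  objects
}

#' Per-class weighted counts
#'
#' @param objects data.frame with \code{class} and \code{weight} columns.
#' @return Named integer vector of weighted counts per class
#'   (\code{A_only}, \code{B_only}, \code{double}); classes absent from the
#'   data report 0. The three counts always sum to [weightedTotal()].
#' @export
classTotals <- function(objects) {
  lev <- c("A_only", "B_only", "double")
  out <- vapply(lev, function(cl) {
    as.integer(sum(objects$weight[objects$class == cl]))
  }, 0L)
  out
}

#' Read a Cell Counter-style manual count export
#'
#' Reads a CSV of manually counted cells with at least \code{row} and
#' \code{col} (or \code{x}/\code{y}) columns; each row is one cell of
#' weight 1. Supported as a reader so manual counts flow into the same
#' spatial and statistical stages as automated ones.
#'
#' @param path CSV file path.
#' @return data.frame with object_id, row, col, area (NA), weight = 1.
#' @export
readManualCounts <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("x", "y") %in% names(df)) && !all(c("row", "col") %in% names(df))) {
    df$col <- df$x
    df$row <- df$y
  }
  if (!all(c("row", "col") %in% names(df)))
    stopf("manual count file needs row/col (or x/y) columns")
  data.frame(object_id = seq_len(nrow(df)), row = df$row, col = df$col,
             area = NA_real_, weight = 1L)
}
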