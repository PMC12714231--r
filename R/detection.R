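#' Maximum-intensity projection
#'
#' Collapses the z dimension of a stack by taking, per pixel and channel,
#' the maximum over z -- the projection the automated counts are made from.
#' A stack that is already 2-D is returned unchanged with a message.
#'
#' @param stack an [ImageStack-class].
#' @return A 2-D [ImageStack-class].
#' @export
setMethod("maxProject", "ImageStack", function(stack) {
  d <- imageData(stack)
  if (length(dim(d)) == 3L) {
    message("stack is already 2-D; returning it unchanged")
    return(stack)
  }
  proj <- apply(d, 1:3, max)
  ImageStack(proj, pixelSize = stack@pixelSize)
})

#' Composite of two channels
#'
#' Rescales each channel to [0, 1] by its own maximum (left untouched when
#' all-zero) and takes the per-pixel maximum, mirroring the composite of the
#' two reporter channels used to identify objects before per-channel
#' intensity extraction.
#'
#' @param channelA,channelB 2-D intensity matrices of equal shape.
#' @return 2-D matrix in [0, 1].
#' @export
compositeChannels <- function(channelA, channelB) {
  if (!identical(dim(channelA), dim(channelB)))
    stopf("channel shapes differ: %s vs %s",
          paste(dim(channelA), collapse = "x"),
          paste(dim(channelB), collapse = "x"))
  rescale <- function(m) if (max(m) > 0) m / max(m) else m
  pmax(rescale(channelA), rescale(channelB))
}

# Otsu threshold of a 2-D image; EBImage::otsu works on [0, 1] so the image
# is normalized into that range and the threshold mapped back.
.otsu <- function(image) {
  lo <- min(image); hi <- max(image)
  if (hi <= lo) return(hi)
  lo + EBImage::otsu((image - lo) / (hi - lo), range = c(0, 1),
                     levels = 256L) * (hi - lo)
}

# label connected components of a logical mask with 8-connectivity
# (ImageJ's particle-analysis default); returns an integer matrix of labels,
# 0 = background. Components are found on the graph of foreground pixels
# joined to their E/S/SE/SW neighbors.
.labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  edges <- list()
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nr2 <- r + off[1L]; nc2 <- c + off[2L]
    ok <- nr2 >= 1L & nr2 <= nr & nc2 >= 1L & nc2 <= nc
    nidx <- (nc2[ok] - 1L) * nr + nr2[ok]
    hit <- mask[nidx]
    edges[[length(edges) + 1L]] <- cbind(idx[ok][hit], nidx[hit])
  }
  edges <- do.call(rbind, edges)
  vmap <- match(seq_len(nr * nc), idx)   # pixel index -> vertex id
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(vmap[edges[, 1L]], vmap[edges[, 2L]]))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Segment fluorescent objects in a 2-D image
#'
#' The particle-analysis step: binarize at a threshold (Otsu by default),
#' label 8-connected components, discard components smaller than
#' \code{minArea} pixels (default 10 px^2, the minimum object size used for
#' the automated counts), and report each surviving object's centroid, area
#' and per-channel mean intensity.
#'
#' @param image 2-D matrix to threshold (typically one channel or a
#'   [compositeChannels()] composite).
#' @param threshold \code{"otsu"} or an absolute intensity value.
#' @param minArea minimum object area in pixels (>= 1).
#' @param channels optional [ImageStack-class] or list of matrices from
#'   which per-object mean intensities are extracted (columns
#'   \code{mean_ch0}, \code{mean_ch1}, ...); defaults to \code{image}
#'   itself.
#' @return data.frame of detected objects: object_id, row, col (0-based
#'   centroid), area (px^2), one mean_ch column per channel, and weight
#'   (initialized to 1; see [assignWeights()]). A threshold above the
#'   global maximum yields an empty table, not an error.
#' @export
segmentObjects <- function(image, threshold = "otsu", minArea = 10,
                           channels = NULL) {
  if (any(!is.finite(image))) stopf("image contains non-finite pixels")
  stopifnot(minArea >= 1)
  thr <- if (identical(threshold, "otsu")) .otsu(image)
         else as.numeric(threshold)
  if (is.null(channels)) channels <- list(image)
  if (is(channels, "ImageStack"))
    channels <- lapply(seq_len(nChannels(channels)),
                       function(ch) channelImage(channels, ch))
  mask <- image > thr
  lab <- .labelComponents8(mask)
  nObj <- max(lab)
  empty <- data.frame(object_id = integer(0), row = numeric(0),
                      col = numeric(0), area = numeric(0))
  if (nObj == 0L) {
    for (ch in seq_along(channels))
      empty[[paste0("mean_ch", ch - 1L)]] <- numeric(0)
    empty$weight <- integer(0)
    return(empty)
  }
  idx <- which(lab > 0L)
  id <- lab[idx]
  area <- tabulate(id, nObj)
  keep <- which(area >= minArea)
  if (!length(keep)) {
    for (ch in seq_along(channels))
      empty[[paste0("mean_ch", ch - 1L)]] <- numeric(0)
    empty$weight <- integer(0)
    return(empty)
  }
  r0 <- (idx - 1L) %% nrow(image)        # 0-based pixel coordinates
  c0 <- (idx - 1L) %/% nrow(image)
  out <- data.frame(
    object_id = seq_along(keep),
    row = vapply(keep, function(k) mean(r0[id == k]), 0),
    col = vapply(keep, function(k) mean(c0[id == k]), 0),
    area = area[keep]
  )
  for (ch in seq_along(channels)) {
    v <- channels[[ch]][idx]
    out[[paste0("mean_ch", ch - 1L)]] <-
      vapply(keep, function(k) mean(v[id == k]), 0)
  }
  out$weight <- 1L
  out
}
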