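#' Construct an ImageStack
#'
#' @param data numeric array in \code{channels x rows x cols[ x z]} order,
#'   or a matrix (taken as a single-channel 2-D image).
#' @param pixelSize optional micrometers per pixel.
#' @return An [ImageStack-class] object.
#' @examples
#' img <- ImageStack(array(0, c(2, 8, 8)))
#' nChannels(img)
#' @export
ImageStack <- function(data, pixelSize = NA_real_) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  new("ImageStack", data = data, pixelSize = as.numeric(pixelSize))
}

#' @describeIn ImageStack Number of channels.
#' @param x an ImageStack.
#' @export
setMethod("nChannels", "ImageStack", function(x) dim(x@data)[1L])

#' @describeIn ImageStack The raw intensity array.
#' @export
setMethod("imageData", "ImageStack", function(x) x@data)

#' @describeIn ImageStack One channel as a rows x cols matrix (2-D stacks
#'   only).
#' @param channel integer channel index (1-based).
#' @export
setMethod("channelImage", "ImageStack", function(x, channel) {
  stopifnot(length(dim(x@data)) == 3L)
  x@data[channel, , ]
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack:", d[1L], "channel(s),", d[2L], "x", d[3L], "px")
  if (length(d) == 4L) cat(",", d[4L], "z-planes")
  cat("\n  intensity range:",
      sprintf("[%.4g, %.4g]", min(object@data), max(object@data)), "\n")
})

#' Build a table of synthetic cells
#'
#' One row per cell. Centers may be given explicitly (\code{row}/\code{col})
#' or left \code{NA}, in which case [renderImage()] places each cell at its
#' \code{axialFraction} along the gut midline, jittered perpendicular to the
#' path by at most one radius. Cells sharing a \code{clusterId} are placed
#' touching (center-to-center spacing 1.2 x radius) so they merge into one
#' connected component at typical thresholds, exercising the median-area
#' weighting rule.
#'
#' @param axialFraction numeric in [0, 1], arc-length fraction along the gut.
#' @param amplitudes numeric matrix (cells x channels) of peak intensities,
#'   or a vector recycled across cells for a 2-channel A/B pattern via
#'   \code{trueClass}.
#' @param radius nominal cell radius in pixels (intensity falls to 1/e^2 of
#'   the peak at this distance, Gaussian-beam convention).
#' @param clusterId integer; cells with the same non-NA value form one
#'   touching cluster anchored at the first member's axial position.
#' @param trueClass one of \code{"A_only"}, \code{"B_only"},
#'   \code{"double"}; when \code{amplitudes} is NULL, channel amplitudes are
#'   derived from the class (A-only cells dark in channel B and vice versa).
#' @param row,col optional explicit centers in 0-based pixel coordinates.
#' @param baseAmplitude peak intensity used when deriving amplitudes from
#'   \code{trueClass}.
#' @return data.frame with columns cellId, axialFraction, row, col, radius,
#'   clusterId, trueClass and one \code{amp<k>} column per channel.
#' @export
simCells <- function(axialFraction, amplitudes = NULL, radius = 6,
                     clusterId = NA_integer_,
                     trueClass = "double", row = NA_real_, col = NA_real_,
                     baseAmplitude = 0.8) {
  n <- length(axialFraction)
  trueClass <- rep_len(trueClass, n)
  if (is.null(amplitudes)) {
    # ratio A:B of 4, 1/4 and 1 for the three classes: comfortably clear of
    # the 2 / 0.5 decision boundaries
    ampA <- ifelse(trueClass == "B_only", baseAmplitude / 4, baseAmplitude)
    ampB <- ifelse(trueClass == "A_only", baseAmplitude / 4, baseAmplitude)
    amplitudes <- cbind(ampA, ampB)
  }
  if (!is.matrix(amplitudes)) amplitudes <- matrix(amplitudes, nrow = n)
  cells <- data.frame(
    cellId = seq_len(n),
    axialFraction = axialFraction,
    row = rep_len(as.numeric(row), n),
    col = rep_len(as.numeric(col), n),
    radius = rep_len(radius, n),
    clusterId = rep_len(as.integer(clusterId), n),
    trueClass = trueClass
  )
  colnames(amplitudes) <- paste0("amp", seq_len(ncol(amplitudes)))
  cbind(cells, amplitudes)
}

#' Standard synthetic scenes
#'
#' \code{wellSeparatedCells} lays n cells on a jittered grid so that no two
#' objects can merge: the scene where the automated count should equal the
#' true count exactly. \code{clusterScene} builds the canonical
#' merge-correction scene: a set of singleton cells plus touching clusters
#' of equal per-cell size, whose weighted total must equal the true cell
#' number (6 singletons + a 2-cell + a 3-cell cluster gives 11).
#'
#' @param n number of cells.
#' @param imageShape integer(2) image size the grid is laid out on.
#' @param radius cell radius in pixels.
#' @param jitter max absolute uniform jitter (px) applied to grid centers.
#' @param seed RNG seed for the jitter.
#' @return A cells data.frame as from [simCells()].
#' @examples
#' spec <- simImageSpec(clusterScene(), noiseSd = 0, seed = 1)
#' @export
wellSeparatedCells <- function(n, imageShape = c(512L, 512L), radius = 6,
                               jitter = 4, seed = 1L) {
  k <- ceiling(sqrt(n))
  margin <- 6 * radius
  rows <- seq(margin, imageShape[1L] - 1 - margin, length.out = k)
  cols <- seq(margin, imageShape[2L] - 1 - margin, length.out = k)
  grid <- expand.grid(row = rows, col = cols)[seq_len(n), ]
  jit <- withSeed(seed, matrix(stats::runif(2 * n, -jitter, jitter),
                               ncol = 2))
  cells <- simCells(axialFraction = rep(0.5, n),
                    row = grid$row + jit[, 1L], col = grid$col + jit[, 2L],
                    radius = radius)
  cells$cellId <- seq_len(n)
  cells
}

#' @rdname wellSeparatedCells
#' @param nSingletons number of isolated cells.
#' @param clusterSizes sizes of the touching clusters to add.
#' @export
clusterScene <- function(nSingletons = 6, clusterSizes = c(2L, 3L),
                         radius = 6) {
  cells <- simCells(seq(0.05, 0.05 + 0.1 * (nSingletons - 1), by = 0.1),
                    radius = radius)
  frac <- 0.72
  for (i in seq_along(clusterSizes)) {
    cells <- rbind(cells, simCells(rep(frac, clusterSizes[i]),
                                   clusterId = i + 1L, radius = radius))
    frac <- frac + 0.18
  }
  cells$cellId <- seq_len(nrow(cells))
  cells
}

#' Run detection and weighting on a rendered scene
#'
#' Convenience wrapper for the standard two-channel pipeline: composite the
#' first two channels, segment with Otsu and the minimum object size, and
#' assign median-area weights.
#'
#' @param rendered list from [renderImage()].
#' @param minArea minimum object size in px^2.
#' @return Weighted object table (see [segmentObjects()]).
#' @export
detectCells <- function(rendered, minArea = 10) {
  img <- compositeChannels(channelImage(rendered$stack, 1),
                           channelImage(rendered$stack, 2))
  assignWeights(segmentObjects(img, minArea = minArea,
                               channels = rendered$stack))
}

#' Specify a synthetic gut image
#'
#' Defaults give a 256 x 256 two-channel image with a straight horizontal
#' gut midline spanning most of the frame, a low uniform background and mild
#' Gaussian noise, emulating a maximum-intensity projection of a larval
#' zebrafish intestine with fluorescent reporter-positive cells.
#'
#' @param cells data.frame from [simCells()] (may have zero rows).
#' @param imageShape integer(2) rows, cols.
#' @param nChannels number of channels.
#' @param gutPath matrix of (row, col) control points of the midline; the
#'   default is a straight line from \code{(rows/2, 0.08 * cols)} to
#'   \code{(rows/2, 0.92 * cols)}.
#' @param gutStart,gutEnd manual marker coordinates; default to the path
#'   endpoints.
#' @param backgroundLevel,noiseSd,psfSigma,seed see
#'   [SimImageSpec-class].
#' @return A validated [SimImageSpec-class] object.
#' @examples
#' spec <- simImageSpec(simCells(c(0.2, 0.7)), seed = 1)
#' res <- renderImage(spec)
#' res$truth
#' @export
simImageSpec <- function(cells = simCells(numeric(0)),
                         imageShape = c(256L, 256L), nChannels = 2L,
                         gutPath = NULL, gutStart = NULL, gutEnd = NULL,
                         backgroundLevel = 0.05, noiseSd = 0.01,
                         psfSigma = 0.5, seed = 1L) {
  imageShape <- as.integer(imageShape)
  if (is.null(gutPath)) {
    r <- imageShape[1L] / 2
    gutPath <- rbind(c(r, 0.08 * imageShape[2L]),
                     c(r, 0.92 * imageShape[2L]))
  }
  gutPath <- matrix(as.numeric(gutPath), ncol = 2L)
  if (is.null(gutStart)) gutStart <- gutPath[1L, ]
  if (is.null(gutEnd)) gutEnd <- gutPath[nrow(gutPath), ]
  new("SimImageSpec",
      imageShape = imageShape, nChannels = as.integer(nChannels),
      gutStart = as.numeric(gutStart), gutEnd = as.numeric(gutEnd),
      gutPath = gutPath, cells = cells,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      psfSigma = psfSigma, seed = as.integer(seed))
}

setMethod("show", "SimImageSpec", function(object) {
  cat("SimImageSpec:", nrow(object@cells), "cell(s) on a",
      paste(object@imageShape, collapse = " x "), "px image,",
      object@nChannels, "channel(s)\n")
  cat("  background", object@backgroundLevel, "| noise sd", object@noiseSd,
      "| seed", object@seed, "\n")
})

# cumulative arc length of a polyline (rows are points)
.pathArcLength <- function(path) {
  seg <- sqrt(rowSums(diff(path)^2))
  c(0, cumsum(seg))
}

# point and unit tangent at arc-length fraction f along a polyline
.pathPoint <- function(path, f) {
  arc <- .pathArcLength(path)
  total <- arc[length(arc)]
  s <- f * total
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(path) - 1L)
  seg <- path[i + 1L, , drop = FALSE] - path[i, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  t <- (s - arc[i]) / len
  point <- path[i, , drop = FALSE] + seg * t
  tangent <- seg / len
  list(point = point, tangent = tangent)
}

# resolve NA cell centers: place each cluster anchor on the gut path with
# perpendicular jitter <= radius, then chain further cluster members at
# center-to-center spacing 1.2 * radius in a random direction
.placeCells <- function(spec) {
  cells <- spec@cells
  if (!nrow(cells)) return(cells)
  needs <- which(is.na(cells$row) | is.na(cells$col))
  if (!length(needs)) return(cells)
  anchors <- !duplicated(cells$clusterId) | is.na(cells$clusterId)
  for (i in needs) {
    if (anchors[i]) {
      pp <- .pathPoint(spec@gutPath, cells$axialFraction[i])
      normal <- c(-pp$tangent[1L, 2L], pp$tangent[1L, 1L])
      jitter <- stats::runif(1, -1, 1) * cells$radius[i]
      center <- pp$point[1L, ] + jitter * normal
    } else {
      prev <- max(which(cells$clusterId[seq_len(i - 1L)] %in%
                          cells$clusterId[i]))
      theta <- stats::runif(1, 0, 2 * pi)
      center <- c(cells$row[prev], cells$col[prev]) +
        1.2 * cells$radius[i] * c(cos(theta), sin(theta))
    }
    cells$row[i] <- center[1L]
    cells$col[i] <- center[2L]
  }
  cells
}

#' Render a synthetic image with ground truth
#'
#' Each cell is drawn as a Gaussian disc: peak amplitude times
#' \code{exp(-d^2 / (2 sigma^2))}, truncated at 3 sigma, with
#' \code{sigma^2 = (radius / 2)^2 + psfSigma^2} (nominal radius at the 1/e^2
#' intensity level, plus point-spread blur in quadrature). Overlapping cells
#' add, as fluorescence does. Uniform background and per-pixel Gaussian
#' noise are added last; intensities are clamped at zero. The same spec
#' (including seed) always renders the identical image.
#'
#' @param spec a [SimImageSpec-class].
#' @return list with \code{stack} (an [ImageStack-class]) and \code{truth},
#'   a data.frame with one row per cell: cell_id, row, col, axial_fraction,
#'   true_class, cluster_id.
#' @export
setMethod("renderImage", "SimImageSpec", function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    cells <- .placeCells(spec)
    shp <- spec@imageShape
    data <- array(spec@backgroundLevel,
                  c(spec@nChannels, shp[1L], shp[2L]))
    ampCols <- grep("^amp", names(cells))
    for (i in seq_len(nrow(cells))) {
      cr <- cells$row[i]; cc <- cells$col[i]
      if (cr < 0 || cr > shp[1L] - 1 || cc < 0 || cc > shp[2L] - 1)
        stopf("cell %d center (%.1f, %.1f) lies outside the %d x %d image",
              cells$cellId[i], cr, cc, shp[1L], shp[2L])
      sigma <- sqrt((cells$radius[i] / 2)^2 + spec@psfSigma^2)
      ext <- ceiling(3 * sigma)
      rows <- max(0, floor(cr - ext)):min(shp[1L] - 1, ceiling(cr + ext))
      cols <- max(0, floor(cc - ext)):min(shp[2L] - 1, ceiling(cc + ext))
      d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
      g <- exp(-d2 / (2 * sigma^2))
      g[d2 > (3 * sigma)^2] <- 0
      for (ch in seq_len(spec@nChannels)) {
        amp <- cells[[ampCols[ch]]][i]
        data[ch, rows + 1L, cols + 1L] <-
          data[ch, rows + 1L, cols + 1L] + amp * g
      }
    }
    if (spec@noiseSd > 0)
      data <- data + stats::rnorm(length(data), 0, spec@noiseSd)
    data[data < 0] <- 0
    truth <- data.frame(
      cell_id = cells$cellId, row = cells$row, col = cells$col,
      axial_fraction = cells$axialFraction,
      true_class = cells$trueClass, cluster_id = cells$clusterId
    )
    list(stack = ImageStack(data), truth = truth)
  })
})

#' Write / read image stacks as multi-page TIFF
#'
#' One TIFF page per channel (z-stacks are an in-memory construct and are
#' projected before writing), 32-bit float samples. Intensities are clamped
#' to [0, 1] on write, the native scale of the generator.
#'
#' @param stack an [ImageStack-class] with no z dimension.
#' @param path file path.
#' @return \code{readImageTIFF} returns an [ImageStack-class];
#'   \code{writeImageTIFF} returns \code{path} invisibly.
#' @export
writeImageTIFF <- function(stack, path) {
  d <- imageData(stack)
  stopifnot(length(dim(d)) == 3L)
  pages <- lapply(seq_len(dim(d)[1L]), function(ch) {
    m <- d[ch, , ]
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- array(0, c(length(pages), dim(pages[[1L]])))
  for (i in seq_along(pages)) d[i, , ] <- pages[[i]]
  ImageStack(d)
}

#' Write a ground-truth or cell table as CSV
#'
#' @param table data.frame (truth table, object table or count table).
#' @param path file path.
#' @export
writeTableCSV <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
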