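#' @import methods
NULL

#' Multi-channel fluorescence image stack
#'
#' Container for a fluorescence image as an intensity array in
#' \code{channel x row x col} order, optionally with a trailing z dimension
#' (\code{channel x row x col x z}) before maximum-intensity projection.
#' Intensities are finite and non-negative; the native scale is [0, 1]
#' (TIFF round trips clamp to that range) but values above 1 are permitted
#' in memory, e.g., where overlapping cells sum.
#'
#' Pixel coordinates throughout the imaging side of the package are 0-based
#' \code{(row, col)} with pixel centers at integers.
#'
#' @slot data numeric array, \code{channels x rows x cols[ x z]}.
#' @slot pixelSize optional physical pixel size in micrometers per pixel
#'   (\code{NA_real_} when unknown); carried as metadata only.
#'
#' @seealso [ImageStack()] for construction, [maxProject()],
#'   [segmentObjects()]
#' @export
setClass("ImageStack",
  representation(data = "array", pixelSize = "numeric"),
  prototype(pixelSize = NA_real_)
)

setValidity("ImageStack", function(object) {
  d <- object@data
  if (!(length(dim(d)) %in% c(3L, 4L)))
    return("data must be channels x rows x cols, optionally x z")
  if (any(!is.finite(d)))
    return("intensities must be finite")
  if (any(d < 0))
    return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L)
    return("pixelSize must be a single value (possibly NA)")
  TRUE
})

#' Specification of one synthetic gut image
#'
#' Describes a two-(or more-)channel synthetic fluorescence image of
#' blob-like cells scattered along a curved gut midline, with enough ground
#' truth to score detection, counting and axial-position recovery exactly.
#' Build with [simImageSpec()]; render with [renderImage()].
#'
#' @slot imageShape integer(2), image size in pixels (rows, cols).
#' @slot nChannels integer, number of fluorescence channels.
#' @slot gutStart,gutEnd numeric(2) pixel coordinates (row, col) of the
#'   manual gut start/end markers.
#' @slot gutPath numeric matrix of ordered (row, col) control points of the
#'   gut midline polyline; first/last rows equal gutStart/gutEnd.
#' @slot cells data.frame of cells, one row per cell (see [simCells()]).
#' @slot backgroundLevel uniform background intensity.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot psfSigma point-spread blur in pixels, added in quadrature to the
#'   intrinsic Gaussian width of each cell.
#' @slot seed integer RNG seed; rendering is a pure function of the spec.
#' @export
setClass("SimImageSpec",
  representation(
    imageShape = "integer", nChannels = "integer",
    gutStart = "numeric", gutEnd = "numeric", gutPath = "matrix",
    cells = "data.frame", backgroundLevel = "numeric",
    noiseSd = "numeric", psfSigma = "numeric", seed = "integer"
  )
)

setValidity("SimImageSpec", function(object) {
  if (length(object@imageShape) != 2L || any(object@imageShape <= 0L))
    return("imageShape must be two positive integers")
  if (object@nChannels < 1L)
    return("nChannels must be >= 1")
  if (object@backgroundLevel < 0)
    return("backgroundLevel must be >= 0")
  if (object@noiseSd < 0)
    return("noiseSd must be >= 0")
  if (object@psfSigma <= 0)
    return("psfSigma must be > 0")
  if (isTRUE(all(object@gutStart == object@gutEnd)))
    return("gutStart and gutEnd must differ")
  cells <- object@cells
  if (nrow(cells)) {
    need <- c("cellId", "axialFraction", "row", "col", "radius",
              "clusterId", "trueClass")
    if (!all(need %in% names(cells)))
      return(paste("cells must have columns:", paste(need, collapse = ", ")))
    if (any(cells$axialFraction < 0 | cells$axialFraction > 1, na.rm = TRUE))
      return("axialFraction must lie in [0, 1]")
    if (any(cells$radius <= 0))
      return("cell radius must be > 0")
    amp <- grep("^amp", names(cells))
    if (length(amp) != object@nChannels)
      return("cells must have one amp column per channel")
    if (any(as.matrix(cells[amp]) < 0))
      return("channel amplitudes must be >= 0")
  }
  TRUE
})

#' Specification of a synthetic ablation cohort
#'
#' Per-fish, per-subtype, per-quarter cell counts for a control and an
#' ablated group, drawn from a negative-binomial model (Poisson in the
#' dispersion = 0 limit) with a multiplicative reduction applied to the
#' ablated group. Build with [simCohortSpec()]; draw with
#' [simulateCounts()].
#'
#' @slot nFishPerGroup integer, fish per group (>= 2).
#' @slot groupMeans numeric matrix, subtypes x 4 quarters, expected cells
#'   per fish in the control group.
#' @slot effect numeric matrix of the same shape, multiplicative reduction
#'   in [0, 1] applied to the ablated group (ablated mean =
#'   groupMeans * (1 - effect)).
#' @slot dispersion negative-binomial overdispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @slot seed integer RNG seed.
#' @export
setClass("SimCohortSpec",
  representation(
    nFishPerGroup = "integer", groupMeans = "matrix", effect = "matrix",
    dispersion = "numeric", seed = "integer"
  )
)

setValidity("SimCohortSpec", function(object) {
  if (object@nFishPerGroup < 2L)
    return("nFishPerGroup must be >= 2")
  if (any(object@groupMeans < 0))
    return("group means must be >= 0")
  if (!identical(dim(object@groupMeans), dim(object@effect)))
    return("effect must have the same shape as groupMeans")
  if (any(object@effect < 0 | object@effect > 1))
    return("effect must lie in [0, 1]")
  if (object@dispersion < 0)
    return("dispersion must be >= 0")
  if (ncol(object@groupMeans) != 4L)
    return("groupMeans must have 4 quarter columns")
  TRUE
})

#' Manual gut start/end markers for one image
#'
#' The two manually annotated markers that define the normalized gut axis of
#' one fish image. Positions of counted cells are expressed as the clamped
#' scalar projection onto the start-to-end chord, divided by the chord
#' length, giving a dimensionless coordinate s in [0, 1].
#'
#' @slot start,end numeric(2) pixel coordinates (row, col); must differ.
#' @seealso [gutFrame()], [normalizePosition()]
#' @export
setClass("GutFrame", representation(start = "numeric", end = "numeric"))

setValidity("GutFrame", function(object) {
  if (length(object@start) != 2L || length(object@end) != 2L)
    return("start and end must be (row, col) pairs")
  if (all(object@start == object@end))
    return("start and end must differ (degenerate frame)")
  TRUE
})

#' Prohormone precursor protein
#'
#' A precursor (preprohormone) amino-acid sequence together with observed
#' missense variants and named functional regions (signal peptide, spans
#' aligning to characterized hormone peptides). Protein coordinates are
#' 1-based inclusive, in contrast to the 0-based pixel convention of the
#' imaging side; each module documents its own convention.
#'
#' @slot id character, precursor identifier.
#' @slot sequence character, amino-acid sequence over the 20-letter
#'   alphabet.
#' @slot variants data.frame with columns \code{pos}, \code{ref},
#'   \code{alt}; \code{ref} must match the sequence at \code{pos}.
#' @slot regions data.frame with columns \code{name}, \code{start},
#'   \code{end} (1-based inclusive, within the sequence).
#' @seealso [precursor()], [locatePeptide()], [buildAtlas()]
#' @export
setClass("Precursor",
  representation(id = "character", sequence = "character",
                 variants = "data.frame", regions = "data.frame")
)

setValidity("Precursor", function(object) {
  seq <- object@sequence
  if (length(seq) != 1L || nchar(seq) < 1L)
    return("sequence must be a single non-empty string")
  if (grepl(sprintf("[^%s]", paste(names(.RESIDUE_MASS), collapse = "")), seq))
    return("sequence contains characters outside the 20-letter alphabet")
  v <- object@variants
  if (nrow(v)) {
    if (!all(c("pos", "ref", "alt") %in% names(v)))
      return("variants must have columns pos, ref, alt")
    if (any(v$pos < 1L | v$pos > nchar(seq)))
      return("variant position outside sequence")
    obs <- substring(seq, v$pos, v$pos)
    if (!all(obs == v$ref))
      return("variant ref residue does not match sequence")
  }
  r <- object@regions
  if (nrow(r)) {
    if (!all(c("name", "start", "end") %in% names(r)))
      return("regions must have columns name, start, end")
    if (any(r$start < 1L | r$end > nchar(seq) | r$start > r$end))
      return("region interval outside [1, length]")
  }
  TRUE
})

#' Per-residue annotation of a precursor from identified peptides
#'
#' The atlas view of one precursor: per-residue coverage depth by aligned
#' peptides, junction positions where one peptide ends and another begins at
#' the adjacent residue (abutting peptides), dibasic cleavage sites, and
#' per-peptide overlaps with annotated functional regions. Built by
#' [buildAtlas()].
#'
#' @slot precursorId character.
#' @slot length precursor length in residues.
#' @slot coverage integer vector, length \code{length}; coverage depth at
#'   residue i = number of aligned peptides whose span contains i.
#' @slot junctions integer vector of positions p such that some peptide ends
#'   at p and another starts at p + 1.
#' @slot dibasicSites data.frame (\code{start}, \code{end}) of adjacent K/R
#'   pairs.
#' @slot regionOverlaps data.frame mapping peptide hits to the regions they
#'   intersect.
#' @slot hits data.frame of the aligned peptides the atlas was built from.
#' @export
setClass("PrecursorAtlas",
  representation(
    precursorId = "character", length = "integer", coverage = "integer",
    junctions = "integer", dibasicSites = "data.frame",
    regionOverlaps = "data.frame", hits = "data.frame"
  )
)

setValidity("PrecursorAtlas", function(object) {
  if (length(object@coverage) != object@length)
    return("coverage must have one entry per residue")
  if (any(object@coverage < 0))
    return("coverage depths must be non-negative")
  TRUE
})
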