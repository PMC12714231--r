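#' @export
setGeneric("renderImage", function(spec, ...) standardGeneric("renderImage"))

#' @export
setGeneric("simulateCounts", function(spec, ...)
  standardGeneric("simulateCounts"))

#' @export
setGeneric("maxProject", function(stack, ...) standardGeneric("maxProject"))

#' @export
setGeneric("locatePeptide", function(peptide, precursor, ...)
  standardGeneric("locatePeptide"))

#' @export
setGeneric("findDibasicSites", function(x, ...)
  standardGeneric("findDibasicSites"))

#' @export
setGeneric("buildAtlas", function(precursor, hits, ...)
  standardGeneric("buildAtlas"))

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @export
setGeneric("channelImage", function(x, channel) standardGeneric("channelImage"))
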