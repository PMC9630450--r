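#' @include utils.R
NULL

#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))

#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @export
setGeneric("fieldSize", function(x) standardGeneric("fieldSize"))

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @export
setGeneric("trackId", function(x) standardGeneric("trackId"))

#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setGeneric("trueMode", function(x) standardGeneric("trueMode"))

#' @export
setGeneric("contactFlags", function(x) standardGeneric("contactFlags"))

#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @export
setGeneric("skeleton", function(x) standardGeneric("skeleton"))

#' @export
setGeneric("surfaceVoxels", function(x) standardGeneric("surfaceVoxels"))

#' @export
setGeneric("radialAxis", function(x) standardGeneric("radialAxis"))
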