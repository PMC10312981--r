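#' @import methods
NULL

#' Channel names of a MarkerImage
#' @param x a [MarkerImage-class]
#' @return character vector of marker names
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel as a matrix
#' @param x a [MarkerImage-class]
#' @param name marker name
#' @return numeric matrix (row = y, col = x)
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' Pixel size in micrometres
#' @param x a [MarkerImage-class]
#' @return scalar, um per pixel
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Imaging modality
#' @param x a [MarkerImage-class]
#' @return `"fluorescence"` or `"imc"`
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Integer label matrix of a LabelMask
#' @param x a [LabelMask-class]
#' @return integer matrix, 0 = background
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Cell instance ids present in a LabelMask
#' @param x a [LabelMask-class]
#' @return sorted integer vector of positive labels
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Tumor compartment mask
#' @param x a [RegionMasks-class]
#' @return logical matrix
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' Stroma compartment mask
#' @param x a [RegionMasks-class]
#' @return logical matrix
#' @export
setGeneric("stromaMask", function(x) standardGeneric("stromaMask"))
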