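#' MarkerImage: named multichannel intensity image
#'
#' Container for a set of co-registered 2D marker channels from a multiplexed
#' acquisition (histocytometry fluorescence or imaging mass cytometry).
#' Channels are numeric matrices (row = y, column = x) sharing one shape;
#' intensities are nonnegative and carried as floating point regardless of
#' on-disk bit depth. Pixels are square; `pixelSize` is the side length in
#' micrometres.
#'
#' @slot channels named list of numeric matrices, one per marker.
#' @slot pixelSize micrometres per pixel (scalar, square pixels).
#' @slot modality `"fluorescence"` or `"imc"`.
#' @slot logTransformed has [imcPreprocess()] already been applied?
#'
#' @seealso [readMarkerImage()], [imcPreprocess()], [getChannel()]
#' @export
setClass("MarkerImage",
  representation(
    channels = "list",
    pixelSize = "numeric",
    modality = "character",
    logTransformed = "logical"
  ),
  prototype(
    channels = list(),
    pixelSize = 1,
    modality = "fluorescence",
    logTransformed = FALSE
  )
)

setValidity("MarkerImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(names(ch) == "") || anyDuplicated(names(ch)))
    return("channels must be uniquely named")
  if (!all(vapply(ch, is.matrix, logical(1L))))
    return("every channel must be a matrix")
  d <- dim(ch[[1L]])
  for (m in ch) {
    if (!identical(dim(m), d)) return("all channels must share one shape")
    if (anyNA(m) || any(m < 0)) return("intensities must be finite and >= 0")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (!object@modality %in% c("fluorescence", "imc"))
    return("modality must be 'fluorescence' or 'imc'")
  TRUE
})

#' LabelMask: integer cell-instance segmentation mask
#'
#' A 2D integer raster in which 0 is background and each positive value k
#' marks the pixels of cell instance k.
#'
#' @slot labels integer matrix; 0 = background.
#' @seealso [readLabelMask()], [extractMembrane()], [findContacts()]
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  m <- object@labels
  if (!is.matrix(m) || !is.numeric(m)) return("labels must be a numeric matrix")
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    return("labels must be nonnegative integers")
  TRUE
})

#' RegionMasks: binary tumor and stroma compartment masks
#'
#' Stroma excludes the tumor mask by construction, so the two compartments
#' are disjoint.
#'
#' @slot tumor logical matrix.
#' @slot stroma logical matrix, disjoint from `tumor`.
#' @seealso [tumorStroma()], [assignRegion()]
#' @export
setClass("RegionMasks", representation(tumor = "matrix", stroma = "matrix"))

setValidity("RegionMasks", function(object) {
  if (!identical(dim(object@tumor), dim(object@stroma)))
    return("tumor and stroma masks must share one shape")
  if (!is.logical(object@tumor) || !is.logical(object@stroma))
    return("masks must be logical matrices")
  if (any(object@tumor & object@stroma))
    return("tumor and stroma must be disjoint")
  TRUE
})

#' AnalysisConfig: fixed parameters of the synapse and spatial analyses
#'
#' Holds the constants of the contact-geometry, synapse-scoring and
#' radial-distribution procedures. Defaults follow the published analysis:
#' a 2-pixel internal membrane for fluorescence (1 for IMC), a radius-2
#' diamond dilation for contact detection, 1 um distance bins out to 100 um,
#' 100 label permutations, and a seed-and-grow null with 5 seeds per cell,
#' 15-pixel minimum regions and 100 iterations.
#'
#' @slot membraneWidthPx internal membrane width in pixels (1 or 2).
#' @slot dilationRadiusPx radius of the diamond (L1 ball) used to detect
#'   contacts.
#' @slot synapseMarker marker scored by default.
#' @slot referenceTypes,targetTypes cell-type labels of reference (T) cells
#'   and target cells.
#' @slot rdfMaxUm,rdfBinUm RDF range and bin width in micrometres.
#' @slot nPermutations label permutations for the expected RDF curve.
#' @slot nullSeedsPerCell,nullMinRegionPx,nullIterations seed-and-grow null
#'   model parameters.
#' @slot rngSeed master seed; all randomised steps derive substreams from it.
#' @seealso [cisaConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    membraneWidthPx = "integer",
    dilationRadiusPx = "integer",
    synapseMarker = "character",
    referenceTypes = "character",
    targetTypes = "character",
    rdfMaxUm = "numeric",
    rdfBinUm = "numeric",
    nPermutations = "integer",
    nullSeedsPerCell = "integer",
    nullMinRegionPx = "integer",
    nullIterations = "integer",
    rngSeed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  pos <- c(
    membraneWidthPx = object@membraneWidthPx,
    dilationRadiusPx = object@dilationRadiusPx,
    rdfMaxUm = object@rdfMaxUm,
    rdfBinUm = object@rdfBinUm,
    nPermutations = object@nPermutations,
    nullSeedsPerCell = object@nullSeedsPerCell,
    nullMinRegionPx = object@nullMinRegionPx,
    nullIterations = object@nullIterations
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all counts and sizes must be positive")
  if (!object@membraneWidthPx %in% c(1L, 2L))
    return("membraneWidthPx must be 1 or 2")
  if (abs(object@rdfMaxUm / object@rdfBinUm -
          round(object@rdfMaxUm / object@rdfBinUm)) > 1e-9)
    return("rdfMaxUm must be divisible by rdfBinUm")
  TRUE
})
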