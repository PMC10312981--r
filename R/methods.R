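#' Construct a MarkerImage from matrices
#'
#' @param channels named list of nonnegative numeric matrices with identical
#'   dimensions, one per marker.
#' @param pixelSize micrometres per pixel (square pixels).
#' @param modality `"fluorescence"` (histocytometry) or `"imc"` (imaging mass
#'   cytometry).
#' @return a [MarkerImage-class]
#' @examples
#' img <- MarkerImage(list(CD3 = matrix(0, 4, 4)), pixelSize = 0.5)
#' channelNames(img)
#' @export
MarkerImage <- function(channels, pixelSize = 1,
                        modality = c("fluorescence", "imc")) {
  modality <- match.arg(modality)
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("MarkerImage", channels = channels, pixelSize = as.numeric(pixelSize),
      modality = modality, logTransformed = FALSE)
}

#' Construct a LabelMask from an integer matrix
#' @param labels integer matrix, 0 = background, k > 0 = cell instance k.
#' @return a [LabelMask-class]
#' @export
LabelMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels)
}

#' Construct RegionMasks; stroma is trimmed to exclude tumor
#' @param tumor,stroma logical matrices of identical shape.
#' @return a [RegionMasks-class]
#' @export
RegionMasks <- function(tumor, stroma) {
  new("RegionMasks", tumor = tumor, stroma = stroma & !tumor)
}

#' @rdname channelNames
#' @export
setMethod("channelNames", "MarkerImage", function(x) names(x@channels))

#' @rdname getChannel
#' @export
setMethod("getChannel", "MarkerImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("unknown channel '", name, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
})

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MarkerImage", function(x) x@pixelSize)

#' @rdname modality
#' @export
setMethod("modality", "MarkerImage", function(x) x@modality)

#' @export
setMethod("dim", "MarkerImage", function(x) dim(x@channels[[1L]]))

setMethod("show", "MarkerImage", function(object) {
  d <- dim(object)
  cat("MarkerImage:", d[1L], "x", d[2L], "px,",
      length(object@channels), "channel(s) [",
      paste(head(names(object@channels), 6L), collapse = ", "),
      if (length(object@channels) > 6L) ", ..." else "", "]\n", sep = " ")
  cat("  pixel size:", object@pixelSize, "um;  modality:", object@modality,
      if (object@logTransformed) " (log2-transformed)" else "", "\n")
})

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabelMask", function(x) x@labels)

#' @rdname cellIds
#' @export
setMethod("cellIds", "LabelMask", function(x) {
  ids <- sort(unique(as.vector(x@labels)))
  ids[ids > 0L]
})

#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat("LabelMask:", d[1L], "x", d[2L], "px,", length(cellIds(object)),
      "cells\n")
})

#' @rdname tumorMask
#' @export
setMethod("tumorMask", "RegionMasks", function(x) x@tumor)

#' @rdname stromaMask
#' @export
setMethod("stromaMask", "RegionMasks", function(x) x@stroma)

setMethod("show", "RegionMasks", function(object) {
  cat("RegionMasks:", sum(object@tumor), "tumor px,", sum(object@stroma),
      "stroma px\n")
})

#' Analysis configuration with published defaults
#'
#' @param membraneWidthPx internal membrane width in pixels; defaults to 2
#'   for fluorescence and 1 for IMC.
#' @param dilationRadiusPx radius of the diamond structuring element used to
#'   detect contacts (default 2).
#' @param synapseMarker marker scored by `sigma` (default `"CD3"`).
#' @param referenceTypes,targetTypes reference (T cell) and target cell type
#'   labels.
#' @param rdfMaxUm,rdfBinUm RDF range and bin width (default 100 um / 1 um).
#' @param nPermutations label permutations for the expected RDF (default 100).
#' @param nullSeedsPerCell,nullMinRegionPx,nullIterations seed-and-grow null
#'   parameters (defaults 5, 15, 100).
#' @param rngSeed master seed for all randomised steps.
#' @param modality used only to pick the membrane-width default.
#' @return an [AnalysisConfig-class]
#' @examples
#' cfg <- cisaConfig(referenceTypes = "Tcell", targetTypes = "APC")
#' @export
cisaConfig <- function(membraneWidthPx = NULL,
                       dilationRadiusPx = 2L,
                       synapseMarker = "CD3",
                       referenceTypes = "Tcell",
                       targetTypes = "APC",
                       rdfMaxUm = 100,
                       rdfBinUm = 1,
                       nPermutations = 100L,
                       nullSeedsPerCell = 5L,
                       nullMinRegionPx = 15L,
                       nullIterations = 100L,
                       rngSeed = 1L,
                       modality = c("fluorescence", "imc")) {
  modality <- match.arg(modality)
  if (is.null(membraneWidthPx))
    membraneWidthPx <- if (modality == "imc") 1L else 2L
  new("AnalysisConfig",
      membraneWidthPx = as.integer(membraneWidthPx),
      dilationRadiusPx = as.integer(dilationRadiusPx),
      synapseMarker = synapseMarker,
      referenceTypes = referenceTypes,
      targetTypes = targetTypes,
      rdfMaxUm = as.numeric(rdfMaxUm),
      rdfBinUm = as.numeric(rdfBinUm),
      nPermutations = as.integer(nPermutations),
      nullSeedsPerCell = as.integer(nullSeedsPerCell),
      nullMinRegionPx = as.integer(nullMinRegionPx),
      nullIterations = as.integer(nullIterations),
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig: membrane", object@membraneWidthPx,
      "px, dilation radius", object@dilationRadiusPx,
      "px, marker", object@synapseMarker, "\n")
  cat("  ref types:", paste(object@referenceTypes, collapse = ","),
      " target types:", paste(object@targetTypes, collapse = ","), "\n")
  cat("  RDF:", object@rdfBinUm, "um bins to", object@rdfMaxUm, "um,",
      object@nPermutations, "permutations\n")
  cat("  null model:", object@nullSeedsPerCell, "seeds/cell, >=",
      object@nullMinRegionPx, "px,", object@nullIterations,
      "iterations; seed", object@rngSeed, "\n")
})
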