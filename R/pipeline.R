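#' End-to-end synapse analysis of one sample
#'
#' Convenience wrapper: contact extraction ([computeContacts()]), scoring
#' ([scoreContacts()]), and per-sample aggregation ([aggregateSynapse()]).
#'
#' @param image a [MarkerImage-class]
#' @param mask a [LabelMask-class]
#' @param cellTable cell table (`id`, `types`, optionally `region`)
#' @param config an [AnalysisConfig-class]
#' @param marker channel to score (default `config@synapseMarker`)
#' @param region restrict reference cells to a compartment (`NULL`: all)
#' @param sampleId carried into the outputs
#' @return list with `contacts`, `scores`, `summary`
#' @examples
#' sim <- generateTissue(syntheticTissueConfig(nPairs = 4, nSingles = 3))
#' res <- synapseAnalysis(sim$image, sim$mask, sim$cellTable)
#' res$summary
#' @export
synapseAnalysis <- function(image, mask, cellTable,
                            config = cisaConfig(modality = modality(image)),
                            marker = config@synapseMarker, region = NULL,
                            sampleId = "sample") {
  cellTable <- validateCellTable(cellTable, mask)
  refIds <- cellTable$id[hasType(cellTable$types, config@referenceTypes)]
  if (!is.null(region))
    refIds <- intersect(refIds,
                        cellTable$id[cellTable$region == region])
  contacts <- computeContacts(mask, cellTable, config, refIds = refIds)
  scores <- scoreContacts(image, contacts, config, marker = marker,
                          mask = mask, cellTable = cellTable)
  if (nrow(scores)) {
    scores$sample_id <- sampleId
    scores$region <- if (is.null(region)) "all" else region
  }
  summary <- aggregateSynapse(scores)
  list(contacts = contacts, scores = scores, summary = summary)
}
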