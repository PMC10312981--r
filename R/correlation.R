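#' Correlation of synapse scores between two markers
#'
#' Matches the two score sets on their contact keys (`sample_id` when
#' present, `ref_id`, `neighbor_id`), drops pairs where either score is
#' excluded, and computes the Pearson correlation across matched contacts —
#' pooled over all samples, or one coefficient per sample.
#'
#' @param scoresA,scoresB data.frames from [scoreContacts()] (one marker
#'   each)
#' @param bySample compute one r per `sample_id` instead of pooling
#' @return data.frame with `marker_a`, `marker_b`, `method = "cisa"`, `r`,
#'   `n` (and `sample_id` when `bySample`); `r` is `NA` with fewer than two
#'   matched contacts or zero variance
#' @export
cisaCorrelation <- function(scoresA, scoresB, bySample = FALSE) {
  keys <- intersect(c("sample_id", "ref_id", "neighbor_id"),
                    intersect(names(scoresA), names(scoresB)))
  a <- scoresA[!scoresA$excluded & is.finite(scoresA$sigma), , drop = FALSE]
  b <- scoresB[!scoresB$excluded & is.finite(scoresB$sigma), , drop = FALSE]
  m <- merge(a[, c(keys, "sigma")], b[, c(keys, "sigma")],
             by = keys, suffixes = c("_a", "_b"))
  markerA <- scoresA$marker[1L]
  markerB <- scoresB$marker[1L]
  pearson <- function(x, y) {
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  if (bySample && "sample_id" %in% keys) {
    sp <- split(m, m$sample_id)
    out <- data.frame(
      sample_id = names(sp),
      marker_a = markerA, marker_b = markerB, method = "cisa",
      r = vapply(sp, function(d) pearson(d$sigma_a, d$sigma_b), numeric(1L)),
      n = vapply(sp, nrow, integer(1L)),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    return(out)
  }
  data.frame(marker_a = markerA, marker_b = markerB, method = "cisa",
             r = pearson(m$sigma_a, m$sigma_b), n = nrow(m),
             stringsAsFactors = FALSE)
}

#' Contact-naive pixel-wise correlation within cells of a type
#'
#' Pools every pixel of every cell holding `cellType` (whole cell area, not
#' only membrane) and computes the Pearson correlation between the two
#' marker channels over that pixel pool — the baseline the synapse-score
#' correlation is compared against.
#'
#' @param image a [MarkerImage-class]
#' @param mask a [LabelMask-class]
#' @param cellTable cell table with `id`, `types`
#' @param cellType type label selecting the cells
#' @param markerA,markerB channel names
#' @return data.frame with `marker_a`, `marker_b`, `cell_type`,
#'   `method = "pixelwise"`, `r`, `n` (pixels); `r` is `NA` for fewer than
#'   two pixels or a constant channel
#' @export
pixelwiseCorrelation <- function(image, mask, cellTable, cellType,
                                 markerA, markerB) {
  ids <- cellTable$id[hasType(cellTable$types, cellType)]
  idx <- which(labelMatrix(mask) %in% ids)
  x <- getChannel(image, markerA)[idx]
  y <- getChannel(image, markerB)[idx]
  r <- if (length(idx) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    NA_real_ else stats::cor(x, y)
  data.frame(marker_a = markerA, marker_b = markerB, cell_type = cellType,
             method = "pixelwise", r = r, n = length(idx),
             stringsAsFactors = FALSE)
}

#' Paired comparison of CISA vs pixel-wise correlations
#'
#' Two-sided paired t-test of per-sample correlation coefficients. With a
#' zero-variance difference vector the test statistic is undefined; the
#' result is flagged degenerate and reports the mean difference with `p = 1`
#' when the difference is exactly 0 and `p = NA` otherwise.
#'
#' @param cisaR,pixelwiseR per-sample correlation coefficients, matched by
#'   position
#' @return list with `mean_difference`, `p`, `n`, `degenerate`
#' @export
compareCorrelationMethods <- function(cisaR, pixelwiseR) {
  ok <- is.finite(cisaR) & is.finite(pixelwiseR)
  if (sum(ok) < 3L) stop("need at least 3 matched samples")
  d <- cisaR[ok] - pixelwiseR[ok]
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    return(list(mean_difference = mean(d),
                p = if (mean(d) == 0) 1 else NA_real_,
                n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(cisaR[ok], pixelwiseR[ok], paired = TRUE)
  list(mean_difference = mean(d), p = tt$p.value, n = length(d),
       degenerate = FALSE)
}
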