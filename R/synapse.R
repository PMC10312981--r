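#' Synapse strength of one contact
#'
#' The synapse strength is the log2 ratio of the mean marker intensity over
#' the contact membrane pixels to the mean over the non-contact membrane
#' pixels. Positive values indicate polarization of the marker toward the
#' neighbor. For IMC data, where either mean is frequently exactly 0, a
#' sample-level noise term (background-cell marker level) provides a fill-in
#' value; the special case contact mean = 0 with non-contact mean below the
#' noise term is scored 0 ("no evidence either way").
#'
#' @param image a [MarkerImage-class]
#' @param record one contact record row (from [computeContacts()]), or any
#'   list with `contact_px` and `noncontact_px` linear-index vectors
#' @param marker channel to score
#' @param noise optional noise term (scalar mean intensity) from
#'   [estimateNoiseTerm()]; required for the IMC fill-in rules
#' @param modality `"fluorescence"` (standard scoring) or `"imc"`
#'   (zero-handling rules active)
#' @return one-row data.frame: `ref_id`, `neighbor_id`, `marker`, `sigma`,
#'   `mode` (`"standard"`, `"imc_noise_adjusted"` or `"zero_rule"`), and
#'   logical flags `fillin_contact`, `fillin_noncontact`, `excluded`
#' @examples
#' img <- MarkerImage(list(CD3 = matrix(c(8, 8, 2, 2), 2, 2)))
#' rec <- list(ref_id = 1L, neighbor_id = 2L,
#'             contact_px = list(1:2), noncontact_px = list(3:4))
#' synapseStrength(img, rec, "CD3")$sigma  # log2(8/2) = 2
#' @export
synapseStrength <- function(image, record, marker, noise = NULL,
                            modality = NULL) {
  if (is.null(modality)) modality <- cisa::modality(image)
  ch <- getChannel(image, marker)
  contact <- record$contact_px[[1L]]
  noncontact <- record$noncontact_px[[1L]]
  refId <- if (!is.null(record$ref_id)) record$ref_id[1L] else NA_integer_
  nbId <- if (!is.null(record$neighbor_id)) record$neighbor_id[1L]
          else NA_integer_
  score <- function(sigma, mode, fc = FALSE, fn = FALSE, excl = FALSE) {
    data.frame(ref_id = refId, neighbor_id = nbId, marker = marker,
               sigma = sigma, mode = mode, fillin_contact = fc,
               fillin_noncontact = fn, excluded = excl,
               stringsAsFactors = FALSE)
  }
  if (!length(contact) || !length(noncontact))
    return(score(NA_real_, "standard", excl = TRUE))
  mc <- mean(ch[contact])
  mn <- mean(ch[noncontact])
  if (modality == "imc") {
    if (is.null(noise)) stop("IMC scoring needs a noise term")
    nv <- if (is.numeric(noise)) noise[1L] else noise$value[1L]
    if (mc == 0 && mn < nv)
      return(score(0, "zero_rule"))
    fc <- mc == 0; fn <- mn == 0
    if (fc) mc <- nv
    if (fn) mn <- nv
    mode <- if (fc || fn) "imc_noise_adjusted" else "standard"
    return(score(log2(mc / mn), mode, fc, fn))
  }
  if (mc == 0 || mn == 0)
    return(score(NA_real_, "standard", excl = TRUE))
  score(log2(mc / mn), "standard")
}

#' Score every contact record of a sample
#'
#' Applies [synapseStrength()] to each row of a [computeContacts()] result,
#' estimating the IMC noise term once per call when needed. Records with an
#' empty non-contact pool are flagged excluded.
#'
#' @param image a [MarkerImage-class]
#' @param records contact records from [computeContacts()]
#' @param marker channel to score; default from `config`
#' @param config an [AnalysisConfig-class]
#' @param mask,cellTable needed only for IMC noise estimation
#' @return data.frame of scores joined to the record keys (`target_type`,
#'   `border`, pixel counts)
#' @export
scoreContacts <- function(image, records, config = cisaConfig(),
                          marker = config@synapseMarker, mask = NULL,
                          cellTable = NULL) {
  noise <- NULL
  if (modality(image) == "imc") {
    if (is.null(mask) || is.null(cellTable))
      stop("IMC scoring needs mask and cellTable for the noise term")
    noise <- estimateNoiseTerm(image, mask, cellTable, marker,
                               config@referenceTypes)
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- synapseStrength(image, records[i, , drop = FALSE], marker,
                         noise = noise, modality = modality(image))
    s$target_type <- records$target_type[i]
    s$border <- records$border[i]
    s$n_contact_px <- records$n_contact_px[i]
    s$n_noncontact_px <- records$n_noncontact_px[i]
    out[[i]] <- s
  }
  if (!length(out))
    return(data.frame(ref_id = integer(0), neighbor_id = integer(0),
                      marker = character(0), sigma = numeric(0),
                      mode = character(0), fillin_contact = logical(0),
                      fillin_noncontact = logical(0), excluded = logical(0),
                      target_type = character(0), border = logical(0),
                      n_contact_px = integer(0),
                      n_noncontact_px = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample-level noise term for IMC zero handling
#'
#' The background marker level of a sample: the mean of the marker channel
#' over all pixels of cells holding none of the reference types (e.g. mean
#' CD3 over non-T cells).
#'
#' @param image a [MarkerImage-class]
#' @param mask a [LabelMask-class]
#' @param cellTable cell table with `id` and `types`
#' @param marker channel name
#' @param referenceTypes type labels excluded from the background pool
#' @return scalar mean intensity (>= 0)
#' @export
estimateNoiseTerm <- function(image, mask, cellTable, marker,
                              referenceTypes) {
  bg <- cellTable$id[!hasType(cellTable$types, referenceTypes)]
  if (!length(bg)) stop("noise term undefined: no non-reference cells")
  lab <- labelMatrix(mask)
  idx <- which(lab %in% bg)
  mean(getChannel(image, marker)[idx])
}

#' Seed-and-grow a random contiguous membrane region
#'
#' Seeds uniformly at random on the membrane, then grows over 8-connected
#' membrane pixels — adding one uniformly chosen frontier pixel at a time —
#' until the region holds at least `minSize` pixels. Membranes smaller than
#' `minSize` are returned whole.
#'
#' @param membranePx linear pixel indices of the membrane
#' @param dim image dimensions `c(nrow, ncol)`
#' @param minSize minimum region size (published value: 15)
#' @param adjacency optional precomputed [adjacencyList8()] over `membranePx`
#' @return integer vector of linear indices, a contiguous subset of
#'   `membranePx`
#' @export
seedAndGrow <- function(membranePx, dim, minSize = 15L, adjacency = NULL) {
  n <- length(membranePx)
  if (n <= minSize) return(membranePx)
  if (is.null(adjacency)) adjacency <- adjacencyList8(membranePx, dim)
  inRegion <- logical(n)
  inFrontier <- logical(n)
  seed <- sample.int(n, 1L)
  inRegion[seed] <- TRUE
  frontier <- adjacency[[seed]]
  inFrontier[frontier] <- TRUE
  size <- 1L
  while (size < minSize && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    inFrontier[pick] <- FALSE
    inRegion[pick] <- TRUE
    size <- size + 1L
    new <- adjacency[[pick]]
    new <- new[!inRegion[new] & !inFrontier[new]]
    if (length(new)) {
      frontier <- c(frontier, new)
      inFrontier[new] <- TRUE
    }
  }
  membranePx[inRegion]
}

#' Seed-and-grow null synapse model
#'
#' For each eligible reference cell (in contact with at least one target and
#' with a membrane of at least `nullMinRegionPx` pixels), draws
#' `nullSeedsPerCell` random contiguous membrane regions, scores each region
#' as a pseudo-contact against the remaining membrane, and averages them into
#' the cell's null value. The iteration value is the mean over cells; the
#' final null value is the mean over `nullIterations` iterations. Each
#' (cell, iteration) pair uses its own derived RNG substream, so results are
#' independent of evaluation order.
#'
#' @param image a [MarkerImage-class]
#' @param mask a [LabelMask-class]
#' @param refIds reference cells in contact (membrane recomputed here)
#' @param config an [AnalysisConfig-class]; uses the null-model slots,
#'   `membraneWidthPx` and `rngSeed`
#' @param marker channel; default `config@synapseMarker`
#' @return list with `null_sigma_bar` (scalar), `iteration_means` (length
#'   `nullIterations`) and `n_cells` used
#' @export
nullSynapseModel <- function(image, mask, refIds, config = cisaConfig(),
                             marker = config@synapseMarker) {
  ch <- getChannel(image, marker)
  dims <- dim(ch)
  membranes <- lapply(refIds, function(id)
    extractMembrane(mask, id, config@membraneWidthPx))
  keep <- vapply(membranes, length, integer(1L)) >= config@nullMinRegionPx
  membranes <- membranes[keep]
  ids <- refIds[keep]
  if (!length(ids)) stop("no eligible cells for the null synapse model")
  adjacency <- lapply(membranes, adjacencyList8, dim = dims)
  nIter <- config@nullIterations
  nSeeds <- config@nullSeedsPerCell
  iterMeans <- numeric(nIter)
  for (it in seq_len(nIter)) {
    cellVals <- numeric(length(ids))
    for (ci in seq_along(ids)) {
      mem <- membranes[[ci]]
      memVals <- ch[mem]
      total <- sum(memVals)
      cellVals[ci] <- withLocalSeed(
        deriveSeed(config@rngSeed, ids[ci], it), {
          sig <- numeric(nSeeds)
          for (s in seq_len(nSeeds)) {
            region <- seedAndGrow(mem, dims, config@nullMinRegionPx,
                                  adjacency[[ci]])
            inR <- mem %in% region
            mc <- mean(memVals[inR])
            mn <- (total - sum(memVals[inR])) / (length(mem) - sum(inR))
            sig[s] <- log2(mc / mn)
          }
          mean(sig)
        })
    }
    iterMeans[it] <- mean(cellVals)
  }
  list(null_sigma_bar = mean(iterMeans), iteration_means = iterMeans,
       n_cells = length(ids))
}

#' Aggregate per-contact scores to sample summaries
#'
#' Arithmetic mean of sigma per grouping key; excluded scores are dropped
#' first. A reference cell contacting several same-type neighbors
#' contributes one sigma per contact.
#'
#' @param scores data.frame from [scoreContacts()], optionally carrying
#'   grouping columns such as `sample_id`, `region`, `ref_type`
#' @param by character vector of grouping columns present in `scores`
#' @return data.frame with the grouping columns, `sigma_bar` and `n_contacts`
#' @export
aggregateSynapse <- function(scores,
                             by = intersect(c("sample_id", "marker",
                                              "ref_type", "target_type",
                                              "region"), names(scores))) {
  ok <- !scores$excluded & is.finite(scores$sigma)
  s <- scores[ok, , drop = FALSE]
  if (!nrow(s)) {
    out <- s[, by, drop = FALSE]
    out$sigma_bar <- numeric(0); out$n_contacts <- integer(0)
    return(out)
  }
  key <- interaction(s[, by, drop = FALSE], drop = TRUE, sep = "\r")
  agg <- data.frame(
    key = levels(key),
    sigma_bar = as.vector(tapply(s$sigma, key, mean)),
    n_contacts = as.vector(tapply(s$sigma, key, length)),
    stringsAsFactors = FALSE
  )
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  out <- stats::setNames(as.data.frame(parts, stringsAsFactors = FALSE), by)
  out$sigma_bar <- agg$sigma_bar
  out$n_contacts <- agg$n_contacts
  rownames(out) <- NULL
  out
}

#' Stratify patients by synapse formation
#'
#' Group 1: the per-sample mean synapse strength is strictly positive
#' (contact with a tendency to form synapses). Group 2: the mean is <= 0, or
#' the patient has no contact of the requested kind at all (`NA` sigma_bar).
#'
#' @param sigmaBar numeric vector of per-patient mean synapse strengths,
#'   `NA` where no contact exists
#' @return integer vector of group labels (1 or 2)
#' @examples
#' stratifyBySynapse(c(0.6, 0, -1, NA))  # 1 2 2 2
#' @export
stratifyBySynapse <- function(sigmaBar) {
  ifelse(!is.na(sigmaBar) & sigmaBar > 0, 1L, 2L)
}

#' One-sided tests used for cohort summaries
#'
#' `synapseTTest`: one-sample t-test of per-sample values against 0 with the
#' one-sided greater alternative. `synapseNullComparison`: one-sided Wilcoxon
#' signed-rank test pairing each sample's observed mean with its null-model
#' value. Zero-variance inputs are reported as degenerate rather than
#' erroring.
#'
#' @param values per-sample statistics (mean sigma or deltaCDF)
#' @return list with `mean`, `p`, `degenerate`
#' @export
synapseTTest <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 samples")
  if (stats::sd(values) == 0)
    return(list(mean = mean(values), p = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(values, mu = 0, alternative = "greater")
  list(mean = mean(values), p = tt$p.value, degenerate = FALSE)
}

#' @rdname synapseTTest
#' @param observed,null paired per-sample observed and null-model values
#' @export
synapseNullComparison <- function(observed, null) {
  ok <- is.finite(observed) & is.finite(null)
  if (sum(ok) < 3L) stop("need at least 3 paired samples")
  d <- observed[ok] - null[ok]
  if (all(d == 0))
    return(list(mean_difference = 0, p = NA_real_, degenerate = TRUE))
  wt <- stats::wilcox.test(observed[ok], null[ok], paired = TRUE,
                           alternative = "greater", exact = FALSE)
  list(mean_difference = mean(d), p = wt$p.value, degenerate = FALSE)
}
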