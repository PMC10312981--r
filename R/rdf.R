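## Radial distribution functions around reference cells, the
## label-permutation expected curve, and the deltaCDF colocalization summary.

#' Exact area of the intersection of a disk with an axis-aligned rectangle
#'
#' Piecewise-analytic: the integral of the clipped vertical extent of the
#' disk is split at the abscissae where the disk boundary crosses the
#' rectangle's horizontal edges, and each piece integrates in closed form.
#'
#' @param cx,cy disk centre
#' @param r disk radius
#' @param window rectangle `c(xmin, xmax, ymin, ymax)`
#' @return intersection area
#' @keywords internal
circleRectArea <- function(cx, cy, r, window) {
  if (r <= 0) return(0)
  x1 <- window[1L] - cx; x2 <- window[2L] - cx
  y1 <- window[3L] - cy; y2 <- window[4L] - cy
  a <- max(x1, -r); b <- min(x2, r)
  if (a >= b) return(0)
  ## antiderivative of sqrt(r^2 - t^2)
  G <- function(t) {
    if (t < -r) t <- -r else if (t > r) t <- r
    (t * sqrt(max(r^2 - t^2, 0)) + r^2 * asin(t / r)) / 2
  }
  breaks <- c(a, b)
  for (y in c(y1, y2)) if (abs(y) < r) {
    t <- sqrt(r^2 - y^2)
    breaks <- c(breaks, -t, t)
  }
  breaks <- breaks[breaks >= a & breaks <= b]
  breaks <- sort(unique(c(a, b, breaks)))
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    if (hi - lo <= 0) next
    m <- (lo + hi) / 2
    s <- sqrt(max(r^2 - m^2, 0))
    top <- min(y2, s); bot <- max(y1, -s)
    if (top <= bot) next
    up <- if (y2 < s) y2 * (hi - lo) else G(hi) - G(lo)
    dn <- if (y1 > -s) y1 * (hi - lo) else -(G(hi) - G(lo))
    total <- total + (up - dn)
  }
  total
}

## fraction of the annulus [r0, r1) around (cx, cy) inside the window
annulusInWindowFraction <- function(cx, cy, r0, r1, window) {
  full <- pi * (r1^2 - r0^2)
  (circleRectArea(cx, cy, r1, window) -
     circleRectArea(cx, cy, r0, window)) / full
}

## per-bin edge-correction weights (1 / in-window fraction) for one cell;
## annuli entirely inside the window get weight 1 without integration
edgeWeights <- function(cx, cy, edges, window) {
  n <- length(edges) - 1L
  w <- rep(1, n)
  dmin <- min(cx - window[1L], window[2L] - cx,
              cy - window[3L], window[4L] - cy)
  need <- which(edges[-1L] > dmin)
  if (!length(need)) return(w)
  ## disk areas at the needed edges, each edge integrated once
  areas <- numeric(length(edges))
  areas[edges <= dmin] <- pi * edges[edges <= dmin]^2
  for (i in which(edges > dmin))
    areas[i] <- circleRectArea(cx, cy, edges[i], window)
  for (b in need) {
    full <- pi * (edges[b + 1L]^2 - edges[b]^2)
    f <- (areas[b + 1L] - areas[b]) / full
    w[b] <- if (f > 0) 1 / f else 0
  }
  w
}

## resolve the rectangular observation window (um) from a cell table
defaultWindow <- function(cellTable) {
  c(0, max(cellTable$x_um), 0, max(cellTable$y_um))
}

#' Radial distribution function of target cells around reference cells
#'
#' For every reference cell, target cells are counted in half-open 1 um (by
#' default) distance bins out to 100 um, the reference itself excluded.
#' Counts are optionally edge-corrected — each cell-bin count is divided by
#' the fraction of the annulus lying inside the rectangular observation
#' window — then summed over reference cells, divided by the number of
#' reference cells, and divided by the full annulus area. The conventional
#' final normalization by overall point density is deliberately omitted, so
#' the curve reads as an absolute target density (cells per um^2) near the
#' reference type.
#'
#' @param cellTable cell table with `x_um`, `y_um`, `types` (and `region`
#'   when `region` is given)
#' @param referenceType,targetType type labels; multi-label cells count when
#'   they hold the label
#' @param config an [AnalysisConfig-class] (`rdfMaxUm`, `rdfBinUm`)
#' @param region restrict *reference* cells to `"intratumor"` or `"stroma"`
#'   (`NULL`: all)
#' @param window rectangle `c(xmin, xmax, ymin, ymax)` in um; default spans
#'   the observed centroids
#' @param edgeCorrection divide counts by the in-window annulus fraction
#'   (recommended for TMA-sized fields; optional for whole slides)
#' @return list with `bin_edges_um`, `observed` (density per um^2 per bin),
#'   `n_ref`, and the call parameters
#' @export
radialDensity <- function(cellTable, referenceType, targetType,
                          config = cisaConfig(), region = NULL,
                          window = NULL, edgeCorrection = TRUE) {
  if (is.null(window)) window <- defaultWindow(cellTable)
  edges <- seq(0, config@rdfMaxUm, by = config@rdfBinUm)
  nbin <- length(edges) - 1L
  isRef <- hasType(cellTable$types, referenceType)
  if (!is.null(region)) isRef <- isRef & cellTable$region == region
  refs <- which(isRef)
  if (!length(refs)) stop("no reference cells",
                          if (!is.null(region)) paste0(" in region '",
                                                       region, "'"))
  isTarget <- hasType(cellTable$types, targetType)
  counts <- numeric(nbin)
  for (i in refs) {
    d <- sqrt((cellTable$x_um - cellTable$x_um[i])^2 +
                (cellTable$y_um - cellTable$y_um[i])^2)
    sel <- isTarget & d < config@rdfMaxUm
    sel[i] <- FALSE
    if (!any(sel)) next
    bin <- findInterval(d[sel], edges, rightmost.closed = FALSE)
    h <- tabulate(bin, nbins = nbin)
    if (edgeCorrection)
      h <- h * edgeWeights(cellTable$x_um[i], cellTable$y_um[i], edges,
                           window)
    counts <- counts + h
  }
  annulus <- pi * (edges[-1L]^2 - edges[-length(edges)]^2)
  list(bin_edges_um = edges,
       observed = counts / length(refs) / annulus,
       n_ref = length(refs),
       reference_type = referenceType, target_type = targetType,
       region = if (is.null(region)) "all" else region,
       edge_correction = edgeCorrection, window = window)
}

#' Label-permutation expected RDF curve
#'
#' For each reference cell, the type labels of all cells within range are
#' permuted uniformly while distances stay fixed — multi-label cells
#' contribute one token per held label, and tokens are shuffled across the
#' neighbor slots — and the binned counts are recollected. The expected
#' curve is the mean over `nPermutations` permutations, normalized exactly
#' like the observed curve. Each permutation conserves the number of target
#' labels within every reference's neighborhood.
#'
#' @inheritParams radialDensity
#' @param seed RNG seed for the permutations; default `config@rngSeed`
#' @return list as [radialDensity()] with `expected` in place of `observed`
#' @export
permutationExpected <- function(cellTable, referenceType, targetType,
                                config = cisaConfig(), region = NULL,
                                window = NULL, edgeCorrection = TRUE,
                                seed = config@rngSeed) {
  if (is.null(window)) window <- defaultWindow(cellTable)
  edges <- seq(0, config@rdfMaxUm, by = config@rdfBinUm)
  nbin <- length(edges) - 1L
  nperm <- config@nPermutations
  isRef <- hasType(cellTable$types, referenceType)
  if (!is.null(region)) isRef <- isRef & cellTable$region == region
  refs <- which(isRef)
  if (!length(refs)) stop("no reference cells")
  typeList <- splitTypes(cellTable$types)
  counts <- numeric(nbin)
  withLocalSeed(seed, {
    for (i in refs) {
      d <- sqrt((cellTable$x_um - cellTable$x_um[i])^2 +
                  (cellTable$y_um - cellTable$y_um[i])^2)
      nb <- which(d < config@rdfMaxUm)
      nb <- nb[nb != i]
      if (!length(nb)) next
      ## expand neighbors to one token per held label; unlabeled cells
      ## contribute an empty token so they can receive a label
      nlab <- lengths(typeList[nb])
      slotOf <- rep(seq_along(nb), pmax(nlab, 1L))
      tokens <- unlist(lapply(typeList[nb], function(t)
        if (length(t)) t else ""), use.names = FALSE)
      slotBin <- findInterval(d[nb], edges, rightmost.closed = FALSE)
      w <- if (edgeCorrection)
        edgeWeights(cellTable$x_um[i], cellTable$y_um[i], edges, window)
      else rep(1, nbin)
      acc <- numeric(nbin)
      for (p in seq_len(nperm)) {
        perm <- tokens[sample.int(length(tokens))]
        hit <- slotOf[perm == targetType]
        if (length(hit))
          acc <- acc + tabulate(slotBin[hit], nbins = nbin) * w
      }
      counts <- counts + acc / nperm
    }
  })
  annulus <- pi * (edges[-1L]^2 - edges[-length(edges)]^2)
  list(bin_edges_um = edges,
       expected = counts / length(refs) / annulus,
       n_ref = length(refs),
       reference_type = referenceType, target_type = targetType,
       region = if (is.null(region)) "all" else region,
       edge_correction = edgeCorrection, window = window,
       n_permutations = nperm)
}

#' deltaCDF colocalization statistic
#'
#' Each curve is normalized to total mass 1 (a pseudo-PDF over distance),
#' cumulated, and the expected CDF is subtracted from the observed CDF bin
#' by bin; deltaCDF is the sum of those differences over all bins. Positive
#' values mean observed target mass sits at shorter distances than the
#' permutation null — colocalization.
#'
#' @param observed,expected per-bin density curves of equal length (from
#'   [radialDensity()] / [permutationExpected()] — the numeric vectors, or
#'   the result lists themselves)
#' @return scalar deltaCDF, or `NA` when either curve has zero total mass
#' @examples
#' deltaCDF(c(1, rep(0, 99)), rep(1, 100))  # all mass in bin 1 vs uniform
#' @export
deltaCDF <- function(observed, expected) {
  if (is.list(observed)) observed <- observed$observed
  if (is.list(expected)) expected <- expected$expected
  stopifnot(length(observed) == length(expected))
  so <- sum(observed); se <- sum(expected)
  if (so <= 0 || se <= 0) return(NA_real_)
  sum(cumsum(observed / so) - cumsum(expected / se))
}

#' Cohort test of per-sample deltaCDF values
#'
#' One-sample t-test against 0 with the one-sided greater alternative.
#' Zero-variance cohorts are flagged degenerate and reported by the sign of
#' their mean.
#'
#' @param values per-sample deltaCDF values (>= 3 finite)
#' @return list with `mean`, `p`, `n`, `degenerate`
#' @export
cohortDeltaCdfTest <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 samples")
  if (stats::sd(values) == 0)
    return(list(mean = mean(values),
                p = if (mean(values) > 0) 0 else 1,
                n = length(values), degenerate = TRUE))
  tt <- stats::t.test(values, mu = 0, alternative = "greater")
  list(mean = mean(values), p = tt$p.value, n = length(values),
       degenerate = FALSE)
}

#' Cell density of a type within a tissue compartment
#'
#' Count of cells of the type assigned to the compartment divided by the
#' compartment mask area, in cells per mm^2.
#'
#' @param cellTable cell table with `types` and `region` (see
#'   [assignRegion()])
#' @param regionMasks a [RegionMasks-class]
#' @param type cell type label
#' @param region `"intratumor"` or `"stroma"`
#' @param pixelSize um per pixel
#' @return cells per mm^2
#' @export
regionDensity <- function(cellTable, regionMasks, type,
                          region = c("intratumor", "stroma"),
                          pixelSize = 1) {
  region <- match.arg(region)
  maskArea <- sum(if (region == "intratumor") tumorMask(regionMasks)
                  else stromaMask(regionMasks))
  if (maskArea == 0) stop("empty ", region, " mask")
  areaMm2 <- maskArea * (pixelSize / 1000)^2
  n <- sum(hasType(cellTable$types, type) & cellTable$region == region)
  n / areaMm2
}
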