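## Adaptive per-sample thresholding: tumor/stroma segmentation from marker
## channels, Multi-Otsu, exact 1-D 2-means cell labeling, and the
## antigen-loaded macrophage call.

#' Gaussian smoothing followed by log2(x + 1)
#'
#' The preprocessing applied to a channel before adaptive thresholding:
#' Gaussian blur (sigma in pixels, kernel truncated at 4 sigma, replicate
#' border handling) followed by the log transform that keeps values
#' nonnegative.
#'
#' @param image a [MarkerImage-class]
#' @param channel marker name
#' @param sigma Gaussian standard deviation in pixels (default 1)
#' @return numeric matrix of smoothed log-intensities
#' @export
preprocessChannel <- function(image, channel, sigma = 1) {
  x <- getChannel(image, channel)
  log2(gaussianSmooth(x, sigma) + 1)
}

## separable Gaussian convolution via EBImage::filter2, replicate borders
gaussianSmooth <- function(x, sigma) {
  radius <- ceiling(4 * sigma)
  g <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  g <- g / sum(g)
  k <- outer(g, g)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

#' Multi-Otsu thresholding (exact)
#'
#' Splits an intensity histogram into `nClasses` classes by maximizing the
#' between-class variance — equivalently, the exact 1-D K-means objective of
#' minimizing within-class variance. Solved by dynamic programming over the
#' distinct values (or a 256-bin histogram when there are more than
#' `maxBins` distinct values), so the optimum is exact, deterministic, and
#' identical to exhaustive search over all threshold tuples. The published
#' segmentation uses 4 classes read as non-tissue background, tissue
#' background, low-intensity foreground and high-intensity foreground.
#'
#' @param values numeric vector (or matrix) of intensities
#' @param nClasses number of classes (default 4)
#' @param maxBins histogram resolution used when `values` has more distinct
#'   values than this (default 256)
#' @return list with `thresholds` (`nClasses - 1` increasing values, each
#'   the midpoint between adjacent class extremes), `classMeans`
#'   (increasing), and `classOf(v)`, a function mapping values to class
#'   index 1..nClasses
#' @export
multiOtsu <- function(values, nClasses = 4L, maxBins = 256L) {
  values <- as.vector(values)
  values <- values[is.finite(values)]
  ux <- sort(unique(values))
  if (length(ux) < nClasses)
    stop("need at least ", nClasses, " distinct values, got ", length(ux))
  if (length(ux) > maxBins) {
    br <- seq(min(values), max(values), length.out = maxBins + 1L)
    bin <- findInterval(values, br, rightmost.closed = TRUE)
    centers <- (br[-1L] + br[-length(br)]) / 2
    w <- tabulate(bin, nbins = maxBins)
    keep <- w > 0
    v <- centers[keep]; w <- w[keep]
  } else {
    v <- ux
    w <- tabulate(match(values, ux), nbins = length(ux))
  }
  n <- length(v)
  W <- cumsum(w); S <- cumsum(w * v); Q <- cumsum(w * v^2)
  csum <- function(x, i, j) x[j] - if (i > 1L) x[i - 1L] else 0
  cost <- function(i, j) {                      # within-class SS of bins i..j
    wi <- csum(W, i, j)
    csum(Q, i, j) - csum(S, i, j)^2 / wi
  }
  ## D[c, j]: best within-class SS splitting bins 1..j into c classes
  D <- matrix(Inf, nClasses, n)
  B <- matrix(0L, nClasses, n)                  # first bin of the last class
  for (j in seq_len(n)) D[1L, j] <- cost(1L, j)
  for (cl in 2L:nClasses) {
    for (j in cl:n) {
      best <- Inf; arg <- 0L
      for (i in cl:j) {
        val <- D[cl - 1L, i - 1L] + cost(i, j)
        if (val < best) { best <- val; arg <- i }
      }
      D[cl, j] <- best; B[cl, j] <- arg
    }
  }
  bounds <- integer(nClasses + 1L)              # class c = bins bounds[c]..bounds[c+1]-1
  bounds[nClasses + 1L] <- n + 1L
  j <- n
  for (cl in nClasses:2L) {
    bounds[cl] <- B[cl, j]
    j <- bounds[cl] - 1L
  }
  bounds[1L] <- 1L
  thresholds <- vapply(2L:nClasses, function(cl)
    (v[bounds[cl] - 1L] + v[bounds[cl]]) / 2, numeric(1L))
  classMeans <- vapply(seq_len(nClasses), function(cl) {
    i <- bounds[cl]; j <- bounds[cl + 1L] - 1L
    csum(S, i, j) / csum(W, i, j)
  }, numeric(1L))
  th <- thresholds
  list(thresholds = thresholds, classMeans = classMeans,
       classOf = function(x) findInterval(x, th) + 1L)
}

#' Binary region mask from a smoothed log channel
#'
#' Thresholds the raster at the mean of the low-intensity-foreground class
#' (3rd of 4 Multi-Otsu classes), then cleans up: morphological closing with
#' a `closingSize` square, filling holes smaller than `minSize` pixels, and
#' removing 8-connected objects smaller than `minSize` pixels.
#'
#' @param raster smoothed log-intensity matrix (see [preprocessChannel()])
#' @param model optional [multiOtsu()] fit on this raster (refitted when
#'   `NULL`)
#' @param closingSize side of the square closing element (default 10)
#' @param minSize holes and objects strictly smaller than this are removed
#'   (default 2500)
#' @return logical matrix (possibly empty, with a warning)
#' @export
regionMaskFromChannel <- function(raster, model = NULL, closingSize = 10L,
                                  minSize = 2500L) {
  if (is.null(model)) model <- multiOtsu(raster, 4L)
  mask <- raster > model$classMeans[3L]
  kern <- matrix(1L, closingSize, closingSize)
  m <- EBImage::erode(EBImage::dilate(mask * 1, kern), kern) > 0
  m <- fillSmallHoles(m, minSize)
  m <- dropSmallObjects(m, minSize)
  if (!any(m)) warning("region mask is empty after cleanup")
  m
}

## fill background components that do not touch the border and are smaller
## than minSize
fillSmallHoles <- function(mask, minSize) {
  bg <- EBImage::bwlabel(!mask)
  edge <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0])
  fill <- setdiff(which(sizes < minSize & sizes > 0), edge)
  mask | matrix(bg %in% fill, nrow(mask), ncol(mask))
}

## drop 8-connected foreground components smaller than minSize
dropSmallObjects <- function(mask, minSize) {
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSize)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

## 8-connected component labeling: 4-connected pass (EBImage::bwlabel) plus
## union-find merging of labels that touch diagonally
label8 <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  merge2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- shiftMat(lab, d[1L], d[2L], fill = 0L)
    touch <- lab > 0L & a > 0L & lab != a
    if (any(touch)) {
      pairs <- unique(cbind(lab[touch], a[touch]))
      for (i in seq_len(nrow(pairs))) merge2(pairs[i, 1L], pairs[i, 2L])
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1L))
  lab[lab > 0L] <- match(root, sort(unique(root)))[lab[lab > 0L]]
  lab
}

#' Tumor and stroma compartments from processed channel masks
#'
#' Tumor is the processed tumor-marker (melanoma) mask; stroma is the
#' processed pan-leukocyte (CD45) mask excluding its intersection with the
#' tumor mask, so immune cells inside tumor nests are separated from
#' stromal ones.
#'
#' @param tumorChannelMask,leukocyteChannelMask logical masks from
#'   [regionMaskFromChannel()]
#' @return a [RegionMasks-class]
#' @export
tumorStroma <- function(tumorChannelMask, leukocyteChannelMask) {
  if (!identical(dim(tumorChannelMask), dim(leukocyteChannelMask)))
    stop("mask shapes differ")
  RegionMasks(tumor = tumorChannelMask,
              stroma = leukocyteChannelMask & !tumorChannelMask)
}

#' Assign cells to tissue compartments
#'
#' By the centroid pixel: `intratumor` when it falls in the tumor mask,
#' else `stroma` when in the stroma mask, else `none`.
#'
#' @param cellTable cell table with `x_um`, `y_um`
#' @param regionMasks a [RegionMasks-class]
#' @param pixelSize um per pixel
#' @return the cell table with its `region` column updated
#' @export
assignRegion <- function(cellTable, regionMasks, pixelSize = 1) {
  tm <- tumorMask(regionMasks); sm <- stromaMask(regionMasks)
  r <- pmin(pmax(floor(cellTable$y_um / pixelSize) + 1L, 1L), nrow(tm))
  c <- pmin(pmax(floor(cellTable$x_um / pixelSize) + 1L, 1L), ncol(tm))
  at <- cbind(r, c)
  cellTable$region <- ifelse(tm[at], "intratumor",
                             ifelse(sm[at], "stroma", "none"))
  cellTable
}

#' Adaptive per-channel cell labeling by exact 1-D 2-means
#'
#' Clusters per-cell log2(mean intensity + 1) into two groups
#' (non-membership / membership) by the exact 2-means optimum — found by
#' scanning every split point of the sorted values, so there is no
#' initialization sensitivity. To limit false positives the decision
#' threshold is the mean of the membership (upper) cluster; cells at or
#' above it are labeled positive.
#'
#' @param cellTable cell table with a `mean_<channel>` column
#' @param channel marker name
#' @param typeLabel label appended to `types` for positive cells (default:
#'   the channel name)
#' @return list with `cellTable` (updated `types`), `threshold` (on the
#'   log2 scale), `positive` (logical vector), `classMeans`
#' @export
classifyCells <- function(cellTable, channel, typeLabel = channel) {
  col <- paste0("mean_", channel)
  if (!col %in% names(cellTable)) stop("missing column ", col)
  v <- log2(cellTable[[col]] + 1)
  if (length(unique(v)) < 2L) {
    warning("all values identical; no cells labeled positive")
    return(list(cellTable = cellTable, threshold = Inf,
                positive = rep(FALSE, nrow(cellTable)),
                classMeans = c(mean(v), NA_real_)))
  }
  km <- twoMeans1d(v)
  threshold <- km$classMeans[2L]
  positive <- v >= threshold
  tl <- splitTypes(cellTable$types)
  tl[positive] <- lapply(tl[positive], function(t) unique(c(t, typeLabel)))
  cellTable$types <- vapply(tl, paste, character(1L), collapse = ";")
  list(cellTable = cellTable, threshold = threshold, positive = positive,
       classMeans = km$classMeans)
}

## exact 1-D 2-means: minimize total within-class SS over all sorted split
## points; ties resolved toward the smallest upper cluster mean (first
## optimal split)
twoMeans1d <- function(v) {
  o <- order(v)
  s <- v[o]
  n <- length(s)
  cs <- cumsum(s); cq <- cumsum(s^2)
  k <- seq_len(n - 1L)
  sse <- (cq[k] - cs[k]^2 / k) +
    ((cq[n] - cq[k]) - (cs[n] - cs[k])^2 / (n - k))
  kbest <- which.min(sse)
  list(split = s[kbest],
       classMeans = c(mean(s[seq_len(kbest)]), mean(s[(kbest + 1L):n])),
       withinSS = sse[kbest])
}

#' Call antigen-loaded macrophages
#'
#' For each macrophage, the cytoplasm is the cell minus its 1-pixel internal
#' membrane boundary; the summary statistic is the upper-quartile average of
#' the tumor-marker signal there — the mean of cytoplasm pixel values at or
#' above their 75th percentile (linear-interpolation convention). A cell is
#' loaded when log2(statistic + 1) reaches the tumor-marker cell-labeling
#' threshold from [classifyCells()]. Cells whose cytoplasm is empty are
#' returned as `NA` and excluded from loaded/unloaded splits.
#'
#' @param image a [MarkerImage-class]
#' @param mask a [LabelMask-class]
#' @param cellTable cell table (`id`, `types`)
#' @param tumorChannel tumor marker (melanoma) channel name
#' @param threshold log2-scale threshold from the tumor channel's
#'   [classifyCells()] fit
#' @param macrophageType label selecting macrophages (default `"CD14"`)
#' @param membraneWidth internal boundary width in pixels (default 1)
#' @return the cell table with logical `loaded` column (`NA` for
#'   non-macrophages and empty-cytoplasm cells) and numeric
#'   `loaded_statistic`
#' @export
callLoadedMacrophages <- function(image, mask, cellTable, tumorChannel,
                                  threshold, macrophageType = "CD14",
                                  membraneWidth = 1L) {
  ch <- getChannel(image, tumorChannel)
  lab <- labelMatrix(mask)
  isMac <- hasType(cellTable$types, macrophageType)
  cellTable$loaded <- NA
  cellTable$loaded_statistic <- NA_real_
  for (i in which(isMac)) {
    cell <- lab == cellTable$id[i]
    cyto <- cytoplasmFromLogical(cell, membraneWidth)
    if (!length(cyto)) next
    stat <- upperQuartileMean(ch[cyto])
    cellTable$loaded_statistic[i] <- stat
    cellTable$loaded[i] <- log2(stat + 1) >= threshold
  }
  cellTable
}

## mean of values at or above their 75th percentile (type-7 quantile)
upperQuartileMean <- function(x) {
  q <- stats::quantile(x, 0.75, type = 7, names = FALSE)
  mean(x[x >= q])
}
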