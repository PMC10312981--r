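## Independent brute-force oracles used across the suite. These deliberately
## use explicit pixel loops and set algebra on (row, col) pairs rather than
## any package internals, so they check the pipeline from the outside.

## sigma by explicit pixel loops over coordinate lists
oracleSigma <- function(channel, contactRC, noncontactRC) {
  sc <- 0
  for (i in seq_len(nrow(contactRC)))
    sc <- sc + channel[contactRC[i, 1L], contactRC[i, 2L]]
  sn <- 0
  for (i in seq_len(nrow(noncontactRC)))
    sn <- sn + channel[noncontactRC[i, 1L], noncontactRC[i, 2L]]
  log2((sc / nrow(contactRC)) / (sn / nrow(noncontactRC)))
}

## linear index -> (row, col) matrix
idxToRC <- function(idx, nr) {
  cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
}

## membrane by definition: cell pixels whose Chebyshev distance to the
## nearest non-cell pixel (image border counts as non-cell) is <= width
oracleMembrane <- function(cellMat, width) {
  nr <- nrow(cellMat); nc <- ncol(cellMat)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!cellMat[r, c]) next
    dmin <- min(r, c, nr - r + 1L, nc - c + 1L)  # distance past the border
    for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!cellMat[rr, cc])
        dmin <- min(dmin, max(abs(rr - r), abs(cc - c)))
    }
    out[r, c] <- dmin <= width
  }
  which(out)
}

## diamond dilation by definition: pixels within L1 distance <= radius of
## any set pixel
oracleDilate <- function(mat, radius) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(FALSE, nr, nc)
  src <- which(mat, arr.ind = TRUE)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (i in seq_len(nrow(src))) {
      if (abs(src[i, 1L] - r) + abs(src[i, 2L] - c) <= radius) {
        out[r, c] <- TRUE
        break
      }
    }
  }
  which(out)
}

## textbook Pearson r from the definition
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## O(n^2) pairwise-distance histogram (no edge correction)
oracleDistanceHist <- function(refXY, targetXY, edges, excludeSelf = TRUE) {
  counts <- numeric(length(edges) - 1L)
  for (i in seq_len(nrow(refXY))) for (j in seq_len(nrow(targetXY))) {
    d <- sqrt(sum((refXY[i, ] - targetXY[j, ])^2))
    if (excludeSelf && d == 0) next
    b <- findInterval(d, edges)
    if (b >= 1L && b <= length(counts) && d < edges[length(edges)])
      counts[b] <- counts[b] + 1
  }
  counts
}

iouMasks <- function(a, b) sum(a & b) / sum(a | b)

## random touching-cell mask: disks rasterized by nearest-centre within
## radius (Voronoi-clipped), so adjacent cells share hard boundaries
randomCellMask <- function(n = 40L, nCells = 4L, rmin = 5, rmax = 9) {
  cx <- runif(nCells, 6, n - 6)
  cy <- runif(nCells, 6, n - 6)
  rad <- runif(nCells, rmin, rmax)
  lab <- matrix(0L, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    d <- sqrt((cy - r)^2 + (cx - c)^2)
    k <- which.min(d)
    if (d[k] <= rad[k]) lab[r, c] <- k
  }
  lab
}
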