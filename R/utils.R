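## Internal pixel-index and morphology helpers.
##
## Rasters are base R matrices indexed [row, col]; pixel sets are integer
## vectors of column-major linear indices. The exported coordinate convention
## is 0-based: x_um = col0 * pixel_size, y_um = row0 * pixel_size.

#' @importFrom stats runif rnorm rpois sd
#' @importFrom utils head
NULL

## shift a logical/numeric matrix by (dr, dc), filling vacated cells
shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

## offsets of the L1 ball (diamond) of given radius, as a 2-column matrix
diamondOffsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(g[abs(g$dr) + abs(g$dc) <= radius, , drop = FALSE])
}

## offsets of the 3x3 square minus centre (8-connectivity)
offsets8 <- cbind(dr = rep(-1:1, times = 3), dc = rep(-1:1, each = 3))[-5, ]

## binary dilation of a logical matrix with an explicit offset set;
## out-of-image territory is background
binDilate <- function(m, offsets) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets)))
    out <- out | shiftMat(m, offsets[i, 1L], offsets[i, 2L], fill = FALSE)
  out
}

## 8-connected binary erosion (3x3 square structuring element), iterated;
## pixels outside the image count as background
binErode8 <- function(m, iterations = 1L) {
  for (k in seq_len(iterations)) {
    out <- m
    for (i in seq_len(nrow(offsets8)))
      out <- out & shiftMat(m, offsets8[i, 1L], offsets8[i, 2L], fill = FALSE)
    m <- out
  }
  m
}

## 8-connected neighbours of linear indices, restricted to the image
neighbors8 <- function(idx, dim) {
  nr <- dim[1L]
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  out <- vector("list", nrow(offsets8))
  for (i in seq_len(nrow(offsets8))) {
    rr <- r + offsets8[i, 1L]; cc <- c + offsets8[i, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= dim[2L]
    out[[i]] <- (cc[ok] - 1L) * nr + rr[ok]
  }
  unique(unlist(out))
}

## adjacency list over a pixel set: for each pixel, which other set members
## are 8-connected neighbours (positions into `idx`)
adjacencyList8 <- function(idx, dim) {
  nr <- dim[1L]
  n <- length(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offsets8))) {
    rr <- r + offsets8[i, 1L]; cc <- c + offsets8[i, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= dim[2L]
    hit <- match((cc[ok] - 1L) * nr + rr[ok], idx)
    keep <- !is.na(hit)
    from <- c(from, which(ok)[keep])
    to <- c(to, hit[keep])
  }
  adj <- rep(list(integer(0)), n)
  if (length(from)) {
    sp <- split(to, from)
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

## evaluate expr under a temporary RNG state seeded with `seed`
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a substream seed below 2^31 from a master seed and stream indices
deriveSeed <- function(master, ...) {
  ks <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

## split ";"-joined type strings into a list of label vectors
splitTypes <- function(types) {
  strsplit(ifelse(is.na(types) | types == "", "", types), ";", fixed = TRUE)
}

## logical: does each ";"-joined type string contain any of `which`
hasType <- function(types, which) {
  vapply(splitTypes(types), function(t) any(t %in% which), logical(1L))
}
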