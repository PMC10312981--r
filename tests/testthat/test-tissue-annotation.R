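test_that("channel preprocessing is Gaussian blur then log2(x+1)", {
  const <- MarkerImage(list(A = matrix(7, 20, 20)))
  expect_equal(preprocessChannel(const, "A"),
               matrix(log2(8), 20, 20), tolerance = 1e-9)
  zero <- MarkerImage(list(A = matrix(0, 10, 10)))
  expect_equal(preprocessChannel(zero, "A"), matrix(0, 10, 10),
               tolerance = 1e-12)
  ## impulse response equals a direct discrete-Gaussian convolution
  imp <- matrix(0, 21, 21); imp[11, 11] <- 100
  got <- cisa:::gaussianSmooth(imp, 1)
  radius <- 4
  g <- exp(-((-radius:radius)^2) / 2); g <- g / sum(g)
  want <- matrix(0, 21, 21)
  for (dr in -radius:radius) for (dc in -radius:radius)
    want[11 + dr, 11 + dc] <- 100 * g[dr + radius + 1] * g[dc + radius + 1]
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("multi-Otsu separates well-separated modes and rejects tiny inputs", {
  v <- rep(c(0, 10, 100, 200), times = c(50, 40, 30, 20))
  fit <- multiOtsu(v, 4)
  expect_true(fit$thresholds[1] > 0 && fit$thresholds[1] < 10)
  expect_true(fit$thresholds[2] > 10 && fit$thresholds[2] < 100)
  expect_true(fit$thresholds[3] > 100 && fit$thresholds[3] < 200)
  expect_equal(fit$classMeans, c(0, 10, 100, 200))
  expect_equal(fit$classOf(c(2, 50, 120, 300)), 1:4)
  expect_error(multiOtsu(rep(c(1, 2), 10), 4), "distinct values")
})

test_that("multi-Otsu equals exhaustive search over all threshold triples", {
  set.seed(71)
  for (i in 1:6) {
    nv <- sample(c(8, 16, 40), 1)
    v <- sort(sample(0:255, nv))
    w <- rpois(nv, runif(nv, 1, 40)) + 1L
    vals <- rep(v, w)
    fit <- multiOtsu(vals, 4)
    ## oracle: maximize between-class variance over all split triples
    W <- cumsum(w); S <- cumsum(as.numeric(w) * v)
    f <- function(i, j) {
      wi <- W[j] - if (i > 1) W[i - 1] else 0
      si <- S[j] - if (i > 1) S[i - 1] else 0
      si^2 / wi
    }
    best <- -Inf; arg <- NULL
    for (a in 1:(nv - 3)) for (b in (a + 1):(nv - 2))
      for (cc in (b + 1):(nv - 1)) {
        obj <- f(1, a) + f(a + 1, b) + f(b + 1, cc) + f(cc + 1, nv)
        if (obj > best) { best <- obj; arg <- c(a, b, cc) }
      }
    expect_equal(fit$thresholds, (v[arg] + v[arg + 1]) / 2)
  }
})

test_that("region mask cleanup honors the object and hole size boundaries", {
  ## object of 2499 px is removed, 2500 px is kept ("fewer than 2500")
  for (sz in c(2499L, 2500L)) {
    m <- matrix(FALSE, 200, 200)
    m[76:125, 76:125] <- TRUE               # 50 x 50 = 2500 px
    if (sz == 2499L) m[125, 125] <- FALSE   # shave one corner
    expect_equal(sum(m), sz)
    out <- cisa:::dropSmallObjects(m, 2500L)
    expect_equal(sum(out), if (sz == 2500L) 2500L else 0L)
  }
  ## hole of 2499 px is filled, 2500 px is not
  for (hole in c(2499L, 2500L)) {
    m <- matrix(TRUE, 300, 300)
    hs <- 50L
    block <- matrix(TRUE, hs, hs)  # 2500
    block[1, 1] <- hole == 2500L
    hmask <- matrix(FALSE, 300, 300)
    hmask[126:(125 + hs), 126:(125 + hs)] <- TRUE
    if (hole == 2499L) hmask[126, 126] <- FALSE
    m[hmask] <- FALSE
    out <- cisa:::fillSmallHoles(m, 2500L)
    if (hole == 2499L) expect_true(all(out)) else
      expect_equal(sum(!out), 2500L)
  }
})

test_that("tumor/stroma masks are disjoint by construction", {
  set.seed(72)
  a <- matrix(runif(400) > 0.5, 20, 20)
  b <- matrix(runif(400) > 0.5, 20, 20)
  rm <- tumorStroma(a, b)
  expect_identical(tumorMask(rm), a)
  expect_identical(stromaMask(rm), b & !a)
  expect_false(any(tumorMask(rm) & stromaMask(rm)))
  expect_true(all(!stromaMask(tumorStroma(a, a))))
  expect_error(tumorStroma(a, matrix(TRUE, 5, 5)), "shapes differ")
})

test_that("cells are assigned to compartments by centroid lookup", {
  tumor <- matrix(FALSE, 50, 50); tumor[1:25, 1:25] <- TRUE
  stroma <- matrix(FALSE, 50, 50); stroma[26:50, ] <- TRUE
  rm <- RegionMasks(tumor, stroma)
  set.seed(73)
  ct <- data.frame(id = 1:100, x_um = runif(100, 0, 49.9),
                   y_um = runif(100, 0, 49.9), types = "T",
                   region = "none")
  got <- assignRegion(ct, rm, pixelSize = 1)
  for (i in 1:100) {
    r <- floor(ct$y_um[i]) + 1; c <- floor(ct$x_um[i]) + 1
    want <- if (tumor[r, c]) "intratumor" else if (stroma[r, c]) "stroma"
            else "none"
    expect_equal(got$region[i], want)
  }
})

test_that("cell labeling uses the exact 2-means split and upper-cluster mean", {
  tab <- data.frame(id = 1:5, types = "",
                    mean_CD3 = 2^c(1, 1, 2, 10, 11) - 1)
  out <- classifyCells(tab, "CD3")
  expect_equal(out$threshold, 10.5)               # mean of {10, 11}
  expect_identical(out$positive, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(hasType(out$cellTable$types, "CD3"),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ## exhaustive split-point oracle on random values
  set.seed(74)
  for (i in 1:10) {
    v <- round(runif(12, 0, 6), 2)
    if (length(unique(v)) < 2) next
    s <- sort(v)
    sse <- sapply(1:11, function(k)
      sum((s[1:k] - mean(s[1:k]))^2) +
        sum((s[(k + 1):12] - mean(s[(k + 1):12]))^2))
    k <- which.min(sse)
    km <- cisa:::twoMeans1d(v)
    expect_equal(km$classMeans[2], mean(s[(k + 1):12]))
  }
  ## two-point and one-outlier edge cases
  t2 <- classifyCells(data.frame(id = 1:2, types = "",
                                 mean_CD3 = 2^c(0, 10) - 1), "CD3")
  expect_equal(t2$threshold, 10)
  expect_identical(t2$positive, c(FALSE, TRUE))
  t3 <- classifyCells(data.frame(id = 1:6, types = "",
                                 mean_CD3 = 2^c(0, 0, 0, 0, 0, 100) - 1),
                      "CD3")
  expect_equal(t3$threshold, 100)
  expect_equal(sum(t3$positive), 1L)
  expect_warning(
    classifyCells(data.frame(id = 1:3, types = "", mean_CD3 = 5), "CD3"),
    "identical")
})

test_that("loaded-macrophage statistic is the upper-quartile average", {
  expect_equal(cisa:::upperQuartileMean(c(0, 0, 0, 0, 4, 4, 4, 4)), 4)
  expect_equal(cisa:::upperQuartileMean(rep(0, 8)), 0)
  set.seed(75)
  x <- runif(37, 0, 50)
  q <- quantile(x, 0.75, type = 7, names = FALSE)
  expect_equal(cisa:::upperQuartileMean(x), mean(sort(x)[sort(x) >= q]))
})

test_that("loaded macrophages are called from cytoplasm signal vs threshold", {
  lab <- matrix(0L, 12, 24)
  lab[2:8, 2:8] <- 1L      # macrophage with loaded cytoplasm
  lab[2:8, 10:16] <- 2L    # macrophage with empty cytoplasm signal
  lab[2:3, 18:19] <- 3L    # tiny macrophage: cytoplasm empty at width 1
  ch <- matrix(0, 12, 24)
  cyto1 <- cisa:::cytoplasmFromLogical(lab == 1L, 1L)
  ch[cyto1] <- 40
  img <- MarkerImage(list(Mel = ch))
  tab <- makeCellTable(LabelMask(lab))
  tab$types <- "CD14"
  out <- callLoadedMacrophages(img, LabelMask(lab), tab, "Mel",
                               threshold = log2(40 + 1) - 0.5)
  expect_identical(out$loaded[1:2], c(TRUE, FALSE))
  expect_true(is.na(out$loaded[3]))
  expect_equal(out$loaded_statistic[1], 40)
})
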