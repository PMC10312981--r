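test_that("single-pair RDF matches the closed-form annulus density", {
  ct <- data.frame(id = 1:2, x_um = c(500, 505.5), y_um = c(500, 500),
                   types = c("T", "B"), region = "none")
  r <- radialDensity(ct, "T", "B", cisaConfig(), window = c(0, 1000, 0, 1000))
  expect_equal(r$observed[6], 1 / (11 * pi), tolerance = 1e-12)
  expect_equal(sum(r$observed[-6]), 0)
  expect_equal(r$n_ref, 1L)
  ## a lone reference of the target type sees nothing (self excluded)
  solo <- data.frame(id = 1, x_um = 500, y_um = 500, types = "T",
                     region = "none")
  expect_equal(sum(radialDensity(solo, "T", "T", cisaConfig(),
                                 window = c(0, 1000, 0, 1000))$observed), 0)
  expect_error(radialDensity(solo, "X", "T", cisaConfig()), "no reference")
})

test_that("per-bin counts equal the brute-force pairwise histogram", {
  set.seed(61)
  ct <- generatePointPattern("poisson", 200, c(0, 1000, 0, 1000),
                             c(T = 0.5, B = 0.5), seed = 61)
  cfg <- cisaConfig()
  r <- radialDensity(ct, "T", "B", cfg, window = c(0, 1000, 0, 1000),
                     edgeCorrection = FALSE)
  refXY <- as.matrix(ct[ct$types == "T", c("x_um", "y_um")])
  tgtXY <- as.matrix(ct[ct$types == "B", c("x_um", "y_um")])
  h <- oracleDistanceHist(refXY, tgtXY, 0:100)
  annulus <- pi * ((1:100)^2 - (0:99)^2)
  expect_equal(r$observed, h / nrow(refXY) / annulus, tolerance = 1e-12)
})

test_that("analytic annulus-in-window fraction matches fine grid integration", {
  win <- c(0, 200, 0, 150)
  gridFrac <- function(cx, cy, r0, r1) {
    ## 0.05-um midpoint grid over the annulus bounding box
    s <- 0.05
    xs <- seq(cx - r1 + s / 2, cx + r1, by = s)
    ys <- seq(cy - r1 + s / 2, cy + r1, by = s)
    g <- expand.grid(x = xs, y = ys)
    d2 <- (g$x - cx)^2 + (g$y - cy)^2
    inA <- d2 >= r0^2 & d2 < r1^2
    inW <- g$x >= win[1] & g$x <= win[2] & g$y >= win[3] & g$y <= win[4]
    sum(inA & inW) / sum(inA)
  }
  cases <- rbind(c(100, 75, 5, 6),    # interior: fraction 1
                 c(3, 75, 5, 6),      # near left edge
                 c(2, 2, 8, 9),       # corner
                 c(199, 149, 10, 11)) # opposite corner
  for (i in seq_len(nrow(cases))) {
    z <- cases[i, ]
    expect_equal(
      cisa:::annulusInWindowFraction(z[1], z[2], z[3], z[4], win),
      gridFrac(z[1], z[2], z[3], z[4]), tolerance = 2e-3)
  }
  expect_equal(cisa:::annulusInWindowFraction(100, 75, 5, 6, win), 1)
})

test_that("permutation expected curve is exact under label symmetry", {
  cfg <- cisaConfig(nPermutations = 50L)
  ## all neighbors already of the target type: expected == observed exactly
  set.seed(62)
  ct <- data.frame(id = 1:8,
                   x_um = runif(8, 450, 550), y_um = runif(8, 450, 550),
                   types = c("T", rep("B", 7)), region = "none")
  obs <- radialDensity(ct, "T", "B", cfg, window = c(0, 1000, 0, 1000))
  exp <- permutationExpected(ct, "T", "B", cfg, window = c(0, 1000, 0, 1000))
  expect_equal(exp$expected, obs$observed, tolerance = 1e-12)
  ## two neighbors, one target label: each bin converges to mass 1/2
  ct2 <- data.frame(id = 1:3, x_um = c(500, 510, 540), y_um = 500,
                    types = c("T", "B", "C"), region = "none")
  cfg2 <- cisaConfig(nPermutations = 4000L)
  exp2 <- permutationExpected(ct2, "T", "B", cfg2,
                              window = c(0, 1000, 0, 1000), seed = 62)
  annulus <- pi * ((1:100)^2 - (0:99)^2)
  mass <- exp2$expected * annulus
  expect_equal(mass[11] + mass[41], 1, tolerance = 1e-12)
  expect_equal(mass[11], 0.5, tolerance = 0.05)
  ## label conservation: total expected mass equals total observed mass
  ct3 <- generatePointPattern("poisson", 300, c(0, 600, 0, 600),
                              c(T = 0.4, B = 0.6), seed = 63)
  cfg3 <- cisaConfig(nPermutations = 20L)
  obs3 <- radialDensity(ct3, "T", "B", cfg3, window = c(0, 600, 0, 600),
                        edgeCorrection = FALSE)
  exp3 <- permutationExpected(ct3, "T", "B", cfg3,
                              window = c(0, 600, 0, 600),
                              edgeCorrection = FALSE, seed = 63)
  expect_equal(sum(exp3$expected * annulus), sum(obs3$observed * annulus),
               tolerance = 1e-9)
})

test_that("deltaCDF matches direct summation and its closed-form cases", {
  expect_equal(deltaCDF(c(1, 1, 1), c(1, 1, 1)), 0)
  ## all observed mass in bin 1 vs uniform over 100 bins: sum(1 - k/100)
  expect_equal(deltaCDF(c(1, rep(0, 99)), rep(1, 100)), 49.5)
  set.seed(64)
  o <- runif(100); e <- runif(100)
  direct <- 0
  co <- cumsum(o / sum(o)); ce <- cumsum(e / sum(e))
  for (k in 1:100) direct <- direct + (co[k] - ce[k])
  expect_equal(deltaCDF(o, e), direct)
  expect_true(abs(deltaCDF(o, e)) <= 100)
  expect_true(is.na(deltaCDF(rep(0, 100), e)))
})

test_that("cohort deltaCDF test is one-sided greater with degeneracy flags", {
  expect_error(cohortDeltaCdfTest(c(1, 2)), "at least 3")
  z <- cohortDeltaCdfTest(c(0, 0, 0))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  pos <- cohortDeltaCdfTest(c(1, 1, 1))
  expect_true(pos$degenerate)
  expect_equal(pos$p, 0)
  set.seed(65)
  v <- rnorm(20, 0.5)
  expect_equal(cohortDeltaCdfTest(v)$p,
               t.test(v, mu = 0, alternative = "greater")$p.value)
})

test_that("region density is count over mask area in mm^2", {
  tumor <- matrix(FALSE, 100, 100); tumor[1:50, 1:50] <- TRUE
  stroma <- matrix(FALSE, 100, 100); stroma[51:100, ] <- TRUE
  rm <- RegionMasks(tumor, stroma)
  ct <- data.frame(id = 1:12, x_um = 1, y_um = 1,
                   types = rep(c("T", "M"), 6),
                   region = rep(c("intratumor", "stroma"), each = 6))
  ## tumor mask: 2500 px at 2 um pixels = 0.01 mm^2; 3 T cells inside
  d <- regionDensity(ct, rm, "T", "intratumor", pixelSize = 2)
  expect_equal(d, 3 / (2500 * 4e-6))
  expect_equal(regionDensity(ct, rm, "X", "stroma", pixelSize = 2), 0)
  empty <- RegionMasks(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5))
  expect_error(regionDensity(ct, empty, "T", "intratumor"), "empty")
})

test_that("clustered patterns give RDF excess below the cluster radius", {
  ct <- generatePointPattern("clustered", lambdaPerMm2 = 60,
                             windowUm = c(0, 1000, 0, 1000),
                             typeProportions = c(T = 1, B = 1),
                             offspringPerParent = 4, clusterRadiusUm = 15,
                             seed = 66)
  cfg <- cisaConfig(nPermutations = 30L)
  obs <- radialDensity(ct, "T", "B", cfg, window = c(0, 1000, 0, 1000))
  ## mean density inside the cluster radius far exceeds the asymptote
  expect_gt(mean(obs$observed[1:15]), 3 * mean(obs$observed[50:100]))
})
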