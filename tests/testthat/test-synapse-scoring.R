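## direct construction of a record from coordinate vectors
recOf <- function(contact, noncontact, ref = 1L, nb = 2L) {
  r <- list(ref_id = ref, neighbor_id = nb)
  r$contact_px <- list(contact)
  r$noncontact_px <- list(noncontact)
  r
}

test_that("sigma is the log2 contact/noncontact mean ratio", {
  ch <- matrix(0, 4, 4)
  ch[1:2] <- 8; ch[3:6] <- 2
  img <- MarkerImage(list(CD3 = ch))
  s <- synapseStrength(img, recOf(1:2, 3:6), "CD3")
  expect_equal(s$sigma, 2)             # log2(8/2)
  expect_equal(s$mode, "standard")
  expect_false(s$excluded)
  ## uniform membrane -> 0
  u <- MarkerImage(list(CD3 = matrix(5, 4, 4)))
  expect_equal(synapseStrength(u, recOf(1:3, 4:9), "CD3")$sigma, 0)
})

test_that("sigma is scale invariant and antisymmetric under set swap", {
  set.seed(21)
  ch <- matrix(runif(64, 1, 10), 8, 8)
  img <- MarkerImage(list(CD3 = ch))
  img3 <- MarkerImage(list(CD3 = ch * 3.7))
  co <- sample(64, 10); nc <- setdiff(sample(64, 30), co)[1:12]
  s <- synapseStrength(img, recOf(co, nc), "CD3")$sigma
  expect_equal(synapseStrength(img3, recOf(co, nc), "CD3")$sigma, s)
  expect_equal(synapseStrength(img, recOf(nc, co), "CD3")$sigma, -s)
})

test_that("IMC zero handling follows the fill-in and zero rules", {
  mk <- function(contactVal, noncontactVal) {
    ch <- matrix(0, 2, 4)
    ch[1:2] <- contactVal; ch[3:6] <- noncontactVal
    MarkerImage(list(CD3 = ch), modality = "imc")
  }
  ## contact 0, noncontact below noise -> sigma = 0 by rule
  s <- synapseStrength(mk(0, 0.5), recOf(1:2, 3:6), "CD3", noise = 1.0)
  expect_equal(s$sigma, 0)
  expect_equal(s$mode, "zero_rule")
  ## contact 0, noncontact above noise -> fill in the contact mean
  s <- synapseStrength(mk(0, 2), recOf(1:2, 3:6), "CD3", noise = 1.0)
  expect_equal(s$sigma, -1)            # log2(1/2)
  expect_equal(s$mode, "imc_noise_adjusted")
  expect_true(s$fillin_contact)
  ## noncontact 0 -> symmetric fill-in, flagged
  s <- synapseStrength(mk(4, 0), recOf(1:2, 3:6), "CD3", noise = 1.0)
  expect_equal(s$sigma, 2)             # log2(4/1)
  expect_true(s$fillin_noncontact)
  ## both positive -> standard even in IMC mode
  s <- synapseStrength(mk(8, 2), recOf(1:2, 3:6), "CD3", noise = 1.0)
  expect_equal(s$sigma, 2)
  expect_equal(s$mode, "standard")
  ## fluorescence mode with a zero mean: excluded, no exception
  f <- MarkerImage(list(CD3 = mk(0, 2)@channels$CD3))
  s <- synapseStrength(f, recOf(1:2, 3:6), "CD3")
  expect_true(s$excluded)
  expect_true(is.na(s$sigma))
})

test_that("noise term pools pixels over all non-reference cells", {
  lab <- matrix(0L, 6, 9)
  lab[2:3, 2:3] <- 1L   # T cell
  lab[2:3, 5:6] <- 2L   # non-T, value 1
  lab[1:4, 8:9] <- 3L   # non-T, value 3, twice the area
  ch <- matrix(0, 6, 9)
  ch[lab == 2L] <- 1; ch[lab == 3L] <- 3
  img <- MarkerImage(list(CD3 = ch), modality = "imc")
  tab <- makeCellTable(LabelMask(lab))
  tab$types <- c("Tcell", "B", "B")[tab$id]
  ## pixel-pooled mean: (4*1 + 8*3)/12
  expect_equal(estimateNoiseTerm(img, LabelMask(lab), tab, "CD3", "Tcell"),
               (4 + 24) / 12)
  ## equal-area case: pooled mean of means
  tab2 <- tab; lab2 <- lab; lab2[1:4, 8:9] <- 0L; lab2[2:3, 8:9] <- 3L
  expect_equal(estimateNoiseTerm(img, LabelMask(lab2), tab2, "CD3", "Tcell"),
               2)
  expect_error(estimateNoiseTerm(img, LabelMask(lab),
                                 within(tab, types <- "Tcell"),
                                 "CD3", "Tcell"),
               "noise term undefined")
})

test_that("seed-and-grow regions are contiguous arcs of the right size", {
  ## ring membrane of a 9x9 square cell, width 1
  lab <- matrix(0L, 11, 11); lab[2:10, 2:10] <- 1L
  mem <- extractMembrane(LabelMask(lab), 1, 1)   # 32-pixel ring
  adj <- cisa:::adjacencyList8(mem, c(11L, 11L))
  set.seed(31)
  for (i in 1:200) {
    reg <- seedAndGrow(mem, c(11L, 11L), 15L, adj)
    expect_length(reg, 15L)
    expect_true(all(reg %in% mem))
    ## contiguity: the region's own adjacency graph is connected
    sub <- cisa:::adjacencyList8(reg, c(11L, 11L))
    seen <- logical(length(reg)); seen[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      nxt <- unlist(sub[queue])
      queue <- nxt[!seen[nxt]]
      seen[queue] <- TRUE
    }
    expect_true(all(seen))
  }
  ## membrane no bigger than the minimum is returned whole
  expect_identical(seedAndGrow(mem, c(11L, 11L), length(mem)), mem)
  expect_identical(seedAndGrow(mem[1:10], c(11L, 11L), 15L), mem[1:10])
})

test_that("null model is 0 on uniform membranes and order independent", {
  sim <- generateTissue(syntheticTissueConfig(
    nPairs = 4L, nSingles = 3L, polarizationFactor = 1, seed = 5L))
  refs <- sim$truth$ref_id
  cfg <- cisaConfig(nullIterations = 3L, rngSeed = 17L)
  nm <- nullSynapseModel(sim$image, sim$mask, refs, cfg)
  expect_equal(nm$null_sigma_bar, 0)   # every ratio is exactly 1
  expect_equal(nm$n_cells, 4L)
  ## scale invariance on polarized membranes
  sim2 <- generateTissue(syntheticTissueConfig(
    nPairs = 4L, nSingles = 3L, polarizationFactor = 2, seed = 5L))
  nm1 <- nullSynapseModel(sim2$image, sim2$mask, sim2$truth$ref_id, cfg)
  img2 <- MarkerImage(lapply(sim2$image@channels, function(m) m * 7),
                      pixelSize = pixelSize(sim2$image))
  nm2 <- nullSynapseModel(img2, sim2$mask, sim2$truth$ref_id, cfg)
  expect_equal(nm1$null_sigma_bar, nm2$null_sigma_bar)
  ## per-(cell, iteration) substreams: reversing cell order changes nothing
  nm3 <- nullSynapseModel(sim2$image, sim2$mask, rev(sim2$truth$ref_id), cfg)
  expect_equal(nm3$null_sigma_bar, nm1$null_sigma_bar)
  expect_error(nullSynapseModel(sim$image, sim$mask, integer(0), cfg),
               "no eligible cells")
})

test_that("aggregation is a group-by mean over non-excluded scores", {
  expect_equal(aggregateSynapse(data.frame(
    sigma = c(1, -1), excluded = FALSE, sample_id = "s",
    marker = "CD3", target_type = "APC"))$sigma_bar, 0)
  one <- aggregateSynapse(data.frame(
    sigma = 0.5, excluded = FALSE, sample_id = "s", marker = "CD3",
    target_type = "APC"))
  expect_equal(one$sigma_bar, 0.5)
  expect_equal(one$n_contacts, 1L)
  set.seed(33)
  scores <- data.frame(
    sigma = rnorm(50),
    excluded = rep(c(FALSE, TRUE), c(45, 5)),
    sample_id = sample(c("a", "b"), 50, TRUE),
    marker = "CD3",
    target_type = sample(c("APC", "B"), 50, TRUE))
  agg <- aggregateSynapse(scores)
  ok <- !scores$excluded
  for (k in seq_len(nrow(agg))) {
    sel <- ok & scores$sample_id == agg$sample_id[k] &
      scores$target_type == agg$target_type[k]
    expect_equal(agg$sigma_bar[k], mean(scores$sigma[sel]))
    expect_equal(agg$n_contacts[k], sum(sel))
  }
})

test_that("patients stratify by strict positivity with no-contact in group 2", {
  expect_identical(stratifyBySynapse(c(0.6, 0, -0.2, NA)),
                   c(1L, 2L, 2L, 2L))
})

test_that("cohort tests handle degenerate variance", {
  expect_error(synapseTTest(c(1, 2)), "at least 3")
  r <- synapseTTest(c(1, 1, 1))
  expect_true(r$degenerate)
  r <- synapseTTest(c(0.5, 1.2, 0.9, 1.4))
  expect_equal(r$p, t.test(c(0.5, 1.2, 0.9, 1.4), mu = 0,
                           alternative = "greater")$p.value)
  w <- synapseNullComparison(c(1, 2, 3, 4), c(0.5, 1, 1.5, 2))
  expect_false(w$degenerate)
  expect_true(w$p < 0.5)
  expect_true(synapseNullComparison(c(1, 2, 3), c(1, 2, 3))$degenerate)
})
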