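table1 <- loadSpeciesSummaryTable()
pairs <- loadSpeciesPairs()

test_that("step-up FDR with Q = 1/(2m) reproduces the published cutoffs", {
  p <- c(2.2e-16, 0.017, 0.018, 0.065, 0.0755, 0.1145)
  fdr <- fdrEvaluate(p)
  expect_equal(fdr$cutoff, (1:6) / 72, tolerance = 1e-12)
  # exactly the three smallest p are significant
  expect_equal(fdr$significant, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  none <- fdrEvaluate(rep(1, 5))
  expect_false(any(none$significant))
  expect_equal(nrow(fdrEvaluate(numeric(0))), 0)
  expect_error(fdrEvaluate(c(0.5, 0)), "p-values")
})

test_that("FDR cutoffs increase with rank and significance is a prefix", {
  set.seed(301)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    p[p == 0] <- 1e-12
    Q <- 1 / (2 * m)
    fdr <- fdrEvaluate(p, Q = Q)
    ord <- order(fdr$rank)
    expect_true(all(diff(fdr$cutoff[ord]) > 0))
    sig <- fdr$significant[ord]
    if (any(sig)) expect_true(all(sig[seq_len(max(which(sig)))]))
    expect_equal(fdr$significant, oracleStepUp(p, Q))
  }
})

test_that("pairwise contrasts from species means match the printed deltas", {
  ct <- pairwiseContrasts(pairs, summaries = table1,
                          pvalues = pairs$published_p)
  expect_equal(ct$delta_printed, c(5.2, 1.6, -1.4, -0.70, -0.70, 0.56))
  expect_equal(ct$significant, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(
    pairwiseContrasts(data.frame(poly = "xxx", mono = "mel"),
                      summaries = table1),
    "unknown species")
})

test_that("per-oocyte contrasts give delta 0 and p 1 on identical samples", {
  meas <- rbind(
    data.frame(species = "a", configuration = "both_out",
               distance_um = c(5, 6, 7, 8)),
    data.frame(species = "b", configuration = "both_out",
               distance_um = c(5, 6, 7, 8)))
  ct <- pairwiseContrasts(data.frame(poly = "a", mono = "b"),
                          measurements = meas)
  expect_equal(ct$delta_um, 0)
  expect_equal(ct$p, 1)
})

test_that("per-oocyte Welch contrasts detect a known group difference", {
  set.seed(77)
  a <- generateSpeciesDataset("a", 400, 1, 8, 1.5, 0.4, 0.1, seed = 10L)
  b <- generateSpeciesDataset("b", 400, 1, 6, 1.5, 0.4, 0.1, seed = 11L)
  meas <- rbind(cbind(species = "a", a), cbind(species = "b", b))
  meas <- meas[meas$configuration %in%
               c("both_out", "one_out_other_locatable"), ]
  ct <- pairwiseContrasts(data.frame(poly = "a", mono = "b"),
                          measurements = meas)
  expect_lt(abs(ct$delta_um - 2), 0.5)
  expect_lt(ct$p, 1e-6)
})

test_that("group means by inversion status match the species table", {
  g <- groupMeanComparison(table1)
  expect_equal(g$nPoly, 7)
  expect_equal(g$nMono, 7)
  expect_equal(round(g$meanPolymorphic, 2), 7.15)
  expect_equal(g$meanMonomorphic, 47.70 / 7, tolerance = 1e-9)
  expect_equal(g$p, 0.75, tolerance = 0.02)
})

test_that("group comparison is symmetric under label swap", {
  flipped <- table1
  flipped$common_inversions <- ifelse(table1$common_inversions == "Yes",
                                      "No", "Yes")
  g1 <- groupMeanComparison(table1)
  g2 <- groupMeanComparison(flipped)
  expect_equal(g2$delta, -g1$delta)
  expect_equal(g2$p, g1$p)
})

test_that("Pearson correlation and regression p behave as published", {
  hc <- pearsonCorrelation(table1$pct_heterochromatin,
                           table1$mean_distance_um)
  expect_equal(hc$n, 9)
  expect_equal(hc$r, 0.279, tolerance = 0.005)
  expect_equal(hc$p, 0.47, tolerance = 0.01)
  # cross-check the t-transform p against cor.test
  ct <- cor.test(table1$pct_heterochromatin, table1$mean_distance_um)
  expect_equal(hc$p, ct$p.value, tolerance = 1e-9)

  expect_equal(pearsonCorrelation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
})

test_that("correlations are invariant under affine rescaling", {
  set.seed(40)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12, sd = 0.4)
  r0 <- pearsonCorrelation(x, y)$r
  expect_equal(pearsonCorrelation(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearsonCorrelation(x, -2 * y + 1)$r, -r0,
               tolerance = 1e-12)
  expect_lte(abs(r0), 1)
})

test_that("pair-averaging preserves perfect correlation and guards input", {
  d <- data.frame(species = letters[1:8],
                  x = 1:8, y = 2 * (1:8) + 3)
  pr <- data.frame(poly = c("a", "c", "e"), mono = c("b", "d", "f"))
  res <- pairAveragedCorrelation(d, "x", "y", pr,
                                 singletons = c("g", "h"))
  expect_equal(res$r, 1)
  expect_equal(res$n, 5)
  bad <- data.frame(poly = c("a", "a"), mono = c("b", "c"))
  expect_error(pairAveragedCorrelation(d, "x", "y", bad),
               "more than one pair")
})

test_that("pairs of identical species reduce to the unpaired correlation", {
  d <- data.frame(species = c("a1", "a2", "b1", "b2", "c"),
                  x = c(4, 4, 9, 9, 6), y = c(1, 1, 7, 7, 3))
  pr <- data.frame(poly = c("a1", "b1"), mono = c("a2", "b2"))
  res <- pairAveragedCorrelation(d, "x", "y", pr, singletons = "c")
  direct <- pearsonCorrelation(c(4, 9, 6), c(1, 7, 3))
  expect_equal(res$r, direct$r)
})

test_that("species summaries aggregate distances, proportions and areas", {
  one <- data.frame(out_flag = TRUE, configuration = "both_out",
                    distance_um = 5, area1_um2 = 0.3, area2_um2 = 0.4)
  s <- suppressWarnings(summarizeSpecies(one, "x"))
  expect_equal(s$mean_distance_um, 5)
  expect_equal(s$proportion_out, 1)
  expect_equal(s$mean_area_um2, 0.35)

  tab <- generateSpeciesDataset("mel", 5000, 0.48, 11.33, 2, 0.85, 0.2,
                                seed = 9L)
  s2 <- summarizeSpecies(tab, "mel")
  expect_lt(abs(s2$mean_distance_um - 11.33),
            3 * 2 / sqrt(s2$n_distance))
  expect_lt(abs(s2$proportion_out - 0.48), 3 * sqrt(0.48 * 0.52 / 5000))
  # same-side rows are excluded from the distance mean but counted out
  expect_lt(s2$n_distance, s2$n_out)
  w <- capture_warnings(summarizeSpecies(one, "x"))
  expect_true(any(grepl("target 30", w)))
  expect_true(any(grepl("target 20", w)))
})

test_that("t-test rejection rate matches theoretical power", {
  n <- 30; delta <- 1; sigma <- 1.5; alpha <- 0.05
  pow <- power.t.test(n = n, delta = delta, sd = sigma,
                      sig.level = alpha)$power
  set.seed(500)
  rej <- 0L; reps <- 600L
  for (i in seq_len(reps)) {
    a <- rnorm(n, 0, sigma); b <- rnorm(n, delta, sigma)
    if (t.test(a, b)$p.value < alpha) rej <- rej + 1L
  }
  rate <- rej / reps
  mcse <- sqrt(pow * (1 - pow) / reps)
  expect_lt(abs(rate - pow), 4 * mcse)
})
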