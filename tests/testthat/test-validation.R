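# Hand-rolled oracles, kept deliberately naive and independent of the
# package (and of the stats:: shortcuts it calls internally).
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
oracle_cv <- function(x) 100 * oracle_sd(x) / (sum(x) / length(x))
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("LLOQD is exactly three baseline standard deviations", {
  set.seed(10)
  for (i in 1:10) {
    ratios <- rnorm(6, 0.003663, runif(1, 1e-5, 5e-4))
    expect_equal(lloqd(ratios), 3 * oracle_sd(ratios) * 100)
  }
  expect_error(lloqd(c(0.003, 0.004)), ">= 3")
  expect_warning(lloqd(rep(0.003663, 5)), "degenerate")
})

test_that("LLOQD reproduces the plasma-urea threshold from its baseline SD", {
  # baseline SD of 0.0384/3 percentage points must yield LLOQD 0.0384%
  target_sd <- 0.0384 / 3 / 100            # ratio units
  base <- 0.003663 + c(-1, 0, 1) * target_sd  # sample SD exactly target_sd
  expect_equal(lloqd(base), 0.0384, tolerance = 1e-12)
})

test_that("precision CV matches the sample-SD oracle", {
  expect_equal(precision_cv(c(10, 10, 10)), 0)
  expect_equal(precision_cv(c(9, 10, 11)), 10)
  set.seed(11)
  for (i in 1:10) {
    x <- runif(sample(3:8, 1), 1, 100)
    expect_equal(precision_cv(x), oracle_cv(x))
  }
  expect_error(precision_cv(c(5)), ">= 2")
  expect_error(precision_cv(c(-1, 1)), "mean is zero")
})

test_that("Monte-Carlo consistency: injected 5% CV is recovered at large n", {
  set.seed(12)
  x <- 0.01 * (1 + rnorm(20000, 0, 0.05))
  expect_equal(precision_cv(x), 5, tolerance = 0.05)
})

test_that("mass accuracy in ppm matches direct evaluation, sign included", {
  expect_equal(mass_accuracy_ppm(61.03964, 61.03964), 0)
  # protonated urea, +0.00009 off the exact monoisotopic mass
  expect_equal(mass_accuracy_ppm(61.03973, 61.03964),
               1e6 * (61.03973 - 61.03964) / 61.03964)
  expect_equal(round(mass_accuracy_ppm(61.03973, 61.03964), 2), 1.47)
  expect_lt(mass_accuracy_ppm(61.03950, 61.03964), 0)
  s <- mass_accuracy_summary(c(-1, 1, 3))
  expect_equal(s$mean, 1)
  expect_equal(s$rms, sqrt(11 / 3))
})

test_that("carry-over is the blank-to-sample percentage", {
  expect_equal(carryover_check(0, 100)$percent, 0)
  expect_true(carryover_check(0, 100)$pass)
  expect_equal(carryover_check(100, 100)$percent, 100)
  expect_false(carryover_check(100, 100)$pass)
  expect_equal(carryover_check(0.5, 100)$percent, 0.5)
  expect_error(carryover_check(1, 0), "> 0")
})

test_that("matrix correlation equals the Pearson oracle with the trivial anchors", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(matrix_correlation(x, x), 1)
  expect_equal(matrix_correlation(x, -2 * x), -1)
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- 0.6 * a + rnorm(20, 0, 0.5)
    expect_equal(matrix_correlation(a, b), oracle_pearson(a, b))
  }
  expect_error(matrix_correlation(x, rep(1, 5)), "zero variance")
})

test_that("shared-truth matrices correlate as the attenuation formula predicts", {
  # plasma = truth + e1, DBS = truth + e2 with independent noise:
  # E[r] = var_t / (var_t + var_e) when both matrices carry equal noise
  set.seed(14)
  truth <- rnorm(4000, 2, 1)
  for (noise_sd in c(0.3, 0.7, 1.2)) {
    r <- matrix_correlation(truth + rnorm(4000, 0, noise_sd),
                            truth + rnorm(4000, 0, noise_sd))
    expect_equal(r, 1 / (1 + noise_sd^2), tolerance = 0.06)
  }
  # attenuation is monotone in the matrix-specific noise
  rs <- vapply(c(0.2, 0.6, 1.0, 1.5), function(s) {
    matrix_correlation(truth + rnorm(4000, 0, s), truth + rnorm(4000, 0, s))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("stability deltas mirror percent change", {
  expect_equal(stability_delta(10, 8.8), -12)
  expect_equal(stability_delta(c(2, 4), c(2, 4)), c(0, 0))
  expect_error(stability_delta(0, 1), "zero reference")
})

test_that("group comparison picks t-test for 2 groups, ANOVA+Tukey beyond", {
  set.seed(15)
  same <- c(rnorm(10, 100, 5), rnorm(10, 100, 5))
  g2 <- rep(c("a", "b"), each = 10)
  res_same <- group_compare(same, g2)
  expect_equal(res_same$method, "t-test")
  expect_false(res_same$significant)

  # 5-SD separation, n = 10 each: power is essentially 1
  sep <- c(rnorm(10, 100, 5), rnorm(10, 125, 5))
  expect_true(group_compare(sep, g2)$significant)

  g3 <- rep(c("a", "b", "c"), each = 8)
  v3 <- c(rnorm(8, 100, 5), rnorm(8, 100, 5), rnorm(8, 130, 5))
  res3 <- group_compare(v3, g3)
  expect_equal(res3$method, "anova+tukey")
  expect_true(res3$significant)
  expect_equal(nrow(res3$pairwise), 3)
  pc <- res3$pairwise
  expect_lt(pc$p_adj[pc$comparison == "c-a"], 0.05)
  expect_gt(pc$p_adj[pc$comparison == "b-a"], 0.05)
  expect_error(group_compare(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("simulated severe cohort has significantly lower RUF than controls", {
  ctrl <- simulate_cohort(10, seed = 21)
  sev <- simulate_cohort(8, preset = disease_preset("CPS1D"), seed = 22)
  pl <- run_pipeline(rbind(ctrl$records, sev$records),
                     rbind(ctrl$subjects, sev$subjects))
  res <- pl$results
  cmp <- group_compare(res$RUF, res$group)
  expect_true(cmp$significant)
  expect_lt(mean(res$RUF[res$group == "CPS1D"]),
            mean(res$RUF[res$group == "CONTROL"]))
})

test_that("validation_report assembles LLOQD, precision and matrix r", {
  set.seed(16)
  base <- expand.grid(metabolite = c("urea", "arginine"),
                      matrix = c("plasma", "DBS"),
                      rep = 1:6, stringsAsFactors = FALSE)
  base$ratio <- 0.003663 * (1 + rnorm(nrow(base), 0, 0.02))
  paired <- data.frame(plasma = rnorm(30, 2, 1))
  paired$dbs <- paired$plasma + rnorm(30, 0, 0.4)
  rep_out <- validation_report(base[, c("metabolite", "matrix", "ratio")],
                               paired)
  expect_equal(nrow(rep_out$lloqd), 4)
  expect_true(all(rep_out$lloqd$lloqd_percent > 0))
  expect_equal(rep_out$matrix_r,
               oracle_pearson(paired$plasma, paired$dbs))
})
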