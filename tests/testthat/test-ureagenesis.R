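test_that("R is the urea-cycle share of the label AUCs", {
  only_urea <- c(urea = 5, citrulline = 0, arginine = 0, glutamine = 0,
                 glycine = 0, glutamate = 0)
  expect_equal(compute_R(only_urea), 1)
  only_gln <- c(urea = 0, citrulline = 0, arginine = 0, glutamine = 3,
                glycine = 0, glutamate = 0)
  expect_equal(compute_R(only_gln), 0)
  mixed <- c(urea = 3, citrulline = 1, arginine = 0.5, glutamine = 4,
             glycine = 1, glutamate = 0.5)
  expect_equal(compute_R(mixed), 0.45)
  expect_error(compute_R(mixed * 0), "denominator")
})

test_that("R is scale-invariant and bounded and honors exclusions", {
  set.seed(3)
  for (i in 1:25) {
    aucs <- setNames(runif(6, 0, 50), assay_metabolites())
    r <- compute_R(aucs)
    expect_gte(r, 0)
    expect_lte(r, 1)
    expect_equal(compute_R(aucs * runif(1, 0.01, 100)), r)
  }
  aucs <- setNames(c(3, 1, 0.5, 4, 1, 0.5), assay_metabolites())
  # excluding glutamine removes it from the denominator only
  expect_equal(compute_R(aucs, setdiff(assay_metabolites(), "glutamine")),
               4.5 / 6)
})

test_that("T accounting: zero curves give 0, matched amounts give 100", {
  zero <- setNames(rep(0, 6), assay_metabolites())
  expect_equal(compute_T(zero, 2, 70), 0)
  # construct AUCs whose implied label amount equals the dose exactly:
  # a flat 100 * dose/pool_amount enrichment over the whole window
  cfg <- assay_config()
  w <- 70
  pool_amt <- cfg$pool_umol_per_L * cfg$v_dist_L_per_kg * w
  share <- setNames(rep(1 / 6, 6), assay_metabolites())
  ie_flat <- 100 * share * dose_umol(2, w) / pool_amt  # percent
  aucs <- ie_flat * 120
  expect_equal(compute_T(aucs, 2, w, cfg$pool_umol_per_L,
                         cfg$v_dist_L_per_kg), 100, tolerance = 1e-9)
  expect_error(compute_T(zero, 0, 70), "dose")
})

test_that("noise-free pipeline recovery equals the designed recovery", {
  pl <- noise_free_reference()
  coh <- simulate_cohort(3, noise = noise_free(), inter_subject_cv = 0,
                         seed = 1)
  expect_equal(pl$results$recovery, coh$subjects$designed_recovery,
               tolerance = 1e-6)
})

test_that("recovery partition sums to one and splits into pathway shares", {
  aucs <- setNames(c(3, 1, 0.5, 4, 1, 0.5), assay_metabolites())
  rec <- tracer_recovery(aucs, 2, 70)
  expect_equal(sum(rec$partition), 1)
  expect_equal(rec$uc_share + rec$alt_share, 1)
  expect_error(tracer_recovery(aucs, 0, 70), "dose")
})

test_that("RUF is 100 at the control means and linear in R*T", {
  ref <- noise_free_reference()$reference
  expect_identical(compute_RUF(ref$R_bar_C, ref$T_bar_C, ref), 100)
  expect_equal(compute_RUF(ref$R_bar_C / 2, ref$T_bar_C, ref), 50)
  expect_equal(compute_RUF(2 * ref$R_bar_C, 3 * ref$T_bar_C, ref), 600)
})

test_that("noise-free RUF increases strictly with residual flux, from 0", {
  rufs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(rf) {
    ruf_for_preset(with_residual_flux(disease_preset("OTCD"), rf))$RUF
  }, numeric(1))
  expect_equal(rufs[1], 0, tolerance = 1e-8)
  expect_true(all(diff(rufs) > 0))
})

test_that("control reference: means, leave-in RUFs and the mean +/- SD band", {
  res <- data.frame(R = c(0.8, 0.8), T = c(50, 50))
  ref <- build_control_reference(res)
  expect_equal(ref$control_rufs, c(100, 100))
  expect_equal(unname(ref$ruf_range), c(100, 100))
  expect_error(build_control_reference(res[1, , drop = FALSE]), ">= 2")

  # synthetic control cohort: mean control RUF within 1% of 100
  coh <- simulate_cohort(22, seed = 1)
  pl <- run_pipeline(coh$records, coh$subjects)
  expect_equal(mean(pl$reference$control_rufs), 100, tolerance = 0.01)
  expect_lt(pl$reference$ruf_range["lower"], pl$reference$ruf_range["upper"])
  # the RUF spread recovers the generator's designed inter-subject spread
  designed_cv <- sd(coh$subjects$designed_recovery) /
    mean(coh$subjects$designed_recovery)
  observed_cv <- sd(pl$reference$control_rufs) / 100
  expect_equal(observed_cv, designed_cv, tolerance = 0.5)
})

test_that("recovery stays within conservation bounds under noise", {
  coh <- simulate_cohort(10, seed = 4)
  pl <- run_pipeline(coh$records, coh$subjects)
  expect_true(all(pl$results$recovery < 100))
  expect_true(all(pl$results$recovery > 0))
})

test_that("pre/post therapy comparison reports the expected deltas", {
  ref <- noise_free_reference()$reference
  pre_preset <- with_residual_flux(disease_preset("OTCD"), 0.05)
  post_preset <- with_residual_flux(disease_preset("OTCD"), 1.0)
  pre <- ruf_for_preset(pre_preset)
  post <- ruf_for_preset(post_preset)

  same <- compare_pre_post(pre, pre)
  expect_equal(same$delta_RUF, 0)
  expect_equal(unname(same$delta_auc), rep(0, 6))

  rep_tx <- compare_pre_post(pre, post)
  expect_gt(rep_tx$delta_RUF, 0)
  # restored flux pulls label out of the alternative pathways
  expect_lt(rep_tx$delta_alt_share, 0)
  expect_lt(rep_tx$delta_auc["glutamine"], 0)

  post_dbs <- post
  post_dbs$matrix <- "DBS"
  expect_warning(compare_pre_post(pre, post_dbs), "matrices")
  pre2 <- pre
  pre2$subject_id <- "other"
  expect_error(compare_pre_post(pre2, post), "same subject")
})

test_that("a persisted reference reproduces the joint-run RUF", {
  pl <- noise_free_reference()
  path <- tempfile(fileext = ".yaml")
  write_control_reference(pl$reference, path)
  ref2 <- read_control_reference(path)
  expect_equal(ref2$R_bar_C, pl$reference$R_bar_C)
  expect_equal(ref2$T_bar_C, pl$reference$T_bar_C)

  coh <- simulate_cohort(2, preset = disease_preset("OTCD"), seed = 9)
  joint_records <- rbind(
    simulate_cohort(3, noise = noise_free(), inter_subject_cv = 0,
                    seed = 1)$records, coh$records)
  joint_subjects <- rbind(
    simulate_cohort(3, noise = noise_free(), inter_subject_cv = 0,
                    seed = 1)$subjects, coh$subjects)
  joint <- run_pipeline(joint_records, joint_subjects)
  alone <- run_pipeline(coh$records, coh$subjects, reference = ref2)
  jr <- joint$results[joint$results$group == "OTCD", ]
  expect_equal(alone$results$RUF, jr$RUF, tolerance = 1e-8)
})
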