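test_that("configuration is validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_patients = 0), "positive count")
  expect_error(simulation_config(tf_zero_prob = 1), "tf_zero_prob")
  expect_error(simulation_config(dla_recovery_beta = c(1, -1)), "Beta")
  expect_error(simulation_config(n_true_dmrs = 10, n_regions = 5), "exceed")
})

test_that("donor arm panel construction: totals, determinism, zero noise", {
  cfg <- simulation_config(seed = 1)
  panel <- simulate_hbd_arm_panel(cfg)
  expect_length(panel, 20)
  totals <- vapply(panel, function(p) sum(p$counts), numeric(1))
  expect_true(all(abs(totals - 5e5) / 5e5 < 0.5))
  expect_true(all(totals >= 90000))
  panel2 <- simulate_hbd_arm_panel(cfg)
  expect_identical(panel, panel2)
  cfg0 <- simulation_config(arm_noise_sd = 0, seed = 2)
  p0 <- simulate_hbd_arm_panel(cfg0)
  props <- attr(p0, "donor_props")
  baseline <- arm_baseline_fractions(cfg0$arms)
  for (i in seq_len(nrow(props))) {
    expect_equal(unname(props[i, ]), unname(baseline), tolerance = 1e-15)
  }
})

test_that("patient arm profile follows the copy-number mixture formula", {
  cfg <- simulation_config(arm_noise_sd = 0, seed = 3)
  baseline <- arm_baseline_fractions(cfg$arms)
  neutral <- stats::setNames(rep(2, length(cfg$arms)), cfg$arms)

  p_tf0 <- simulate_patient_arm_profile(0, neutral, cfg, seed = 3)
  expect_equal(attr(p_tf0, "expected_fractions"), baseline, tolerance = 1e-12)

  # tf = 1 is outside the domain, but a diploid tumor at high tf stays at
  # baseline because the mixture is copy-neutral
  p_dip <- simulate_patient_arm_profile(0.999, neutral, cfg, seed = 3)
  expect_equal(attr(p_dip, "expected_fractions"), baseline, tolerance = 1e-12)

  # tf = 0.5 with a 4-copy arm: expected fraction inflated by (0.5+0.5*2)/norm
  cna <- neutral; cna["1p"] <- 4
  p_amp <- simulate_patient_arm_profile(0.5, cna, cfg, seed = 3)
  w <- baseline * ifelse(names(baseline) == "1p", 0.5 + 0.5 * 2, 1)
  expect_equal(attr(p_amp, "expected_fractions"), w / sum(w), tolerance = 1e-12)
  expect_gt(attr(p_amp, "expected_fractions")[["1p"]], baseline[["1p"]])

  expect_error(simulate_patient_arm_profile(1, neutral, cfg), "\\[0, 1\\)")
  expect_error(simulate_patient_arm_profile(-0.1, neutral, cfg), "\\[0, 1\\)")
})

test_that("methylation generator scales true-DMR means with tumor fraction", {
  cfg <- small_config(nb_dispersion = 0, seed = 4, n_patients = 2)
  m <- simulate_methylation(cfg, tumor_fractions = c(0.5, 0), seed = 4)
  dmr <- attr(m, "true_dmr_ids")
  expect_length(dmr, 40)
  # with tf = 0.5 and effect 3 the expected count in a true DMR is 2x the
  # HBD mean; compare mean ratios over the DMR set (library sizes vary, so
  # normalize by the non-DMR regions first)
  hbd <- m$counts[, m$groups == "HBD", drop = FALSE]
  pat <- m$counts[, "patient_01"]
  other <- setdiff(rownames(m$counts), dmr)
  ratio_dmr <- mean(pat[dmr]) / mean(rowMeans(hbd)[dmr])
  ratio_other <- mean(pat[other]) / mean(rowMeans(hbd)[other])
  expect_equal(ratio_dmr / ratio_other, 2, tolerance = 0.15)
  # a tf = 0 patient shows no DMR enrichment
  pat0 <- m$counts[, "patient_02"]
  r0 <- (mean(pat0[dmr]) / mean(rowMeans(hbd)[dmr])) /
    (mean(pat0[other]) / mean(rowMeans(hbd)[other]))
  expect_equal(r0, 1, tolerance = 0.15)
})

test_that("dmr_effect = 1 is a null generator", {
  cfg <- small_config(dmr_effect = 1, nb_dispersion = 0, seed = 5,
                      n_patients = 3)
  m <- simulate_methylation(cfg, tumor_fractions = c(0.5, 0.4, 0.3), seed = 5)
  dmr <- attr(m, "true_dmr_ids")
  hbd_mean <- rowMeans(m$counts[, m$groups == "HBD"])
  pat <- m$counts[, m$groups == "patient", drop = FALSE]
  other <- setdiff(rownames(m$counts), dmr)
  r <- (mean(pat[dmr, ]) / mean(hbd_mean[dmr])) /
    (mean(pat[other, ]) / mean(hbd_mean[other]))
  expect_equal(r, 1, tolerance = 0.15)
})

test_that("droplet generator matches the Poisson-partition closed form", {
  cfg <- simulation_config(seed = 6)
  a <- simulate_ddpcr(0, 5000, cfg, seed = 6)
  expect_equal(a$mutant_positive, 0)
  # copies = droplets, tf = 0.5: each channel lambda = 0.5,
  # expected positive fraction 1 - exp(-0.5) = 0.3935
  reps <- vapply(1:50, function(i) {
    a <- simulate_ddpcr(0.5, 20000, cfg)
    c(a$mutant_positive, a$wildtype_positive) / a$total_droplets
  }, numeric(2))
  expect_equal(mean(reps), 1 - exp(-0.5), tolerance = 0.01)
  expect_identical(simulate_ddpcr(0.2, 8000, cfg, seed = 9),
                   simulate_ddpcr(0.2, 8000, cfg, seed = 9))
  expect_error(simulate_ddpcr(0.2, -1, cfg), "nonnegative")
})

test_that("CTC/clinical generator couples burden to counts and LDH", {
  cfg <- simulation_config(seed = 7)
  set.seed(7)
  rec0 <- do.call(rbind, lapply(1:30, function(i)
    simulate_ctc_and_clinical(0, cfg)))
  expect_gt(mean(rec0$pb_ctc == 0), 0.9)
  expect_lt(median(rec0$ldh), cfg$ldh_baseline + 50)

  # lossless limit: recovery Beta collapsed at 1
  cfg1 <- simulation_config(dla_recovery_beta = c(1e6, 1e-6), seed = 8)
  set.seed(8)
  rec1 <- do.call(rbind, lapply(1:50, function(i)
    simulate_ctc_and_clinical(300, cfg1)))
  expect_equal(mean(rec1$dla_recovery_true), 1, tolerance = 1e-4)

  # burden-count coupling over a wide volume range
  set.seed(9)
  vols <- exp(runif(50, 0, log(700)))
  counts <- vapply(vols, function(v)
    simulate_ctc_and_clinical(v, cfg)$dla_fcm_ctc, numeric(1))
  expect_gt(suppressWarnings(cor(vols, counts, method = "spearman")), 0)
})

test_that("cohort simulation is seed-deterministic and in printed ranges", {
  cfg <- small_config(seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$ddpcr, c2$ddpcr)
  expect_identical(c1$clinical, c2$clinical)
  tf <- c1$truth$tumor_fractions
  expect_true(all(tf >= 0 & tf < 1))
  expect_true(all(c1$clinical$processed_blood_L >= 2.4 &
                    c1$clinical$processed_blood_L <= 6.8))
  expect_true(all(c1$clinical$product_volume_mL >= 46 &
                    c1$clinical$product_volume_mL <= 121))
  expect_true(all(c1$clinical$ldh >= 0.85 * cfg$ldh_baseline))
  expect_true(all(c1$clinical$tumor_volume_cm3 <= 1000))
})

test_that("explicit tumor-fraction grids are honored", {
  cfg <- small_config(seed = 12)
  tf <- seq(0, 0.5, length.out = 10)
  coh <- simulate_cohort(cfg, tumor_fractions = tf)
  expect_equal(unname(coh$truth$tumor_fractions), tf)
  expect_length(coh$patient_arm_profiles, 10)
})
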