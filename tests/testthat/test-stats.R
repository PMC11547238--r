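test_that("spearman handles monotone, reversed and tied inputs", {
  x <- 1:10
  expect_equal(spearman(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman(x, rev(x))$rho, -1)
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_error(spearman(x, rep(1, 10)), "constant")
  # missing pairs removed pairwise and counted
  res <- spearman(c(x, NA), c(2 * x, 5))
  expect_equal(res$n, 10)
  expect_equal(res$n_removed, 1)
})

test_that("spearman equals brute-force rank-Pearson with ties", {
  set.seed(51)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE) + 0.3 * x
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman(x, y)$rho,
                 cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact branch matches full enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  # rank invariance under monotone scaling
  x <- c(1.2, 3.4, 2.2); y <- c(5.5, 0.1, 9.9, 4.4)
  expect_equal(mann_whitney(x, y), mann_whitney(2 * x, 2 * y))
  # brute-force oracle: all assignments of ranks to group labels
  set.seed(52)
  for (i in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(100, nx + ny)      # no ties
    x <- v[1:nx]; y <- v[-(1:nx)]
    got <- mann_whitney(x, y)
    u_obs <- sum(outer(x, y, ">"))
    combs <- combn(nx + ny, nx)
    u_all <- apply(combs, 2, function(idx) {
      sum(outer(v[idx], v[-idx], ">"))
    })
    # two-sided p: share of assignments at least as extreme as observed
    p_exact <- mean(pmin(u_all, nx * ny - u_all) <=
                      min(u_obs, nx * ny - u_obs))
    expect_equal(got$U, u_obs)
    expect_equal(got$p, p_exact, tolerance = 1e-12)
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  res <- fisher_exact_2x2(5, 0, 0, 5)
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(4, 6, 4, 6)$p, 1)
  expect_warning(z <- fisher_exact_2x2(0, 0, 3, 4), "zero margin")
  expect_equal(z$p, 1)
  # probability-mass oracle over random small tables
  set.seed(53)
  for (i in 1:25) {
    m <- sample(3:15, 1); n <- sample(3:15, 1); k <- sample(1:(m + n - 1), 1)
    a <- sample(max(0, k - n):min(k, m), 1)
    tab <- c(a, m - a, k - a, n - (k - a))
    got <- suppressWarnings(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]))
    supp <- max(0, k - n):min(k, m)
    pr <- dhyper(supp, m, n, k)
    p_oracle <- sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
    expect_equal(got$p, p_oracle, tolerance = 1e-7)
  }
})

test_that("square-root transform is display-only and monotone", {
  expect_equal(sqrt_display(c(0, 4, 9)), c(0, 2, 3))
  expect_error(sqrt_display(-1), "nonnegative")
  set.seed(54)
  x <- rexp(20); y <- rexp(20) + x
  expect_equal(spearman(sqrt_display(x), sqrt_display(y))$rho,
               spearman(x, y)$rho, tolerance = 1e-12)
})

test_that("Simon search reproduces independently enumerated designs", {
  d <- simon_two_stage(0.4, 0.7, 0.05, 0.2, n_max = 60)
  # frozen from an independent brute-force enumeration over all
  # (n1, r1, n, r) with exact binomial convolution
  expect_equal(d$optimal$n, 20)
  expect_equal(d$optimal$n1, 7)
  expect_equal(d$optimal$r1, 3)
  expect_equal(d$optimal$r, 11)
  expect_equal(d$optimal$expected_n_p0, 10.767296, tolerance = 1e-6)
  expect_equal(d$optimal$attained_alpha, 0.04500037, tolerance = 1e-6)
  expect_equal(d$optimal$attained_power, 0.81178844, tolerance = 1e-6)
  expect_equal(d$minimax$n, 18)
  expect_equal(d$minimax$n1, 12)

  d2 <- simon_two_stage(0.05, 0.25, 0.05, 0.2, n_max = 30)
  expect_equal(d2$optimal$r1, 0)
  expect_equal(d2$optimal$n1, 9)
  expect_equal(d2$optimal$r, 2)
  expect_equal(d2$optimal$n, 17)
  expect_equal(d2$optimal$expected_n_p0, 11.958005, tolerance = 1e-6)
})

test_that("returned designs always attain their nominal error bounds", {
  cases <- list(c(0.1, 0.3), c(0.2, 0.4), c(0.3, 0.6))
  for (cs in cases) {
    d <- simon_two_stage(cs[1], cs[2], 0.05, 0.2, n_max = 45)
    for (des in d) {
      expect_lte(des$attained_alpha, 0.05)
      expect_gte(des$attained_power, 0.8)
      expect_true(des$r1 < des$r && des$r <= des$n && des$n1 < des$n)
      expect_gte(des$pet_p0, 0)
      expect_lte(des$expected_n_p0, des$n)
    }
  }
  expect_error(simon_two_stage(0.4, 0.4), "exceed")
  expect_error(simon_two_stage(0.4, 0.41, n_max = 10), "no feasible")
})

test_that("cohort report computes the full statistics panel", {
  set.seed(55)
  n <- 50
  vol <- exp(rnorm(n, log(100), 1))
  tf <- pmin(0.6, vol / 2000 + rexp(n, 50))
  tab <- data.frame(
    patient_id = sprintf("p%02d", 1:n),
    vaf = tf, aneuploidy_score = 50 * tf + rnorm(n, 0, 0.5),
    dmr_score = 100 * tf + rnorm(n, 0, 2),
    ldh = 164 + 0.8 * vol + rnorm(n, 0, 20),
    tumor_volume_cm3 = vol,
    lesion_count = 1 + rpois(n, vol / 60),
    pb_ctc = rpois(n, vol / 150), dla_cs_ctc = rpois(n, vol / 80),
    dla_fcm_ctc = rpois(n, vol / 40),
    mutation_detected = tf > 0.002, aneuploidy_positive = 50 * tf > 3,
    methylation_altered = 100 * tf > 5)
  rep <- cohort_report(tab)
  cors <- rep$correlations
  vl <- cors[cors$marker == "vaf" & cors$clinical == "ldh", ]
  expect_gt(vl$rho, 0)
  expect_lt(vl$p, 0.05)
  expect_equal(nrow(cors), 9)
  expect_equal(nrow(rep$group_tests), 9)
  expect_equal(nrow(rep$platform_tests), 3)
  expect_true(all(c("ctc_PB_CellSearch", "mutation_detected") %in%
                    names(rep$calls)))
})

test_that("an all-null cohort rarely flags significance", {
  flagged <- vapply(1:10, function(i) {
    set.seed(500 + i)
    n <- 20
    tab <- data.frame(
      patient_id = sprintf("p%02d", 1:n),
      vaf = rexp(n, 100), aneuploidy_score = rnorm(n),
      dmr_score = abs(rnorm(n)), ldh = 164 + rnorm(n, 0, 20),
      tumor_volume_cm3 = exp(rnorm(n, log(100), 1)),
      lesion_count = 1 + rpois(n, 2),
      pb_ctc = rpois(n, 0.5), dla_cs_ctc = rpois(n, 1),
      dla_fcm_ctc = rpois(n, 2))
    r <- cohort_report(tab)
    min(c(r$correlations$p, 1), na.rm = TRUE) < 0.05 / 9
  }, logical(1))
  expect_lte(mean(flagged), 0.3)
})

test_that("a single-patient report is produced with not-evaluable tests", {
  tab <- data.frame(patient_id = "p1", vaf = 0.1, aneuploidy_score = 5,
                    dmr_score = 10, ldh = 300, tumor_volume_cm3 = 100,
                    lesion_count = 3, pb_ctc = 1, dla_cs_ctc = 2,
                    dla_fcm_ctc = 4)
  rep <- cohort_report(tab)
  expect_true(all(is.na(rep$correlations$rho)))
  expect_true(all(nzchar(rep$correlations$note)))
  expect_true(all(is.na(rep$group_tests$p)))
})
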