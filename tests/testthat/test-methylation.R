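test_that("digestion QC threshold is inclusive at 20%", {
  expect_true(lpnpi_qc(400000, 2e6))
  expect_false(lpnpi_qc(399999, 2e6))
  expect_true(lpnpi_qc(1900000, 2e6))
  expect_error(lpnpi_qc(1, 0), "positive")
})

test_that("completeness filter applies the 75% rule and the HBD rule", {
  counts <- matrix(50, nrow = 4, ncol = 8,
                   dimnames = list(paste0("r", 1:4),
                                   c(paste0("HBD_0", 1:3),
                                     paste0("patient_0", 1:5))))
  counts["r3", 1:3 + 3] <- 0            # r3: data in 5/8 = 62.5%
  counts["r2", "HBD_01"] <- 0           # r2: data in 7/8 but missing an HBD
  m <- toy_region_matrix(counts)
  f <- filter_regions(m, completeness = 0.75, require_all_hbds = TRUE)
  expect_equal(rownames(f$counts), c("r1", "r4"))
  f2 <- filter_regions(m, completeness = 0.75, require_all_hbds = FALSE)
  expect_equal(rownames(f2$counts), c("r1", "r2", "r4"))  # 7/8 = 87.5% kept

  # exactly 75% is retained (6/8 samples)
  counts3 <- matrix(50, 4, 8, dimnames = dimnames(counts))
  counts3["r1", 7:8] <- 0
  f3 <- filter_regions(toy_region_matrix(counts3))
  expect_true("r1" %in% rownames(f3$counts))

  # all regions complete -> identity
  f4 <- filter_regions(toy_region_matrix(matrix(50, 4, 8,
                                                dimnames = dimnames(counts))))
  expect_equal(rownames(f4$counts), paste0("r", 1:4))
})

test_that("normalization is scale-invariant and hits the CPM closed form", {
  m <- toy_region_matrix()
  n1 <- normalize_counts(m)
  m2 <- m
  m2$counts[, 1] <- m$counts[, 1] * 2L   # doubled library
  m2$lib_size[1] <- m$lib_size[1] * 2
  n2 <- normalize_counts(m2)
  expect_equal(n2[, 1], n1[, 1], tolerance = 1e-12)
  # a count equal to library/1e6 has CPM 1, so log2(1 + 1) = 1
  counts <- matrix(c(1, rep(0, 3)), nrow = 4, ncol = 8,
                   dimnames = dimnames(m$counts))
  mm <- toy_region_matrix(counts)
  mm$lib_size[] <- 1e6
  expect_equal(unname(normalize_counts(mm)["r1", 1]), 1)
  expect_equal(unname(normalize_counts(mm)["r2", 1]), 0)
})

test_that("region z-scores use the donor panel with leave-one-out", {
  counts <- matrix(c(10, 20, 30, 20, 20, 20, 20, 20,
                     rep(20, 24)), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("r", 1:4),
                                   c(paste0("HBD_0", 1:3),
                                     paste0("patient_0", 1:5))))
  m <- toy_region_matrix(counts)
  m$lib_size[] <- 1e6   # make normalized values a fixed transform of counts
  norm <- normalize_counts(m)
  hbd <- paste0("HBD_0", 1:3)
  z <- region_zscores(norm, "patient_01", hbd)
  mu <- mean(norm["r1", hbd]); s <- sd(norm["r1", hbd])
  expect_equal(unname(z["r1"]), (norm["r1", "patient_01"] - mu) / s,
               tolerance = 1e-12)
  # constant regions are excluded
  expect_false("r2" %in% names(z))
  expect_true("r2" %in% attr(z, "excluded"))
  # an extreme donor scored leave-one-out sits further out than with the
  # full panel (its own value no longer drags the mean toward itself)
  z_loo <- region_zscores(norm, "HBD_03", hbd)["r1"]
  others <- norm["r1", c("HBD_01", "HBD_02")]
  expect_equal(unname(z_loo),
               (norm["r1", "HBD_03"] - mean(others)) / sd(others),
               tolerance = 1e-12)
  full_z <- (norm["r1", "HBD_03"] - mean(norm["r1", hbd])) / sd(norm["r1", hbd])
  expect_gt(abs(z_loo), abs(full_z))
})

test_that("squared-sum scores are arithmetic and order-invariant", {
  expect_equal(genome_wide_score(c(r1 = 0, r2 = 0)), 0)
  expect_equal(genome_wide_score(c(r1 = 1, r2 = 2)), 5)
  z <- c(r1 = 2, r2 = -2, r3 = 1, r4 = 5)
  expect_equal(as.numeric(melanoma_score(z, c("r1", "r2", "r3"))), 9)
  expect_equal(as.numeric(melanoma_score(rev(z), c("r3", "r1", "r2"))), 9)
  expect_warning(sc <- melanoma_score(z, c("r1", "missing")), "missing")
  expect_equal(as.numeric(sc), 4)
  expect_equal(attr(sc, "n_regions_used"), 1)
})

test_that("high-ctDNA selection thresholds the aneuploidy score", {
  df <- data.frame(sample_id = c("a", "b", "c"), score = c(2.9, 3.0, 11))
  expect_equal(select_high_ctdna(df), c("b", "c"))
  expect_error(select_high_ctdna(data.frame(sample_id = "a", score = 1)),
               "no high-ctDNA")
})

test_that("donor cutoff matches the closed-form t interval", {
  expect_equal(as.numeric(hbd_cutoff(rep(4, 5))), 4)
  sc <- 1:9
  expect_equal(as.numeric(hbd_cutoff(sc)),
               5 + qt(0.975, 8) * sd(sc) / 3, tolerance = 1e-12)
  expect_equal(as.numeric(hbd_cutoff(sc)), 7.1052, tolerance = 1e-4)
  expect_equal(as.numeric(hbd_cutoff(2 * sc)), 2 * as.numeric(hbd_cutoff(sc)),
               tolerance = 1e-12)
  # prediction interval is wider than the CI of the mean
  expect_gt(as.numeric(hbd_cutoff(sc, mode = "prediction")),
            as.numeric(hbd_cutoff(sc)))
  expect_error(hbd_cutoff(c(1, 2)), "at least 3")
})

test_that("altered call is strict", {
  expect_false(call_altered(5, 5))
  expect_true(call_altered(5 + 1e-9, 5))
})

test_that("moderated t stays finite with zero within-group variance", {
  norm <- matrix(c(1, 1, 1, 5, 5, 5,
                   rnorm(6 * 49, 3, 1)), nrow = 50, byrow = TRUE,
                 dimnames = list(paste0("r", 1:50), paste0("s", 1:6)))
  res <- find_dmrs(norm, paste0("s", 1:3), paste0("s", 4:6), fdr = 0.1)
  all_r <- attr(res, "all_regions")
  t1 <- all_r$t[all_r$region_id == "r1"]
  expect_true(is.finite(t1))
  expect_gt(t1, 0)
  expect_gt(attr(res, "df_prior"), 0)
})

test_that("moderated t agrees with an established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(21)
  norm <- matrix(rnorm(300 * 10, 5, 1), nrow = 300,
                 dimnames = list(paste0("r", 1:300), paste0("s", 1:10)))
  norm[1:20, 6:10] <- norm[1:20, 6:10] + 1.5
  ga <- paste0("s", 1:5); gb <- paste0("s", 6:10)
  res <- attr(find_dmrs(norm, ga, gb, fdr = 0.1), "all_regions")
  design <- cbind(1, rep(0:1, each = 5))
  fit <- limma::eBayes(limma::lmFit(norm, design))
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(find_dmrs(norm, ga, gb), "df_prior"),
               unname(fit$df.prior), tolerance = 1e-4)
})

test_that("null data yields no DMRs in most runs", {
  hits <- vapply(1:10, function(i) {
    set.seed(100 + i)
    norm <- matrix(rnorm(500 * 12, 5, 1), nrow = 500,
                   dimnames = list(paste0("r", 1:500), paste0("s", 1:12)))
    nrow(find_dmrs(norm, paste0("s", 1:6), paste0("s", 7:12), fdr = 0.1))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("spiked DMRs are recovered with controlled FDR", {
  cfg <- simulation_config(n_regions = 5000, n_true_dmrs = 200, seed = 22)
  tf <- runif(7, 0.3, 0.5)
  m <- simulate_methylation(cfg, tumor_fractions = tf, seed = 22)
  truth <- attr(m, "true_dmr_ids")
  norm <- normalize_counts(filter_regions(m))
  hbd <- names(m$groups)[m$groups == "HBD"]
  pats <- names(m$groups)[m$groups == "patient"]
  dmrs <- find_dmrs(norm, hbd, pats, fdr = 0.1)
  recovered <- sum(dmrs$region_id %in% truth)
  expect_gte(recovered, 160)
  expect_lte(1 - recovered / nrow(dmrs), 0.15)
})

test_that("PCA of most-variable regions behaves on structured input", {
  # rank-1 matrix: one component explains everything
  s <- matrix(seq(0, 3, length.out = 8), nrow = 1)
  norm <- matrix(1, 40, 8) + matrix(seq(1, 4, length.out = 40), 40, 1) %*% s
  dimnames(norm) <- list(paste0("r", 1:40), paste0("s", 1:8))
  p <- pca_top_variable(norm, fraction = 0.5, n_components = 2)
  expect_gt(p$explained_variance[1], 0.999)
  expect_equal(nrow(p$coordinates), 8)
  expect_error(pca_top_variable(matrix(1, 4, 4,
                                       dimnames = list(paste0("r", 1:4),
                                                       paste0("s", 1:4)))),
               "constant")
})

test_that("healthy donors and low-tumor patients co-cluster in PCA", {
  cfg <- small_config(seed = 23, n_regions = 1000, n_true_dmrs = 100)
  tf <- c(rep(0, 4), rep(0.4, 4))
  m <- simulate_methylation(cfg, tumor_fractions = tf, seed = 23)
  norm <- normalize_counts(filter_regions(m))
  p <- pca_top_variable(norm, fraction = 0.5, n_components = 2)
  xy <- p$coordinates
  hbd <- grep("^HBD", rownames(xy))
  low <- paste0("patient_0", 1:4); high <- paste0("patient_0", 5:8)
  centroid <- function(ids) colMeans(xy[ids, , drop = FALSE])
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(d(centroid(hbd), centroid(low)),
            d(centroid(hbd), centroid(high)))
})

test_that("full methylation scoring produces donor-calibrated calls", {
  cfg <- small_config(seed = 24, n_regions = 1000, n_true_dmrs = 100)
  tf <- c(rep(0, 3), 0.3, 0.4, 0.5)
  m <- simulate_methylation(cfg, tumor_fractions = tf, seed = 24)
  res <- score_methylation(m, high_ctdna_ids = paste0("patient_0", 4:6))
  expect_true(all(res$scores$genome_wide_z_sum >= 0))
  expect_true(all(res$scores$dmr_score >= 0))
  # high-tumor patients are called altered; most donors are not
  pat_high <- res$scores$altered[res$scores$sample_id %in%
                                   paste0("patient_0", 4:6)]
  expect_true(all(pat_high))
  hbd_rows <- res$scores$group == "HBD"
  expect_lte(sum(res$scores$altered[hbd_rows]), 2)
})
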