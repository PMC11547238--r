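#' Region-by-sample methylation count matrix
#'
#' Container for methylation-dependent restriction-enzyme sequencing counts:
#' an integer matrix of regions x samples, region coordinates restricted to
#' autosomes, a group label per sample (healthy blood donor vs patient) and
#' per-sample library sizes.
#'
#' @param counts Integer matrix, regions in rows, samples in columns;
#'   dimnames required.
#' @param regions `data.frame` with columns `region_id`, `chrom` (1-22),
#'   `start`, `end` (0-based half-open), one row per count row.
#' @param groups Named character vector (`"HBD"` or `"patient"`), one entry
#'   per sample.
#' @param lib_size Optional named per-sample library sizes; defaults to
#'   column sums.
#' @return An object of class `region_count_matrix`.
#' @export
region_count_matrix <- function(counts, regions, groups,
                                lib_size = colSums(counts)) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must carry region and sample dimnames")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!identical(rownames(counts), regions$region_id)) {
    stop("region order in 'counts' and 'regions' must match")
  }
  if (any(regions$start >= regions$end)) {
    bad <- which(regions$start >= regions$end)[1]
    stop("invalid region interval (start >= end) at row ", bad)
  }
  if (!all(regions$chrom %in% 1:22)) {
    stop("regions must lie on autosomes (chrom 1-22)")
  }
  if (!setequal(names(groups), colnames(counts))) {
    stop("'groups' must name every sample in 'counts'")
  }
  if (!all(groups %in% c("HBD", "patient"))) {
    stop("group labels must be 'HBD' or 'patient'")
  }
  structure(
    list(counts = counts, regions = regions,
         groups = groups[colnames(counts)],
         lib_size = lib_size[colnames(counts)]),
    class = "region_count_matrix"
  )
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat("<region_count_matrix>", nrow(x$counts), "regions x",
      ncol(x$counts), "samples (", sum(x$groups == "HBD"), "HBD /",
      sum(x$groups == "patient"), "patient )\n")
  invisible(x)
}

#' Restriction-digestion QC on read-filter pass rate
#'
#' A methylation library is considered failed when fewer than 20% of the
#' first two million inspected reads pass the methylation-dependent
#' restriction-enzyme filter (a signature of failed digestion).
#'
#' @param reads_passing_filter Reads passing the enzyme filter.
#' @param reads_inspected Reads inspected (default 2,000,000).
#' @param min_fraction Minimum pass fraction (inclusive).
#' @return `TRUE` if the library passes QC.
#' @export
lpnpi_qc <- function(reads_passing_filter, reads_inspected = 2e6,
                     min_fraction = 0.20) {
  if (reads_inspected <= 0) stop("reads_inspected must be positive")
  reads_passing_filter / reads_inspected >= min_fraction
}

#' Region completeness filter
#'
#' Retains regions with data (a nonzero count) in at least a given fraction
#' of all samples and, by default, in every healthy-donor control. Region
#' order is preserved.
#'
#' @param m A [region_count_matrix()].
#' @param completeness Minimum fraction of all samples with data (inclusive).
#' @param require_all_hbds Additionally require data in every HBD column.
#' @return A filtered [region_count_matrix()].
#' @export
filter_regions <- function(m, completeness = 0.75, require_all_hbds = TRUE) {
  stopifnot(inherits(m, "region_count_matrix"))
  if (!any(m$groups == "HBD") || !any(m$groups == "patient")) {
    stop("matrix must contain at least one HBD and one patient sample")
  }
  has_data <- m$counts > 0
  keep <- rowMeans(has_data) >= completeness
  if (require_all_hbds) {
    keep <- keep & rowSums(!has_data[, m$groups == "HBD", drop = FALSE]) == 0
  }
  if (!any(keep)) stop("no regions retained by the completeness filter")
  region_count_matrix(m$counts[keep, , drop = FALSE],
                      m$regions[keep, , drop = FALSE],
                      m$groups, m$lib_size)
}

#' Library-size normalization
#'
#' Scales counts to counts-per-million using the stored library sizes, then
#' applies `log2(x + 1)`. Two samples with proportional counts map to
#' identical profiles.
#'
#' @param m A [region_count_matrix()].
#' @return Numeric matrix (regions x samples) of log2 CPM values, with the
#'   input's `groups` attached as attribute `"groups"`.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "region_count_matrix"))
  if (any(m$lib_size <= 0)) stop("library sizes must be positive")
  cpm <- sweep(m$counts, 2, m$lib_size / 1e6, "/")
  out <- log2(cpm + 1)
  attr(out, "groups") <- m$groups
  out
}

# HBD mean/SD per region with optional leave-one-out.
hbd_region_stats <- function(norm, hbd_ids, leave_out = NULL) {
  use <- setdiff(hbd_ids, leave_out)
  if (length(use) < 2) stop("need at least 2 HBDs after leave-one-out")
  x <- norm[, use, drop = FALSE]
  mu <- rowMeans(x)
  sigma <- apply(x, 1, stats::sd)
  list(mu = mu, sigma = sigma)
}

#' Per-region z-scores against the healthy-donor panel
#'
#' z_r = (x_r - mu_r) / sigma_r on normalized values, with mu/sigma from the
#' HBD columns. When the scored sample is itself an HBD, leave-one-out panel
#' statistics are used. Regions with zero panel SD are excluded; their ids
#' are attached as attribute `"excluded"`.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param sample_id Column to score.
#' @param hbd_ids Character vector of HBD column names (>= 3).
#' @return Named numeric z-score vector over usable regions.
#' @export
region_zscores <- function(norm, sample_id, hbd_ids) {
  if (length(hbd_ids) < 3) stop("need at least 3 HBDs in the panel")
  if (!sample_id %in% colnames(norm)) stop("unknown sample: ", sample_id)
  loo <- if (sample_id %in% hbd_ids) sample_id else NULL
  st <- hbd_region_stats(norm, hbd_ids, leave_out = loo)
  usable <- st$sigma > 0
  if (!any(usable)) stop("degenerate panel: all regions have zero SD")
  z <- (norm[usable, sample_id] - st$mu[usable]) / st$sigma[usable]
  attr(z, "excluded") <- rownames(norm)[!usable]
  z
}

#' Genome-wide methylation score
#'
#' Sum of squared per-region z-scores over all retained regions.
#'
#' @param z Z-score vector from [region_zscores()].
#' @return Nonnegative scalar.
#' @export
genome_wide_score <- function(z) sum(z^2)

#' Select high-ctDNA patients by aneuploidy score
#'
#' The differential-methylation contrast is defined against patients whose
#' cfDNA demonstrably carries tumor signal, selected as aneuploidy score >=
#' `min_score`.
#'
#' @param aneuploidy `data.frame` from [score_aneuploidy()] (columns
#'   `sample_id`, `score`).
#' @param min_score Selection threshold (inclusive, default 3).
#' @return Character vector of selected sample ids.
#' @export
select_high_ctdna <- function(aneuploidy, min_score = 3) {
  sel <- aneuploidy$sample_id[!is.na(aneuploidy$score) &
                                aneuploidy$score >= min_score]
  if (length(sel) == 0) {
    stop("no high-ctDNA patients (aneuploidy score >= ", min_score,
         "); differential methylation cannot be run")
  }
  sel
}

# Newton inversion of the trigamma function (monotone decreasing on (0,Inf)).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy)) return(NA_real_)
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

# Empirical-Bayes squeeze of region-wise variances: the ensemble of sample
# variances s^2 (df d) is modeled as scaled-F around a prior variance s0^2
# with prior df d0, estimated by moment matching on log variances.
squeeze_variances <- function(s2, df) {
  med <- stats::median(s2)
  if (!is.finite(med) || med <= 0 || length(s2) < 2) return(NULL)
  # zero variances carry no information about the prior; offset them away
  # from zero for estimation only
  s2e <- pmax(s2, 1e-5 * med)
  e <- log(s2e) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  t2 <- evar - trigamma(df / 2)
  if (!is.finite(t2)) return(NULL)
  if (t2 > 0) {
    d0 <- 2 * trigamma_inverse(t2)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2e)
  }
  post <- if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df) else rep(s02, length(s2))
  list(df_prior = d0, var_prior = s02, var_post = post)
}

#' Differentially methylated region discovery (moderated t)
#'
#' Two-group comparison of normalized methylation values with
#' empirical-Bayes variance moderation: region-wise pooled variances are
#' shrunk toward a prior variance whose weight (prior degrees of freedom)
#' is estimated from the ensemble of region variances by moment matching on
#' log variances; the moderated t-statistic is referred to a t distribution
#' with augmented degrees of freedom and p-values are Benjamini-Hochberg
#' adjusted. Regions with adjusted p below `fdr` form the DMR set. If the
#' variance ensemble is degenerate the function falls back to the ordinary
#' t-test with a warning.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param group_a,group_b Column ids of the two groups (each >= 3 samples);
#'   conventionally A = healthy donors, B = high-ctDNA patients. Effects are
#'   reported as B minus A.
#' @param fdr FDR threshold for DMR membership.
#' @return `data.frame` of the DMR set (columns `region_id`, `logfc`, `t`,
#'   `p`, `q`) sorted by `q`, with the full per-region table as attribute
#'   `"all_regions"` and the prior df/variance as attributes.
#' @export
find_dmrs <- function(norm, group_a, group_b, fdr = 0.10) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("both groups need at least 3 samples")
  }
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var)
  vb <- apply(xb, 1, stats::var)
  df <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df
  sq <- squeeze_variances(s2, df)
  if (is.null(sq)) {
    warning("degenerate variance ensemble; falling back to ordinary t")
    sq <- list(df_prior = 0, var_prior = NA_real_, var_post = s2)
  }
  se <- sqrt(sq$var_post * (1 / na + 1 / nb))
  logfc <- mb - ma
  tstat <- logfc / se
  # total df capped at the pooled residual df across regions
  df_total <- min(df + sq$df_prior, df * nrow(norm))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- stats::p.adjust(p, method = "BH")
  all_regions <- data.frame(region_id = rownames(norm), logfc = logfc,
                            t = tstat, p = p, q = q,
                            stringsAsFactors = FALSE, row.names = NULL)
  out <- all_regions[!is.na(q) & q < fdr, , drop = FALSE]
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_regions") <- all_regions
  attr(out, "fdr_threshold") <- fdr
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  out
}

#' Melanoma-specific methylation score
#'
#' Sum of squared z-scores restricted to the DMR set. DMR regions missing
#' from the z-score vector (e.g. excluded as zero-SD) are dropped with a
#' warning; the number used is attached as attribute `"n_regions_used"`.
#'
#' @param z Z-score vector from [region_zscores()].
#' @param dmr_ids Character vector of DMR region ids (or a [find_dmrs()]
#'   result, whose `region_id` column is used).
#' @return Nonnegative scalar.
#' @export
melanoma_score <- function(z, dmr_ids) {
  if (is.data.frame(dmr_ids)) dmr_ids <- dmr_ids$region_id
  present <- dmr_ids %in% names(z)
  if (!all(present)) {
    warning(sum(!present), " DMR region(s) missing from z-scores; excluded")
  }
  out <- sum(z[dmr_ids[present]]^2)
  attr(out, "n_regions_used") <- sum(present)
  out
}

#' Healthy-donor score cutoff
#'
#' Upper limit of the confidence interval of the mean healthy-donor score:
#' `mean + t_{(1+level)/2, n-1} * SD / sqrt(n)`. A prediction-interval
#' variant (`mode = "prediction"`, `mean + t * SD * sqrt(1 + 1/n)`) is the
#' defensible alternative when the cutoff is meant to bound a new donor's
#' score rather than the donor mean.
#'
#' @param hbd_scores Numeric vector of donor scores (>= 3).
#' @param level Confidence level (default 0.95).
#' @param mode `"ci_mean"` (default) or `"prediction"`.
#' @return The cutoff, with the inputs echoed in attribute `"inputs"`.
#' @export
hbd_cutoff <- function(hbd_scores, level = 0.95,
                       mode = c("ci_mean", "prediction")) {
  mode <- match.arg(mode)
  n <- length(hbd_scores)
  if (n < 3) stop("need at least 3 donor scores")
  m <- mean(hbd_scores)
  s <- stats::sd(hbd_scores)
  tq <- stats::qt((1 + level) / 2, df = n - 1)
  cut <- if (mode == "ci_mean") m + tq * s / sqrt(n)
         else m + tq * s * sqrt(1 + 1 / n)
  attr(cut, "inputs") <- list(scores = hbd_scores, level = level, mode = mode)
  cut
}

#' Altered-methylation call
#'
#' A sample's melanoma-specific methylation is called altered when its score
#' strictly exceeds the healthy-donor cutoff.
#'
#' @param dmr_score Sample score from [melanoma_score()].
#' @param cutoff Cutoff from [hbd_cutoff()] on donor leave-one-out scores.
#' @return Logical.
#' @export
call_altered <- function(dmr_score, cutoff) as.numeric(dmr_score) > as.numeric(cutoff)

#' Principal component analysis of the most variable regions
#'
#' Regions are ranked by variance of normalized values across all samples;
#' the top fraction is kept, values are centered per region, and sample
#' coordinates are computed by singular value decomposition.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param fraction Fraction of most-variable regions to keep (default 0.5).
#' @param n_components Number of components to return.
#' @return List with `coordinates` (samples x components),
#'   `explained_variance` (ratios) and `regions_used`.
#' @export
pca_top_variable <- function(norm, fraction = 0.50, n_components = 3) {
  if (ncol(norm) < 3) stop("need at least 3 samples")
  v <- apply(norm, 1, stats::var)
  if (all(v == 0)) stop("constant matrix: no variable regions")
  n_keep <- max(1, floor(fraction * nrow(norm)))
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  x <- t(norm[keep, , drop = FALSE])        # samples x regions
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(coords) <- colnames(norm)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       regions_used = rownames(norm)[keep])
}

#' Full methylation scoring of a cohort
#'
#' Filters regions, normalizes, discovers DMRs (healthy donors vs
#' high-ctDNA patients), computes per-sample genome-wide and
#' melanoma-specific scores (leave-one-out for donors), derives the donor
#' cutoff and calls altered samples.
#'
#' @param m A [region_count_matrix()].
#' @param high_ctdna_ids Patient ids defining the DMR contrast (from
#'   [select_high_ctdna()]).
#' @param fdr DMR FDR threshold.
#' @param completeness Region completeness threshold.
#' @param cutoff_mode Passed to [hbd_cutoff()].
#' @param level Confidence level of the donor cutoff.
#' @return List with `scores` (per-sample `data.frame`), `dmrs`, `cutoff`,
#'   `pca`, `filtered` (the filtered matrix).
#' @export
score_methylation <- function(m, high_ctdna_ids, fdr = 0.10,
                              completeness = 0.75,
                              cutoff_mode = "ci_mean", level = 0.95) {
  stopifnot(inherits(m, "region_count_matrix"))
  mf <- filter_regions(m, completeness = completeness)
  norm <- normalize_counts(mf)
  hbd_ids <- names(mf$groups)[mf$groups == "HBD"]
  missing_sel <- setdiff(high_ctdna_ids, colnames(norm))
  if (length(missing_sel) > 0) {
    stop("high-ctDNA sample(s) absent from the methylation matrix: ",
         paste(missing_sel, collapse = ", "))
  }
  dmrs <- find_dmrs(norm, group_a = hbd_ids, group_b = high_ctdna_ids,
                    fdr = fdr)
  if (nrow(dmrs) == 0) {
    warning("no DMRs at FDR ", fdr, "; melanoma-specific scores are zero")
  }
  zs <- lapply(colnames(norm), function(id) region_zscores(norm, id, hbd_ids))
  names(zs) <- colnames(norm)
  gw <- vapply(zs, genome_wide_score, numeric(1))
  dmr_sc <- vapply(zs, function(z) as.numeric(melanoma_score(z, dmrs$region_id)),
                   numeric(1))
  cutoff <- hbd_cutoff(dmr_sc[hbd_ids], level = level, mode = cutoff_mode)
  scores <- data.frame(
    sample_id = colnames(norm),
    group = unname(mf$groups[colnames(norm)]),
    genome_wide_z_sum = unname(gw),
    dmr_score = unname(dmr_sc),
    altered = unname(vapply(dmr_sc, call_altered, logical(1), cutoff = cutoff)),
    qc_pass = TRUE,
    stringsAsFactors = FALSE
  )
  list(scores = scores, dmrs = dmrs, cutoff = cutoff,
       pca = pca_top_variable(norm), filtered = mf)
}
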