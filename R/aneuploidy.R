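#' Arm-level read-count profile for one sample
#'
#' Container for the per-chromosome-arm read counts of a single cfDNA sample,
#' the unit of input for aneuploidy scoring.
#'
#' @param sample_id Sample identifier.
#' @param counts Named integer vector of read counts, names are arm
#'   identifiers such as `"1p"`.
#' @param total_mapped_reads Total mapped reads for the sample; defaults to
#'   `sum(counts)`. Must be at least `sum(counts)`.
#' @return An object of class `arm_count_profile`.
#' @export
arm_count_profile <- function(sample_id, counts,
                              total_mapped_reads = sum(counts)) {
  if (is.null(names(counts)) || anyNA(names(counts))) {
    stop("'counts' must be a named vector of arm counts")
  }
  if (any(counts < 0) || anyNA(counts)) stop("arm counts must be nonnegative")
  if (total_mapped_reads < sum(counts)) {
    stop("total_mapped_reads cannot be smaller than the sum of arm counts")
  }
  structure(
    list(sample_id = as.character(sample_id),
         counts = counts,
         total_mapped_reads = as.numeric(total_mapped_reads)),
    class = "arm_count_profile"
  )
}

#' @export
print.arm_count_profile <- function(x, ...) {
  cat("<arm_count_profile>", x$sample_id, "-", length(x$counts), "arms,",
      format(x$total_mapped_reads, big.mark = ","), "mapped reads\n")
  invisible(x)
}

#' Mapped-read depth QC
#'
#' A sample is evaluable for aneuploidy scoring only when it has sufficient
#' mapped reads; the assay's validated minimum is 90,000.
#'
#' @param profile An [arm_count_profile()].
#' @param threshold Minimum total mapped reads (inclusive).
#' @return `TRUE` if the profile passes QC.
#' @export
qc_mapped_reads <- function(profile, threshold = 90000) {
  stopifnot(inherits(profile, "arm_count_profile"))
  profile$total_mapped_reads >= threshold
}

#' Normalized arm fractions
#'
#' @param profile An [arm_count_profile()].
#' @return Named numeric vector of per-arm read fractions (summing to 1).
#' @export
arm_fractions <- function(profile) {
  stopifnot(inherits(profile, "arm_count_profile"))
  tot <- sum(profile$counts)
  if (tot <= 0) stop("empty profile: all arm counts are zero")
  profile$counts / tot
}

#' Build a healthy-blood-donor reference panel
#'
#' Computes per-arm mean and sample SD (divisor n-1) of arm fractions across
#' donor profiles. Member fraction vectors are retained to support
#' leave-one-out scoring and the score-normalization step. Arms whose panel
#' SD is zero are flagged unusable and excluded from scoring.
#'
#' @param profiles List of [arm_count_profile()] objects, all QC-passing.
#' @param qc_threshold Mapped-read threshold applied to each member.
#' @return An object of class `ref_panel` with fields `member_ids`,
#'   `fractions` (members x arms matrix), `mu`, `sigma`, `usable`.
#' @export
build_panel <- function(profiles, qc_threshold = 90000) {
  if (length(profiles) < 3) {
    stop("insufficient panel: at least 3 donor profiles are required")
  }
  ok <- vapply(profiles, qc_mapped_reads, logical(1), threshold = qc_threshold)
  if (!all(ok)) {
    stop("panel members failing read QC: ",
         paste(vapply(profiles[!ok], `[[`, "", "sample_id"), collapse = ", "))
  }
  arms <- names(profiles[[1]]$counts)
  frac <- t(vapply(profiles, function(p) arm_fractions(p)[arms], numeric(length(arms))))
  rownames(frac) <- vapply(profiles, `[[`, "", "sample_id")
  colnames(frac) <- arms
  mu <- colMeans(frac)
  sigma <- apply(frac, 2, stats::sd)
  structure(
    list(member_ids = rownames(frac), fractions = frac,
         mu = mu, sigma = sigma, usable = sigma > 0),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel>", length(x$member_ids), "donors,",
      sum(x$usable), "of", length(x$usable), "arms usable\n")
  invisible(x)
}

# Panel statistics with one member held out; used whenever a member is scored
# against a panel containing itself.
panel_loo_stats <- function(panel, member_id) {
  keep <- panel$member_ids != member_id
  if (sum(keep) < 2) stop("leave-one-out panel too small")
  frac <- panel$fractions[keep, , drop = FALSE]
  mu <- colMeans(frac)
  sigma <- apply(frac, 2, stats::sd)
  list(mu = mu, sigma = sigma, usable = sigma > 0)
}

#' Per-arm z-scores against a reference panel
#'
#' z = (fraction - panel mean) / panel SD per arm. If the sample is itself a
#' panel member, leave-one-out panel statistics are used so that the sample
#' does not deflate its own reference. Unusable (zero-SD) arms are excluded;
#' their identifiers are attached as attribute `"excluded"`.
#'
#' @param profile An [arm_count_profile()].
#' @param panel A [build_panel()] result.
#' @return Named numeric vector of z-scores over usable arms.
#' @export
arm_zscores <- function(profile, panel) {
  stopifnot(inherits(profile, "arm_count_profile"), inherits(panel, "ref_panel"))
  st <- if (profile$sample_id %in% panel$member_ids) {
    panel_loo_stats(panel, profile$sample_id)
  } else {
    panel[c("mu", "sigma", "usable")]
  }
  frac <- arm_fractions(profile)
  arms <- names(st$mu)[st$usable]
  z <- (frac[arms] - st$mu[arms]) / st$sigma[arms]
  attr(z, "excluded") <- names(st$mu)[!st$usable]
  z
}

# Leave-one-out raw squared-sum for every panel member. These null sums are
# the reference distribution that turns a raw squared z sum into a
# control-normalized score.
panel_loo_raw_sums <- function(panel) {
  vapply(panel$member_ids, function(id) {
    st <- panel_loo_stats(panel, id)
    arms <- names(st$mu)[st$usable]
    frac <- panel$fractions[id, arms]
    sum(((frac - st$mu[arms]) / st$sigma[arms])^2)
  }, numeric(1))
}

#' Genome-wide aneuploidy score
#'
#' The raw statistic is the sum of squared arm z-scores. Its null expectation
#' grows with the number of arms (~39), so the reported aneuploidy score is
#' the raw sum re-expressed as a z-score against the leave-one-out raw sums
#' of the reference-panel members; under the null it is centred near 0 with
#' unit scale, which is what makes a positivity cutoff of 3 meaningful.
#'
#' @param arm_z Named z-score vector from [arm_zscores()].
#' @param panel The [build_panel()] panel the z-scores were computed against.
#' @param min_arms Minimum number of usable arms for a reliable score.
#' @return List with `raw_sum` (sum of squared z) and `score`
#'   (control-normalized).
#' @export
aneuploidy_score <- function(arm_z, panel, min_arms = 5) {
  stopifnot(inherits(panel, "ref_panel"))
  if (length(arm_z) < min_arms) {
    stop("unreliable score: fewer than ", min_arms, " usable arms")
  }
  raw_sum <- sum(arm_z^2)
  loo <- panel_loo_raw_sums(panel)
  s <- stats::sd(loo)
  if (!is.finite(s) || s <= 0) stop("degenerate panel: null score spread is zero")
  list(raw_sum = raw_sum, score = (raw_sum - mean(loo)) / s)
}

#' Positivity call for the aneuploidy score
#'
#' @param result A per-sample result list/row with fields `score` and
#'   `qc_pass`, or a bare numeric score (assumed QC-passing).
#' @param threshold Positivity threshold (inclusive, default 3).
#' @return `TRUE`/`FALSE`, or `NA` ("not evaluable") when QC failed.
#' @export
call_aneuploid <- function(result, threshold = 3) {
  if (is.numeric(result)) return(result >= threshold)
  if (!isTRUE(result$qc_pass)) return(NA)
  result$score >= threshold
}

#' Score a set of samples against a donor panel
#'
#' Convenience driver: read QC, per-arm z-scores, genome-wide score and
#' positivity call for each profile.
#'
#' @param profiles List of [arm_count_profile()].
#' @param panel A [build_panel()] reference panel.
#' @param threshold Positivity threshold on the normalized score.
#' @param qc_threshold Mapped-read QC threshold.
#' @return `data.frame` with columns `sample_id`, `qc_pass`, `n_arms_used`,
#'   `raw_sum`, `score`, `positive` (`NA` when not evaluable).
#' @export
score_aneuploidy <- function(profiles, panel, threshold = 3,
                             qc_threshold = 90000) {
  rows <- lapply(profiles, function(p) {
    qc <- qc_mapped_reads(p, qc_threshold)
    if (!qc) {
      return(data.frame(sample_id = p$sample_id, qc_pass = FALSE,
                        n_arms_used = NA_integer_, raw_sum = NA_real_,
                        score = NA_real_, positive = NA))
    }
    z <- arm_zscores(p, panel)
    sc <- aneuploidy_score(z, panel)
    data.frame(sample_id = p$sample_id, qc_pass = TRUE,
               n_arms_used = length(z), raw_sum = sc$raw_sum,
               score = sc$score, positive = sc$score >= threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
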