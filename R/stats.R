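#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation (Pearson correlation of average
#' ranks). Pairs with missing values are removed pairwise and counted. The
#' p-value is exact for n <= 9 without ties, otherwise from the
#' t approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List: `rho`, `p`, `n` (complete pairs), `n_removed`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  n_removed <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho undefined: constant input vector")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (!ties && n <= 9))
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       n_removed = n_removed)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups: exact
#' enumeration when the product of group sizes is at most 400 and there are
#' no ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return List: `U` (statistic for the first group), `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. The reported odds ratio is the
#' sample odds ratio `(a d)/(b c)`. A zero margin makes the table
#' uninformative; p = 1 is returned with a warning.
#'
#' @param a,b,c,d Cell counts, row-wise: `a b / c d`.
#' @return List: `odds_ratio`, `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be nonnegative integers")
  }
  or <- (a * d) / (b * c)  # may be Inf or NaN with zero cells
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warning("zero margin: test is uninformative, p = 1 by convention")
    return(list(odds_ratio = or, p = 1))
  }
  ft <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
  list(odds_ratio = or, p = ft$p.value)
}

#' Square-root display transform
#'
#' Element-wise square root used to de-skew plots; all statistics are
#' computed on untransformed values (rank statistics are invariant to the
#' transform anyway).
#'
#' @param values Nonnegative numeric vector.
#' @return `sqrt(values)`.
#' @export
sqrt_display <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be nonnegative")
  sqrt(values)
}

# Exact two-stage operating characteristics for bounds (r1, n1, r, n) at
# response probability p. The trial stops for futility after stage 1 when
# responses <= r1; the drug is declared promising when total responses > r.
simon_operating <- function(r1, n1, r, n, p) {
  n2 <- n - n1
  x <- (r1 + 1):n1
  pr_x <- stats::dbinom(x, n1, p)
  # P(X2 > r - x) = P(X2 >= r - x + 1)
  tail2 <- stats::pbinom(pmax(r - x, -1), n2, p, lower.tail = FALSE)
  pet <- stats::pbinom(r1, n1, p)
  list(prob_promising = sum(pr_x * tail2),
       pet = pet,
       expected_n = n1 + (1 - pet) * n2)
}

new_simon_design <- function(r1, n1, r, n, p0, p1, criterion) {
  op0 <- simon_operating(r1, n1, r, n, p0)
  op1 <- simon_operating(r1, n1, r, n, p1)
  structure(
    list(r1 = r1, n1 = n1, r = r, n = n,
         attained_alpha = op0$prob_promising,
         attained_power = op1$prob_promising,
         expected_n_p0 = op0$expected_n,
         pet_p0 = op0$pet,
         criterion = criterion),
    class = "simon_design"
  )
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf(
    "<simon_design %s> r1/n1 = %d/%d, r/n = %d/%d | alpha = %.4f, power = %.4f, E[N|p0] = %.2f, PET(p0) = %.3f\n",
    x$criterion, x$r1, x$n1, x$r, x$n,
    x$attained_alpha, x$attained_power, x$expected_n_p0, x$pet_p0))
  invisible(x)
}

#' Simon two-stage phase-II designs by exhaustive search
#'
#' Searches all stage-1/overall bound combinations `(r1, n1, r, n)` with
#' `n <= n_max`, computing exact type-I error and power from the two-stage
#' binomial convolution
#' `P(promising) = sum_{x > r1} Bin(x; n1, p) P(X2 > r - x; n - n1, p)`.
#' Feasible designs attain `alpha` and power `1 - beta`; the optimal design
#' minimizes the expected sample size under `p0`, the minimax design
#' minimizes the maximal sample size `n` (then expected size). Ties are
#' broken by smaller `n1`. The drug is rejected (trial stopped / declared
#' not promising) when responses are `<= r1` after stage 1 or `<= r`
#' overall.
#'
#' @param p0 Uninteresting response probability.
#' @param p1 Promising response probability (`p1 > p0`).
#' @param alpha One-sided type-I error bound.
#' @param beta Type-II error bound.
#' @param n_max Largest total sample size searched.
#' @return List with elements `optimal` and `minimax`, each a
#'   `simon_design`.
#' @export
simon_two_stage <- function(p0, p1, alpha = 0.05, beta = 0.2, n_max = 60) {
  if (!(p0 > 0 && p0 < 1 && p1 > 0 && p1 < 1)) stop("p0, p1 must be in (0,1)")
  if (p1 <= p0) stop("p1 must exceed p0")
  if (!(alpha > 0 && alpha < 1 && beta > 0 && beta < 1)) {
    stop("alpha and beta must be in (0,1)")
  }
  best_opt <- NULL
  best_mm <- NULL
  better_opt <- function(cand, cur) {
    is.null(cur) ||
      cand$expected_n_p0 < cur$expected_n_p0 - 1e-12 ||
      (abs(cand$expected_n_p0 - cur$expected_n_p0) < 1e-12 && cand$n1 < cur$n1)
  }
  better_mm <- function(cand, cur) {
    is.null(cur) || cand$n < cur$n ||
      (cand$n == cur$n &&
         (cand$expected_n_p0 < cur$expected_n_p0 - 1e-12 ||
            (abs(cand$expected_n_p0 - cur$expected_n_p0) < 1e-12 &&
               cand$n1 < cur$n1)))
  }
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1)) {
      for (r1 in 0:(n1 - 1)) {
        # alpha and power both decrease in r; the smallest feasible-alpha r
        # has the best power, so only that r needs checking.
        for (r in (r1 + 1):n) {
          op0 <- simon_operating(r1, n1, r, n, p0)
          if (op0$prob_promising > alpha) next
          op1 <- simon_operating(r1, n1, r, n, p1)
          if (op1$prob_promising >= 1 - beta) {
            cand <- new_simon_design(r1, n1, r, n, p0, p1, "optimal")
            if (better_opt(cand, best_opt)) best_opt <- cand
            cand$criterion <- "minimax"
            if (better_mm(cand, best_mm)) best_mm <- cand
          }
          break
        }
      }
    }
  }
  if (is.null(best_opt)) {
    stop("no feasible design with n <= ", n_max,
         "; increase n_max or relax the error bounds")
  }
  list(optimal = best_opt, minimax = best_mm)
}

# Run a test and fold errors into a not-evaluable (NA) record.
try_test <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Integrated cohort report
#'
#' Assembles the per-patient call matrix (CTC positivity per platform,
#' mutation detected, aneuploidy positive, methylation altered) and the
#' pairwise statistics relating blood measurements to clinical parameters:
#' Spearman correlations of VAF / aneuploidy score / melanoma methylation
#' score against LDH, tumor volume and lesion count; Mann-Whitney
#' comparisons of LDH / volume / lesions by CTC positivity per platform;
#' and Fisher tests between platform detection rates. No multiplicity
#' adjustment is applied across the panel; p-values are raw. Tests that
#' cannot be computed (constant input, single patient) are reported as
#' not evaluable (`NA` with a note), never silently dropped.
#'
#' @param table Per-patient `data.frame` with columns `patient_id`, `vaf`,
#'   `aneuploidy_score`, `dmr_score`, `ldh`, `tumor_volume_cm3`,
#'   `lesion_count`, `pb_ctc`, `dla_cs_ctc`, `dla_fcm_ctc`, plus call
#'   columns `mutation_detected`, `aneuploidy_positive`,
#'   `methylation_altered` (logical, `NA` allowed).
#' @param ctc_threshold CTC positivity threshold.
#' @return List of class `cohort_report`: `calls` (per-patient logical
#'   matrix), `correlations`, `group_tests`, `platform_tests`.
#' @export
cohort_report <- function(table, ctc_threshold = 1) {
  need <- c("patient_id", "vaf", "aneuploidy_score", "dmr_score", "ldh",
            "tumor_volume_cm3", "lesion_count", "pb_ctc", "dla_cs_ctc",
            "dla_fcm_ctc")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$patient_id)) stop("duplicate patient ids")

  platforms <- c(PB_CellSearch = "pb_ctc", DLA_CellSearch = "dla_cs_ctc",
                 DLA_FCM = "dla_fcm_ctc")
  calls <- data.frame(patient_id = table$patient_id, stringsAsFactors = FALSE)
  for (p in names(platforms)) {
    calls[[paste0("ctc_", p)]] <- table[[platforms[[p]]]] >= ctc_threshold
  }
  for (col in c("mutation_detected", "aneuploidy_positive",
                "methylation_altered")) {
    calls[[col]] <- if (col %in% names(table)) table[[col]] else NA
  }

  markers <- c(vaf = "vaf", aneuploidy_score = "aneuploidy_score",
               dmr_score = "dmr_score")
  clin <- c(ldh = "ldh", tumor_volume = "tumor_volume_cm3",
            lesions = "lesion_count")
  correlations <- do.call(rbind, lapply(names(markers), function(mk) {
    do.call(rbind, lapply(names(clin), function(cl) {
      res <- try_test(spearman(table[[markers[[mk]]]], table[[clin[[cl]]]]))
      data.frame(marker = mk, clinical = cl,
                 rho = if (is.null(res$error)) res$rho else NA_real_,
                 p = if (is.null(res$error)) res$p else NA_real_,
                 note = if (is.null(res$error)) "" else res$error,
                 stringsAsFactors = FALSE)
    }))
  }))

  group_tests <- do.call(rbind, lapply(names(platforms), function(pf) {
    pos <- calls[[paste0("ctc_", pf)]]
    do.call(rbind, lapply(names(clin), function(cl) {
      v <- table[[clin[[cl]]]]
      res <- if (sum(pos, na.rm = TRUE) == 0 || sum(!pos, na.rm = TRUE) == 0) {
        list(error = "one group empty")
      } else {
        try_test(mann_whitney(v[pos %in% TRUE], v[pos %in% FALSE]))
      }
      data.frame(platform = pf, clinical = cl,
                 U = if (is.null(res$error)) res$U else NA_real_,
                 p = if (is.null(res$error)) res$p else NA_real_,
                 note = if (is.null(res$error)) "" else res$error,
                 stringsAsFactors = FALSE)
    }))
  }))

  pf_names <- names(platforms)
  pairs <- utils::combn(pf_names, 2, simplify = FALSE)
  platform_tests <- do.call(rbind, lapply(pairs, function(pr) {
    x <- calls[[paste0("ctc_", pr[1])]]
    y <- calls[[paste0("ctc_", pr[2])]]
    res <- try_test(suppressWarnings(
      fisher_exact_2x2(sum(x), sum(!x), sum(y), sum(!y))))
    data.frame(platform_a = pr[1], platform_b = pr[2],
               p = if (is.null(res$error)) res$p else NA_real_,
               note = if (is.null(res$error)) "" else res$error,
               stringsAsFactors = FALSE)
  }))

  structure(list(calls = calls, correlations = correlations,
                 group_tests = group_tests, platform_tests = platform_tests),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", nrow(x$calls), "patients\n")
  cat("Correlations (Spearman):\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
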