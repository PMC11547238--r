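#' Droplet digital PCR well summary
#'
#' Positive/total droplet counts for the mutant and wild-type channels of a
#' uniplex mutation assay.
#'
#' @param sample_id,assay_name Identifiers (e.g. `"BRAF p.V600E"`).
#' @param mutant_positive,wildtype_positive Positive droplets per channel.
#' @param total_droplets Accepted droplets in the well.
#' @param droplet_volume_nl Droplet volume in nanoliters (metadata only).
#' @return An object of class `droplet_assay`.
#' @export
droplet_assay <- function(sample_id, assay_name, mutant_positive,
                          wildtype_positive, total_droplets,
                          droplet_volume_nl = 0.85) {
  if (total_droplets <= 0) stop("total_droplets must be positive")
  if (mutant_positive < 0 || mutant_positive > total_droplets ||
      wildtype_positive < 0 || wildtype_positive > total_droplets) {
    stop("positive droplet counts must lie in [0, total_droplets]")
  }
  structure(
    list(sample_id = as.character(sample_id),
         assay_name = as.character(assay_name),
         mutant_positive = as.integer(mutant_positive),
         wildtype_positive = as.integer(wildtype_positive),
         total_droplets = as.integer(total_droplets),
         droplet_volume_nl = droplet_volume_nl),
    class = "droplet_assay"
  )
}

#' Poisson-corrected mean copies per droplet
#'
#' Target molecules distribute over droplets approximately as Poisson, so a
#' droplet is negative with probability `exp(-lambda)`; inverting gives
#' `lambda = -log(1 - positive/total)`.
#'
#' @param positive Positive droplets.
#' @param total Total droplets.
#' @return Mean copies per droplet (>= 0).
#' @export
lambda_from_droplets <- function(positive, total) {
  if (total <= 0) stop("total droplets must be positive")
  if (positive < 0 || positive > total) stop("positive must be in [0, total]")
  if (positive == total) {
    stop("all droplets positive: assay saturated; dilute the sample and rerun")
  }
  -log(1 - positive / total)
}

#' Variant allele fraction from a droplet assay
#'
#' Both channels are Poisson-corrected and the VAF is the mutant share of
#' total corrected copies, `lambda_mut / (lambda_mut + lambda_wt)` (0 when
#' both are 0). A mutation is called detected when at least `min_droplets`
#' mutant droplets are positive.
#'
#' @param assay A [droplet_assay()].
#' @param min_droplets Detection threshold on mutant-positive droplets.
#' @return List of class `vaf_estimate`: `sample_id`, `assay_name`,
#'   `lambda_mut`, `lambda_wt`, `vaf`, `detected`, `n_mutant_positive`.
#' @export
estimate_vaf <- function(assay, min_droplets = 3) {
  stopifnot(inherits(assay, "droplet_assay"))
  lam_mut <- lambda_from_droplets(assay$mutant_positive, assay$total_droplets)
  lam_wt <- lambda_from_droplets(assay$wildtype_positive, assay$total_droplets)
  vaf <- if (lam_mut + lam_wt == 0) 0 else lam_mut / (lam_mut + lam_wt)
  structure(
    list(sample_id = assay$sample_id, assay_name = assay$assay_name,
         lambda_mut = lam_mut, lambda_wt = lam_wt, vaf = vaf,
         detected = assay$mutant_positive >= min_droplets,
         n_mutant_positive = assay$mutant_positive),
    class = "vaf_estimate"
  )
}

#' @export
print.vaf_estimate <- function(x, ...) {
  cat(sprintf("<vaf_estimate> %s %s: VAF %.4f (%s)\n", x$sample_id,
              x$assay_name, x$vaf,
              if (x$detected) "detected" else "not detected"))
  invisible(x)
}

#' Dominant mutation per sample
#'
#' Among a sample's assays, returns the detected estimate with the highest
#' VAF; when no assay is detected, a zero-VAF undetected estimate is
#' returned (the convention under which cohort VAF ranges start at 0).
#'
#' @param estimates List of `vaf_estimate` objects for one sample.
#' @return A single `vaf_estimate`.
#' @export
dominant_vaf <- function(estimates) {
  if (length(estimates) == 0) stop("at least one assay is required")
  stopifnot(all(vapply(estimates, inherits, logical(1), "vaf_estimate")))
  det <- Filter(function(e) e$detected, estimates)
  if (length(det) == 0) {
    out <- estimates[[1]]
    out$vaf <- 0
    out$detected <- FALSE
    return(out)
  }
  det[[which.max(vapply(det, `[[`, numeric(1), "vaf"))]]
}

#' Pool replicate wells of the same assay
#'
#' Positives and totals are summed before Poisson correction
#' (maximum-likelihood pooling of replicate wells).
#'
#' @param df `data.frame` with columns `sample_id`, `assay`,
#'   `mutant_positive`, `wildtype_positive`, `total_droplets`.
#' @return Pooled `data.frame`, one row per sample x assay.
#' @export
pool_wells <- function(df) {
  agg <- stats::aggregate(
    df[c("mutant_positive", "wildtype_positive", "total_droplets")],
    by = df[c("sample_id", "assay")], FUN = sum)
  agg[order(agg$sample_id, agg$assay), , drop = FALSE]
}

#' VAF table for a cohort
#'
#' Pools replicate wells, estimates per-assay VAFs and flags each sample's
#' dominant mutation.
#'
#' @param df ddPCR `data.frame` (see [pool_wells()] for columns).
#' @param min_droplets Detection threshold on mutant-positive droplets.
#' @return `data.frame` with one row per sample x assay: `lambda_mut`,
#'   `lambda_wt`, `vaf`, `detected`, `dominant`.
#' @export
estimate_vaf_table <- function(df, min_droplets = 3) {
  pooled <- pool_wells(df)
  est <- lapply(seq_len(nrow(pooled)), function(i) {
    estimate_vaf(droplet_assay(pooled$sample_id[i], pooled$assay[i],
                               pooled$mutant_positive[i],
                               pooled$wildtype_positive[i],
                               pooled$total_droplets[i]),
                 min_droplets = min_droplets)
  })
  out <- data.frame(
    sample_id = pooled$sample_id, assay = pooled$assay,
    lambda_mut = vapply(est, `[[`, numeric(1), "lambda_mut"),
    lambda_wt = vapply(est, `[[`, numeric(1), "lambda_wt"),
    vaf = vapply(est, `[[`, numeric(1), "vaf"),
    detected = vapply(est, `[[`, logical(1), "detected"),
    stringsAsFactors = FALSE
  )
  out$dominant <- FALSE
  for (s in unique(out$sample_id)) {
    rows <- which(out$sample_id == s)
    dets <- rows[out$detected[rows]]
    if (length(dets) > 0) {
      out$dominant[dets[which.max(out$vaf[dets])]] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}

#' Dominant VAF per sample as a summary table
#'
#' @param vaf_table Output of [estimate_vaf_table()].
#' @return `data.frame` with one row per sample: `sample_id`, `vaf`
#'   (0 when nothing detected), `detected`, `assay`.
#' @export
dominant_vaf_table <- function(vaf_table) {
  rows <- lapply(split(vaf_table, vaf_table$sample_id), function(d) {
    dom <- d[d$dominant, , drop = FALSE]
    if (nrow(dom) == 0) {
      data.frame(sample_id = d$sample_id[1], assay = NA_character_,
                 vaf = 0, detected = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = dom$sample_id[1], assay = dom$assay[1],
                 vaf = dom$vaf[1], detected = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
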