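#' @importFrom utils read.delim read.csv write.table
NULL

# Read a delimited table, skipping provenance header lines starting "#".
read_table_checked <- function(path, sep, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

write_with_provenance <- function(df, path, provenance = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance) > 0) {
    writeLines(paste0("# ", names(provenance), "=",
                      vapply(provenance, format, "")), con)
  }
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read arm counts from a TSV
#'
#' Long format with columns `sample_id`, `arm`, `count`, one header line.
#'
#' @param path TSV path.
#' @return Named list of [arm_count_profile()] objects.
#' @export
read_arm_counts <- function(path) {
  df <- read_table_checked(path, "\t", c("sample_id", "arm", "count"))
  bad <- which(is.na(df$count) | df$count < 0 | df$count != floor(df$count))
  if (length(bad) > 0) {
    stop(basename(path), ": invalid count at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    arm_count_profile(d$sample_id[1],
                      stats::setNames(as.integer(d$count), d$arm))
  })
  out[unique(df$sample_id)]
}

#' Write arm counts to a TSV
#'
#' @param profiles List of [arm_count_profile()].
#' @param path Output path.
#' @param provenance Optional named list written as `# key=value` headers.
#' @export
write_arm_counts <- function(profiles, path, provenance = NULL) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, arm = names(p$counts),
               count = unname(p$counts), stringsAsFactors = FALSE)
  }))
  write_with_provenance(df, path, provenance)
  invisible(path)
}

#' Read a methylation region-count matrix
#'
#' Regions come from a BED file (0-based half-open, columns chrom start end
#' name), counts from a TSV whose first column is `region_id` followed by
#' one column per sample, and group labels from a CSV with columns
#' `sample_id`, `group`.
#'
#' @param counts_path,bed_path,groups_path File paths.
#' @return A [region_count_matrix()].
#' @export
read_region_counts <- function(counts_path, bed_path, groups_path) {
  bed <- utils::read.delim(bed_path, header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4) stop(basename(bed_path), ": need chrom/start/end/name")
  names(bed)[1:4] <- c("chrom", "start", "end", "region_id")
  bed$chrom <- as.integer(sub("^chr", "", bed$chrom))
  if (any(bed$start >= bed$end)) {
    stop(basename(bed_path), ": interval with start >= end at row ",
         which(bed$start >= bed$end)[1])
  }
  if (min(bed$start) == 1) {
    warning(basename(bed_path), ": smallest start is 1; coordinates look ",
            "1-based. Intervals are interpreted as 0-based half-open as-is.")
  }
  counts_df <- read_table_checked(counts_path, "\t", "region_id")
  m <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(m) <- counts_df$region_id
  if (!setequal(rownames(m), bed$region_id)) {
    stop("region ids differ between counts and BED")
  }
  bed <- bed[match(rownames(m), bed$region_id),
             c("region_id", "chrom", "start", "end")]
  groups_df <- read_table_checked(groups_path, ",", c("sample_id", "group"))
  region_count_matrix(m, bed,
                      stats::setNames(groups_df$group, groups_df$sample_id))
}

#' Write a methylation region-count matrix
#'
#' @param m A [region_count_matrix()].
#' @param counts_path,bed_path,groups_path Output paths.
#' @export
write_region_counts <- function(m, counts_path, bed_path, groups_path) {
  bed <- data.frame(chrom = m$regions$chrom, start = m$regions$start,
                    end = m$regions$end, name = m$regions$region_id)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  counts_df <- data.frame(region_id = rownames(m$counts),
                          m$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write_with_provenance(counts_df, counts_path)
  groups_df <- data.frame(sample_id = names(m$groups),
                          group = unname(m$groups))
  write_with_provenance(groups_df, groups_path, sep = ",")
  invisible(counts_path)
}

#' Read/write ddPCR droplet summaries
#'
#' CSV with columns `sample_id`, `assay`, `mutant_positive`,
#' `wildtype_positive`, `total_droplets`.
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_ddpcr <- function(path) {
  df <- read_table_checked(path, ",", c("sample_id", "assay",
                                        "mutant_positive",
                                        "wildtype_positive",
                                        "total_droplets"))
  bad <- which(df$mutant_positive < 0 | df$wildtype_positive < 0 |
                 df$total_droplets <= 0 |
                 df$mutant_positive > df$total_droplets |
                 df$wildtype_positive > df$total_droplets)
  if (length(bad) > 0) {
    stop(basename(path), ": invalid droplet counts at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' @rdname read_ddpcr
#' @param df ddPCR `data.frame`.
#' @param provenance Optional named list written as `# key=value` headers.
#' @export
write_ddpcr <- function(df, path, provenance = NULL) {
  write_with_provenance(df, path, provenance, sep = ",")
  invisible(path)
}

#' Read/write the per-patient clinical/CTC table
#'
#' CSV, one row per patient; missing values are empty fields, never 0.
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_clinical <- function(path) {
  read_table_checked(path, ",", c("patient_id", "tumor_volume_cm3", "ldh",
                                  "processed_blood_L", "product_volume_mL",
                                  "pb_ctc", "dla_cs_ctc", "dla_fcm_ctc"))
}

#' @rdname read_clinical
#' @param df Clinical `data.frame`.
#' @param provenance Optional named list written as `# key=value` headers.
#' @export
write_clinical <- function(df, path, provenance = NULL) {
  write_with_provenance(df, path, provenance, sep = ",")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `arms.tsv` (donors + patients), `regions.bed` +
#' `methylation_counts.tsv` + `methylation_groups.csv`, `ddpcr.csv`,
#' `cohort.csv` and `truth.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = cohort$config$seed)
  write_arm_counts(c(cohort$hbd_arm_profiles, cohort$patient_arm_profiles),
                   file.path(dir, "arms.tsv"), provenance = prov)
  write_region_counts(cohort$methylation,
                      file.path(dir, "methylation_counts.tsv"),
                      file.path(dir, "regions.bed"),
                      file.path(dir, "methylation_groups.csv"))
  write_ddpcr(cohort$ddpcr, file.path(dir, "ddpcr.csv"), provenance = prov)
  write_clinical(cohort$clinical, file.path(dir, "cohort.csv"),
                 provenance = prov)
  truth <- cohort$truth
  truth$cna <- lapply(truth$cna, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' Counterpart of [write_cohort()]; the returned list has the shape
#' [run_pipeline()] expects. Donor arm profiles are identified by sample
#' ids starting `"HBD"`.
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled with
#'   the same file names). `methylation_counts.tsv` may be absent, in which
#'   case the methylation element is `NULL` and the pipeline skips that
#'   stage.
#' @return List with elements `hbd_arm_profiles`, `patient_arm_profiles`,
#'   `methylation` (or `NULL`), `ddpcr`, `clinical`.
#' @export
read_tables <- function(dir) {
  profiles <- read_arm_counts(file.path(dir, "arms.tsv"))
  is_hbd <- grepl("^HBD", names(profiles))
  meth_path <- file.path(dir, "methylation_counts.tsv")
  meth <- if (file.exists(meth_path)) {
    read_region_counts(meth_path, file.path(dir, "regions.bed"),
                       file.path(dir, "methylation_groups.csv"))
  } else NULL
  list(hbd_arm_profiles = profiles[is_hbd],
       patient_arm_profiles = profiles[!is_hbd],
       methylation = meth,
       ddpcr = read_ddpcr(file.path(dir, "ddpcr.csv")),
       clinical = read_clinical(file.path(dir, "cohort.csv")))
}

#' Pipeline thresholds
#'
#' Central bundle of every decision threshold used by [run_pipeline()];
#' defaults are the study's operating points.
#'
#' @param aneuploidy_threshold Aneuploidy positivity (score >=, default 3).
#' @param fdr DMR FDR threshold (default 0.10).
#' @param completeness Region completeness (default 0.75).
#' @param reads_qc Minimum mapped reads per arm profile (default 90,000).
#' @param min_droplets ddPCR detection threshold (default 3).
#' @param ctc_positivity Minimum CTC count called positive (default 1).
#' @param cutoff_mode Donor cutoff mode, `"ci_mean"` or `"prediction"`.
#' @param cutoff_level Donor cutoff confidence level (default 0.95).
#' @return Named list.
#' @export
pipeline_thresholds <- function(aneuploidy_threshold = 3, fdr = 0.10,
                                completeness = 0.75, reads_qc = 90000,
                                min_droplets = 3, ctc_positivity = 1,
                                cutoff_mode = "ci_mean",
                                cutoff_level = 0.95) {
  stopifnot(fdr > 0, fdr < 1, completeness > 0, completeness <= 1,
            cutoff_level > 0, cutoff_level < 1)
  as.list(environment())
}

#' Run the full scoring pipeline
#'
#' Executes QC, aneuploidy scoring, high-ctDNA selection, differential
#' methylation and methylation scoring, variant-allele-fraction estimation,
#' CTC metrics and the integrated cohort report on an in-memory dataset (a
#' [simulate_cohort()] result or the list returned by [read_tables()]).
#' When the methylation element is absent the methylation stage is marked
#' skipped rather than failing the run. If `out_dir` is given, every
#' stage's table is written with the thresholds embedded as `# key=value`
#' provenance headers.
#'
#' @param data Cohort data (synthetic cohort or [read_tables()] list).
#' @param out_dir Optional output directory.
#' @param thresholds A [pipeline_thresholds()] list.
#' @param dry_run If `TRUE`, return the planned stages without computing or
#'   writing anything.
#' @return List of class `pipeline_bundle`: `aneuploidy`, `methylation`
#'   (or `NULL` with `stages$methylation == "skipped"`), `vaf`,
#'   `dominant_vaf`, `ctc`, `cohort_table`, `report`, `stages`,
#'   `thresholds`.
#' @export
run_pipeline <- function(data, out_dir = NULL,
                         thresholds = pipeline_thresholds(),
                         dry_run = FALSE) {
  stages <- c("qc", "aneuploidy", "high_ctdna_selection", "methylation",
              "vaf", "ctc", "report")
  if (dry_run) return(list(planned_stages = stages))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  panel <- run_stage("qc", build_panel(data$hbd_arm_profiles,
                                       qc_threshold = thresholds$reads_qc))
  aneu <- run_stage("aneuploidy",
                    score_aneuploidy(data$patient_arm_profiles, panel,
                                     threshold = thresholds$aneuploidy_threshold,
                                     qc_threshold = thresholds$reads_qc))

  meth_res <- NULL
  meth_status <- "skipped"
  if (!is.null(data$methylation)) {
    high <- tryCatch(
      select_high_ctdna(aneu, thresholds$aneuploidy_threshold),
      error = function(e) character(0))
    high <- intersect(high, colnames(data$methylation$counts))
    if (length(high) < 3) {
      # the DMR contrast needs at least 3 high-ctDNA samples; run the rest
      # of the pipeline rather than failing (mirrors per-assay dropout)
      meth_status <- "skipped: fewer than 3 high-ctDNA samples"
    } else {
      meth_res <- run_stage("methylation",
                            score_methylation(data$methylation, high,
                                              fdr = thresholds$fdr,
                                              completeness = thresholds$completeness,
                                              cutoff_mode = thresholds$cutoff_mode,
                                              level = thresholds$cutoff_level))
      meth_status <- "run"
    }
  }

  vaf_tab <- run_stage("vaf", estimate_vaf_table(data$ddpcr,
                                                 min_droplets = thresholds$min_droplets))
  dom <- dominant_vaf_table(vaf_tab)
  ctc <- run_stage("ctc", cohort_ctc_metrics(data$clinical,
                                             thresholds$ctc_positivity))

  ids <- data$clinical$patient_id
  meth_scores <- if (!is.null(meth_res)) meth_res$scores else NULL
  pick <- function(df, key, col, default = NA_real_) {
    if (is.null(df)) return(rep(default, length(ids)))
    df[[col]][match(ids, df[[key]])]
  }
  cohort_table <- data.frame(
    patient_id = ids,
    vaf = pick(dom, "sample_id", "vaf"),
    mutation_detected = pick(dom, "sample_id", "detected", NA),
    aneuploidy_score = pick(aneu, "sample_id", "score"),
    aneuploidy_positive = pick(aneu, "sample_id", "positive", NA),
    genome_wide_methylation = pick(meth_scores, "sample_id", "genome_wide_z_sum"),
    dmr_score = pick(meth_scores, "sample_id", "dmr_score"),
    methylation_altered = pick(meth_scores, "sample_id", "altered", NA),
    ldh = data$clinical$ldh,
    tumor_volume_cm3 = data$clinical$tumor_volume_cm3,
    lesion_count = data$clinical$lesion_count,
    pb_ctc = data$clinical$pb_ctc,
    dla_cs_ctc = data$clinical$dla_cs_ctc,
    dla_fcm_ctc = data$clinical$dla_fcm_ctc,
    stringsAsFactors = FALSE
  )
  report <- run_stage("report",
                      cohort_report(cohort_table,
                                    ctc_threshold = thresholds$ctc_positivity))

  bundle <- structure(
    list(aneuploidy = aneu, methylation = meth_res, vaf = vaf_tab,
         dominant_vaf = dom, ctc = ctc, cohort_table = cohort_table,
         report = report,
         stages = list(methylation = meth_status),
         thresholds = thresholds),
    class = "pipeline_bundle"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- thresholds[vapply(thresholds, is.atomic, logical(1))]
    write_with_provenance(aneu, file.path(out_dir, "aneuploidy.tsv"), prov)
    if (!is.null(meth_res)) {
      write_with_provenance(meth_res$scores,
                            file.path(out_dir, "methylation_scores.tsv"), prov)
      write_with_provenance(meth_res$dmrs, file.path(out_dir, "dmrs.tsv"), prov)
    }
    write_with_provenance(vaf_tab, file.path(out_dir, "vaf.tsv"), prov)
    write_with_provenance(ctc$detection,
                          file.path(out_dir, "ctc_summary.tsv"), prov)
    write_with_provenance(ctc$recovery, file.path(out_dir, "recovery.tsv"),
                          prov)
    write_with_provenance(cohort_table, file.path(out_dir, "cohort_table.tsv"),
                          prov)
    jsonlite::write_json(
      list(correlations = report$correlations,
           group_tests = report$group_tests,
           platform_tests = report$platform_tests,
           thresholds = prov),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Read a per-patient score table
#'
#' Loads an externally supplied per-patient summary (dominant VAF,
#' aneuploidy score, melanoma-specific methylation score) such as a study's
#' supplementary per-patient table, for reproduction of cross-assay
#' correlations.
#'
#' @param path CSV with columns `patient_id`, `vaf`, `aneuploidy_score`,
#'   `dmr_score` (missing values empty).
#' @return `data.frame`.
#' @export
read_patient_scores <- function(path) {
  read_table_checked(path, ",", c("patient_id", "vaf", "aneuploidy_score",
                                  "dmr_score"))
}
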