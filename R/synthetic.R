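#' Simulation configuration for a synthetic liquid-biopsy cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate a
#' 20-patient metastatic-melanoma cohort: a 9-donor methylation reference
#' panel and a 20-donor arm-count panel, ~500,000 mapped reads per sample,
#' ~20,000 droplets per ddPCR well, a tumor-fraction mixture with a point
#' mass at zero plus a Beta tail (median ~3.2%, upper range reaching ~0.56),
#' arm-level gains/losses on a quarter of the arms, 3-fold methylation
#' effects in true differentially methylated regions, a leukapheresis
#' recovery step with mean 29% for tumor cells and 70% for mononuclear
#' cells, processed blood volumes of 2.4-6.8 L and an LDH baseline of
#' 164 U/L rising with tumor burden.
#'
#' @param n_patients Number of patients.
#' @param n_hbd_methylation Healthy blood donors in the methylation panel.
#' @param n_hbd_arms Healthy blood donors in the arm-count panel.
#' @param n_regions Methylation regions simulated.
#' @param n_true_dmrs Regions given a true tumor methylation effect.
#' @param arms Arm identifiers; default all 39 autosomal arms.
#' @param reads_per_sample Mean total mapped reads per sample.
#' @param droplets_per_well Droplets per ddPCR well.
#' @param tf_zero_prob Probability a patient has tumor fraction exactly 0.
#' @param tf_beta_shape1,tf_beta_shape2 Beta parameters of the nonzero
#'   tumor-fraction component.
#' @param tf_volume_coupling Gaussian-copula correlation between tumor
#'   fraction and log tumor volume.
#' @param cna_arm_fraction Fraction of arms copy-number-altered per tumor.
#' @param dmr_effect Multiplicative methylation fold-change in tumor DNA.
#' @param nb_dispersion Negative-binomial dispersion of region counts
#'   (variance = mu + dispersion * mu^2).
#' @param arm_noise_sd Donor-to-donor log-normal noise SD on arm proportions.
#' @param ctc_burden_coupling Slope of log CTC concentration on log1p tumor
#'   volume.
#' @param ctc_base_log_conc Log CTC concentration (cells/mL) at zero volume.
#' @param ctc_log_sd Patient-to-patient SD of log CTC concentration.
#' @param dla_recovery_beta Beta(shape1, shape2) of the tumor-cell recovery
#'   fraction through leukapheresis + depletion (mean 0.29).
#' @param mnc_recovery_beta Beta parameters of mononuclear-cell recovery
#'   (mean 0.70).
#' @param cs_dla_efficiency Extra efficiency of the semi-automated counting
#'   platform on the leukapheresis aliquot relative to flow cytometry.
#' @param ldh_baseline Baseline LDH in U/L.
#' @param ldh_slope LDH increase per cm^3 of tumor volume.
#' @param cfdna_copies_meanlog,cfdna_copies_sdlog Log-normal parameters of
#'   amplifiable cfDNA copies per ddPCR well.
#' @param volume_meanlog,volume_sdlog Log-normal parameters of extracranial
#'   tumor volume (cm^3).
#' @param seed Integer seed; every draw in [simulate_cohort()] derives from it.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_patients = 20,
                              n_hbd_methylation = 9,
                              n_hbd_arms = 20,
                              n_regions = 5000,
                              n_true_dmrs = 200,
                              arms = autosomal_arms()$arm,
                              reads_per_sample = 500000,
                              droplets_per_well = 20000,
                              tf_zero_prob = 0.1,
                              tf_beta_shape1 = 0.45,
                              tf_beta_shape2 = 6,
                              tf_volume_coupling = 0.7,
                              cna_arm_fraction = 0.25,
                              dmr_effect = 3,
                              nb_dispersion = 0.05,
                              arm_noise_sd = 0.02,
                              ctc_burden_coupling = 1.0,
                              ctc_base_log_conc = log(5e-4),
                              ctc_log_sd = 1.0,
                              dla_recovery_beta = c(2.9, 7.1),
                              mnc_recovery_beta = c(7, 3),
                              cs_dla_efficiency = 0.5,
                              ldh_baseline = 164,
                              ldh_slope = 0.8,
                              cfdna_copies_meanlog = log(8000),
                              cfdna_copies_sdlog = 0.5,
                              volume_meanlog = log(107),
                              volume_sdlog = 1.1,
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_patients", "n_hbd_methylation", "n_hbd_arms", "n_regions",
              "n_true_dmrs", "reads_per_sample", "droplets_per_well")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("configuration error: '", f, "' must be a positive count")
    }
  }
  if (cfg$n_true_dmrs > cfg$n_regions) {
    stop("configuration error: n_true_dmrs cannot exceed n_regions")
  }
  if (tf_zero_prob < 0 || tf_zero_prob >= 1) {
    stop("configuration error: tf_zero_prob must be in [0, 1)")
  }
  for (f in c("tf_beta_shape1", "tf_beta_shape2")) {
    if (cfg[[f]] <= 0) stop("configuration error: '", f, "' must be positive")
  }
  for (f in c("dla_recovery_beta", "mnc_recovery_beta")) {
    if (length(cfg[[f]]) != 2 || any(cfg[[f]] <= 0)) {
      stop("configuration error: '", f, "' must be two positive Beta shapes")
    }
  }
  if (cna_arm_fraction < 0 || cna_arm_fraction > 1) {
    stop("configuration error: cna_arm_fraction must be in [0, 1]")
  }
  if (nb_dispersion < 0) stop("configuration error: nb_dispersion must be >= 0")
  if (dmr_effect <= 0) stop("configuration error: dmr_effect must be positive")
  if (length(arms) < 2) stop("configuration error: need at least 2 arms")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# Internal: one donor's underlying arm proportion vector (baseline perturbed
# by log-normal donor noise, renormalized).
donor_arm_props <- function(baseline, noise_sd) {
  if (noise_sd == 0) return(baseline)
  p <- baseline * exp(stats::rnorm(length(baseline), 0, noise_sd))
  p / sum(p)
}

# Internal: total mapped reads for one sample, never below the QC floor.
draw_total_reads <- function(mean_reads, qc_floor = 90000) {
  max(qc_floor, round(stats::rlnorm(1, log(mean_reads), 0.1)))
}

#' Simulate a healthy-donor arm-count panel
#'
#' Each donor's counts are a multinomial draw of their total reads over arms,
#' around the arm-length baseline proportion vector perturbed by small
#' donor-to-donor log-normal noise. The underlying per-donor proportion
#' vectors are attached as attribute `"donor_props"`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed; defaults to `config$seed`. Use `NULL` to draw
#'   from the current RNG state (as [simulate_cohort()] does).
#' @return List of [arm_count_profile()] objects of length `n_hbd_arms`.
#' @export
simulate_hbd_arm_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  baseline <- arm_baseline_fractions(config$arms)
  props <- list()
  profiles <- lapply(seq_len(config$n_hbd_arms), function(i) {
    p <- donor_arm_props(baseline, config$arm_noise_sd)
    props[[i]] <<- p
    total <- draw_total_reads(config$reads_per_sample)
    counts <- as.vector(stats::rmultinom(1, total, p))
    names(counts) <- config$arms
    arm_count_profile(sprintf("HBD_arm_%02d", i), counts, total)
  })
  attr(profiles, "donor_props") <- do.call(rbind, props)
  profiles
}

#' Draw a random arm-level copy-number specification
#'
#' Selects `round(cna_arm_fraction * n_arms)` arms and assigns each a gain
#' or a loss (copy number 3 or 1; with small probability 4 or 0).
#'
#' @param config A [simulation_config()].
#' @return Named numeric vector of copy numbers over all arms (2 = neutral).
#' @export
simulate_cna_spec <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cn <- stats::setNames(rep(2, length(config$arms)), config$arms)
  n_alt <- round(config$cna_arm_fraction * length(config$arms))
  if (n_alt == 0) return(cn)
  altered <- sample(config$arms, n_alt)
  gain <- stats::runif(n_alt) < 0.5
  extreme <- stats::runif(n_alt) < 0.15
  cn[altered] <- ifelse(gain, ifelse(extreme, 4, 3), ifelse(extreme, 0, 1))
  cn
}

#' Simulate a patient arm-count profile
#'
#' The patient's cfDNA is a mixture of normal (diploid) and tumor DNA at the
#' given tumor fraction: the expected share of arm `a` is proportional to
#' `baseline_a * ((1 - tf) + tf * c_a / 2)` where `c_a` is the tumor copy
#' number of the arm, renormalized over arms; counts are multinomial.
#'
#' @param tumor_fraction Tumor fraction of cfDNA, in `[0, 1)`.
#' @param cna_spec Named copy-number vector over arms (see
#'   [simulate_cna_spec()]); values in `{0, 1, 2, 3, 4}`.
#' @param config A [simulation_config()].
#' @param sample_id Sample identifier.
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return An [arm_count_profile()] with attribute `"expected_fractions"`.
#' @export
simulate_patient_arm_profile <- function(tumor_fraction, cna_spec, config,
                                         sample_id = "patient",
                                         seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (tumor_fraction < 0 || tumor_fraction >= 1) {
    stop("tumor_fraction must be in [0, 1)")
  }
  if (!all(cna_spec %in% 0:4)) stop("copy numbers must be in {0,1,2,3,4}")
  if (!is.null(seed)) set.seed(seed)
  baseline <- arm_baseline_fractions(config$arms)
  cn <- cna_spec[config$arms]
  w <- baseline * ((1 - tumor_fraction) + tumor_fraction * cn / 2)
  p <- w / sum(w)
  p <- donor_arm_props(p, config$arm_noise_sd)
  total <- draw_total_reads(config$reads_per_sample)
  counts <- as.vector(stats::rmultinom(1, total, p))
  names(counts) <- config$arms
  out <- arm_count_profile(sample_id, counts, total)
  attr(out, "expected_fractions") <- w / sum(w)
  out
}

#' Simulate a methylation region-count matrix (donors + patients)
#'
#' Region counts are negative-binomial around log-normal region means, with
#' per-sample library-size factors varying about two-fold. For a patient
#' with tumor fraction `tf`, true-DMR region means are scaled by
#' `(1 - tf) + tf * dmr_effect`; all other regions are unchanged. The true
#' DMR identifiers are attached to the returned matrix as attribute
#' `"true_dmr_ids"`.
#'
#' @param config A [simulation_config()].
#' @param tumor_fractions Numeric vector of patient tumor fractions; defaults
#'   to zeros of length `n_patients`.
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return A [region_count_matrix()] with HBD and patient columns.
#' @export
simulate_methylation <- function(config,
                                 tumor_fractions = rep(0, config$n_patients),
                                 seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(tumor_fractions < 0 | tumor_fractions >= 1)) {
    stop("tumor fractions must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  nr <- config$n_regions
  region_mean <- stats::rlnorm(nr, log(config$reads_per_sample / nr), 1)
  dmr_idx <- sort(sample.int(nr, config$n_true_dmrs))
  regions <- data.frame(
    region_id = sprintf("region_%05d", seq_len(nr)),
    chrom = sample(1:22, nr, replace = TRUE),
    start = (pos <- sample.int(2e8, nr)),
    end = pos + 1000L,
    stringsAsFactors = FALSE
  )
  n_hbd <- config$n_hbd_methylation
  n_pat <- length(tumor_fractions)
  ids <- c(sprintf("HBD_%02d", seq_len(n_hbd)),
           sprintf("patient_%02d", seq_len(n_pat)))
  groups <- stats::setNames(rep(c("HBD", "patient"), c(n_hbd, n_pat)), ids)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  draw_col <- function(mu) {
    lib <- 2^stats::runif(1, -1, 1)  # +/- two-fold library size
    m <- mu * lib
    if (is.finite(size)) stats::rnbinom(length(m), mu = m, size = size)
    else stats::rpois(length(m), m)
  }
  cols <- c(
    lapply(seq_len(n_hbd), function(i) draw_col(region_mean)),
    lapply(tumor_fractions, function(tf) {
      mu <- region_mean
      mu[dmr_idx] <- mu[dmr_idx] * ((1 - tf) + tf * config$dmr_effect)
      draw_col(mu)
    })
  )
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(regions$region_id, ids)
  out <- region_count_matrix(counts, regions, groups)
  attr(out, "true_dmr_ids") <- regions$region_id[dmr_idx]
  out
}

#' Simulate a droplet digital PCR well
#'
#' With `v` the variant allele fraction (equated to tumor fraction under a
#' heterozygous clonal mutation in otherwise diploid DNA... see vignette for
#' the mapping), mean copies per droplet are
#' `lambda_mut = v * copies / droplets` and
#' `lambda_wt = (1 - v) * copies / droplets`; the number of positive
#' droplets per channel is Binomial(droplets, 1 - exp(-lambda)).
#'
#' @param tumor_fraction Tumor fraction (= simulated VAF), in `[0, 1)`.
#' @param total_cfdna_copies Amplifiable cfDNA copies loaded in the well.
#' @param config A [simulation_config()].
#' @param sample_id,assay_name Identifiers for the returned assay.
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return A [droplet_assay()].
#' @export
simulate_ddpcr <- function(tumor_fraction, total_cfdna_copies, config,
                           sample_id = "patient", assay_name = "BRAF p.V600E",
                           seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (total_cfdna_copies < 0) stop("total_cfdna_copies must be nonnegative")
  if (tumor_fraction < 0 || tumor_fraction >= 1) {
    stop("tumor_fraction must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  nd <- config$droplets_per_well
  lam_mut <- tumor_fraction * total_cfdna_copies / nd
  lam_wt <- (1 - tumor_fraction) * total_cfdna_copies / nd
  droplet_assay(
    sample_id = sample_id, assay_name = assay_name,
    mutant_positive = stats::rbinom(1, nd, 1 - exp(-lam_mut)),
    wildtype_positive = stats::rbinom(1, nd, 1 - exp(-lam_wt)),
    total_droplets = nd
  )
}

#' Simulate CTC counts and clinical covariates for one patient
#'
#' CTC concentration in blood is log-normal with location increasing in
#' log1p(tumor volume). The peripheral-blood count is Poisson over 7.5 mL.
#' The leukapheresis product nominally contains `concentration x processed
#' volume` cells; the measured (flow-cytometry) product total is a binomial
#' thinning of that by a Beta-drawn recovery fraction, and the
#' semi-automated platform counts a 2 mL aliquot of the product with an
#' additional efficiency factor, so the flow-cytometry count dominates it
#' in expectation. LDH rises linearly with tumor volume around the healthy
#' baseline.
#'
#' @param tumor_volume Extracranial tumor volume in cm^3.
#' @param config A [simulation_config()].
#' @param patient_id Identifier.
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return One-row `data.frame` with CTC counts per platform, volumes and
#'   clinical covariates.
#' @export
simulate_ctc_and_clinical <- function(tumor_volume, config,
                                      patient_id = "patient", seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (tumor_volume < 0) stop("tumor_volume must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  conc <- exp(config$ctc_base_log_conc +
                config$ctc_burden_coupling * log1p(tumor_volume) +
                stats::rnorm(1, 0, config$ctc_log_sd))
  pb_count <- stats::rpois(1, 7.5 * conc)
  processed_L <- stats::runif(1, 2.4, 6.8)
  product_mL <- stats::runif(1, 46, 121)
  in_product <- stats::rpois(1, conc * processed_L * 1000)
  recovery <- stats::rbeta(1, config$dla_recovery_beta[1],
                           config$dla_recovery_beta[2])
  fcm_total <- stats::rbinom(1, in_product, recovery)
  aliquot_mL <- min(2, product_mL)
  cs_dla <- stats::rbinom(1, fcm_total,
                          (aliquot_mL / product_mL) * config$cs_dla_efficiency)
  mnc_recovery <- stats::rbeta(1, config$mnc_recovery_beta[1],
                               config$mnc_recovery_beta[2])
  ldh <- max(0.85 * config$ldh_baseline,
             config$ldh_baseline + config$ldh_slope * tumor_volume +
               stats::rnorm(1, 0, 25))
  data.frame(
    patient_id = patient_id,
    tumor_volume_cm3 = tumor_volume,
    lesion_count = 1L + stats::rpois(1, tumor_volume / 60),
    ldh = ldh,
    processed_blood_L = processed_L,
    product_volume_mL = product_mL,
    pb_ctc = pb_count,
    dla_cs_ctc = cs_dla,
    dla_cs_aliquot_mL = aliquot_mL,
    dla_fcm_ctc = fcm_total,
    dla_recovery_true = recovery,
    mnc_recovery_true = mnc_recovery,
    stringsAsFactors = FALSE
  )
}

# Internal: tumor fractions coupled to volume through a Gaussian copula so
# that blood tumor fraction and radiological burden correlate, while the
# marginal stays point-mass-at-0 + Beta.
draw_tumor_fractions <- function(config, z_volume) {
  n <- length(z_volume)
  rho <- config$tf_volume_coupling
  z <- rho * z_volume + sqrt(1 - rho^2) * stats::rnorm(n)
  u <- stats::pnorm(z)
  tf <- numeric(n)
  nz <- u >= config$tf_zero_prob
  tf[nz] <- stats::qbeta((u[nz] - config$tf_zero_prob) / (1 - config$tf_zero_prob),
                         config$tf_beta_shape1, config$tf_beta_shape2)
  tf
}

#' Simulate a complete synthetic cohort
#'
#' Draws, from a single seed, the healthy-donor arm panel, per-patient tumor
#' volumes and tumor fractions (copula-coupled), arm-level copy-number
#' profiles and arm counts, the methylation count matrix (donors +
#' patients), one ddPCR well per patient, and CTC/clinical covariates. The
#' `truth` element records everything needed to score parameter recovery.
#'
#' @param config A [simulation_config()].
#' @param tumor_fractions Optional explicit patient tumor fractions
#'   (overrides the mixture; length defines the number of patients).
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `config`, `hbd_arm_profiles`, `patient_arm_profiles`, `methylation`,
#'   `ddpcr`, `clinical`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            tumor_fractions = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  hbd_arm <- simulate_hbd_arm_panel(config, seed = NULL)

  n <- if (is.null(tumor_fractions)) config$n_patients else length(tumor_fractions)
  log_vol <- stats::rnorm(n, config$volume_meanlog, config$volume_sdlog)
  volumes <- pmin(pmax(exp(log_vol), 1), 1000)
  if (is.null(tumor_fractions)) {
    z_vol <- (log_vol - config$volume_meanlog) / config$volume_sdlog
    tf <- draw_tumor_fractions(config, z_vol)
  } else {
    if (any(tumor_fractions < 0 | tumor_fractions >= 1)) {
      stop("tumor fractions must be in [0, 1)")
    }
    tf <- tumor_fractions
    # keep burden consistent with an imposed tumor-fraction grid
    ranks <- rank(tf, ties.method = "first")
    volumes <- sort(volumes)[ranks]
  }
  ids <- sprintf("patient_%02d", seq_len(n))

  cna <- lapply(seq_len(n), function(i) simulate_cna_spec(config))
  names(cna) <- ids
  pat_arm <- lapply(seq_len(n), function(i) {
    simulate_patient_arm_profile(tf[i], cna[[i]], config, sample_id = ids[i])
  })

  meth <- simulate_methylation(config, tumor_fractions = tf, seed = NULL)

  copies <- stats::rlnorm(n, config$cfdna_copies_meanlog,
                          config$cfdna_copies_sdlog)
  ddpcr <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- simulate_ddpcr(tf[i], copies[i], config, sample_id = ids[i])
    data.frame(sample_id = a$sample_id, assay = a$assay_name,
               mutant_positive = a$mutant_positive,
               wildtype_positive = a$wildtype_positive,
               total_droplets = a$total_droplets, stringsAsFactors = FALSE)
  }))

  clinical <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_ctc_and_clinical(volumes[i], config, patient_id = ids[i])
  }))

  structure(
    list(config = config,
         hbd_arm_profiles = hbd_arm,
         patient_arm_profiles = pat_arm,
         methylation = meth,
         ddpcr = ddpcr,
         clinical = clinical,
         truth = list(
           tumor_fractions = stats::setNames(tf, ids),
           tumor_volumes = stats::setNames(volumes, ids),
           cfdna_copies = stats::setNames(copies, ids),
           cna = cna,
           true_dmr_ids = attr(meth, "true_dmr_ids")
         )),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$patient_arm_profiles), "patients,",
      length(x$hbd_arm_profiles), "arm-panel donors,",
      sum(x$methylation$groups == "HBD"), "methylation donors,",
      nrow(x$methylation$counts), "regions\n")
  invisible(x)
}
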