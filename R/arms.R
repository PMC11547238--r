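#' Autosomal chromosome-arm table (GRCh38)
#'
#' Static table of the 39 autosomal chromosome arms used for arm-level
#' aneuploidy analysis. The short arms of the five acrocentric chromosomes
#' (13p, 14p, 15p, 21p, 22p) are excluded: they consist almost entirely of
#' repetitive rDNA and carry no usable LINE-1 amplicon signal. Lengths are
#' approximate arm spans in megabases (chromosome split at the centromere
#' midpoint) and serve as the default baseline for the expected share of
#' genome-wide reads mapping to each arm.
#'
#' @return A `data.frame` with columns `arm` (e.g. `"1p"`), `chrom`
#'   (integer 1-22) and `length_mb` (numeric, megabases).
#' @examples
#' arms <- autosomal_arms()
#' nrow(arms) # 39
#' @export
autosomal_arms <- function() {
  # chromosome length and centromere midpoint, GRCh38, Mb
  chrom_mb <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35,
                145.14, 138.39, 133.80, 135.09, 133.28, 114.36, 107.04,
                101.99, 90.34, 83.26, 80.37, 58.62, 64.44, 46.71, 50.82)
  centro_mb <- c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0,
                 39.8, 53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5,
                 26.2, 28.1, 12.0, 15.0)
  acrocentric <- c(13L, 14L, 15L, 21L, 22L)
  out <- do.call(rbind, lapply(1:22, function(ch) {
    rows <- data.frame(
      arm = paste0(ch, c("p", "q")),
      chrom = ch,
      length_mb = c(centro_mb[ch], chrom_mb[ch] - centro_mb[ch]),
      stringsAsFactors = FALSE
    )
    if (ch %in% acrocentric) rows <- rows[2, , drop = FALSE]
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Baseline arm read-share vector
#'
#' Expected fraction of mapped reads per arm under a diploid genome,
#' proportional to arm length. Used as the generator baseline and as the
#' default arm universe.
#'
#' @param arms Character vector of arm identifiers; defaults to all 39
#'   autosomal arms.
#' @return Named numeric vector summing to 1.
#' @export
arm_baseline_fractions <- function(arms = autosomal_arms()$arm) {
  tab <- autosomal_arms()
  miss <- setdiff(arms, tab$arm)
  if (length(miss) > 0) {
    stop("unknown arm identifier(s): ", paste(miss, collapse = ", "))
  }
  len <- tab$length_mb[match(arms, tab$arm)]
  stats::setNames(len / sum(len), arms)
}
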