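# Small in-code fixtures shared across test files.

# Three-donor arm panel over three arms with hand-computable statistics.
toy_arm_panel <- function() {
  mk <- function(id, counts) {
    arm_count_profile(id, stats::setNames(as.integer(counts), c("1p", "1q", "2p")),
                      total_mapped_reads = 100000)
  }
  list(mk("HBD_1", c(20000, 50000, 30000)),
       mk("HBD_2", c(25000, 45000, 30000)),
       mk("HBD_3", c(30000, 40000, 30000)))
}

# Tiny region count matrix: 4 regions x (3 HBD + 5 patients).
toy_region_matrix <- function(counts = NULL) {
  ids <- c(paste0("HBD_0", 1:3), paste0("patient_0", 1:5))
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(rpois(4 * 8, 50), nrow = 4,
                     dimnames = list(paste0("r", 1:4), ids))
  }
  regions <- data.frame(region_id = rownames(counts),
                        chrom = 1:nrow(counts),
                        start = seq(0, by = 1000, length.out = nrow(counts)),
                        end = seq(500, by = 1000, length.out = nrow(counts)),
                        stringsAsFactors = FALSE)
  groups <- stats::setNames(rep(c("HBD", "patient"), c(3, 5)), ids)
  region_count_matrix(counts, regions, groups)
}

small_config <- function(...) {
  args <- list(n_regions = 500, n_true_dmrs = 40, reads_per_sample = 200000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
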