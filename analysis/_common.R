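# Shared study design for the analysis scripts (sourced by 01..06).
#
# The design mirrors a low-coverage marine population-genomic survey:
# eight sampling locations x 12 diploids at ~0.7X mean coverage, a genome of
# 5 x 2 Mb chromosomes (~50k SNPs), two large non-recombining inversion
# polymorphisms with location-specific haplotype-frequency clines, and one
# narrow (150 kb) outlier region separating a "spring-spawning" set of
# locations from a "winter-spawning" set. Big intermediates live under
# scratch/analysis/, result tables under results/analysis/.

suppressMessages(library(glscan))

SEED <- 101
SCRATCH <- "scratch/analysis"
RESULTS <- "results/analysis"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

LOCS <- sprintf("loc%02d", 1:8)
SPRING <- LOCS[1:3]
WINTER <- LOCS[4:6]

study_config <- function(seed = SEED) {
  sim_config(
    n_locations = 8, n_per_location = 12, n_chromosomes = 5,
    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.005,
    coverage_mean = 0.7, error_rate = 0.01, seed = seed,
    inversions = list(
      inversion_spec("chr01", 4e5, 14e5, 200,
                     stats::setNames(seq(0.15, 0.85, length.out = 8), LOCS)),
      inversion_spec("chr02", 6e5, 11e5, 120,
                     stats::setNames(rep(c(0.2, 0.7), 4), LOCS))),
    outlier_regions = list(
      outlier_spec("chr03", 9e5, 10.5e5, SPRING, WINTER, 0.6)))
}

CHROM_LENGTHS <- stats::setNames(rep(2e6, 5), sprintf("chr%02d", 1:5))

msg <- function(...) cat(sprintf(...), "\n")
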