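#!/usr/bin/env Rscript
# Simulate the study: low-coverage read counts with known truth.
source("analysis/_common.R")

cfg <- study_config()
d <- simulate_dataset(cfg)

msg("simulated %d sites x %d individuals across %d chromosomes",
    nrow(d$sites), nrow(d$manifest), cfg$n_chromosomes)
msg("per-individual coverage: mean %.2fX, range %.2f-%.2fX",
    mean(d$lambda), min(d$lambda), max(d$lambda))

write_counts(d$counts, d$sites, d$manifest$individual,
             file.path(SCRATCH, "counts.tsv.gz"))
write_manifest(d$manifest, file.path(SCRATCH, "manifest.tsv"))
tr <- d$truth$regions
write_bed(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                     name = tr$name),
          file.path(SCRATCH, "truth_regions.bed"))
inv <- as.data.frame(d$truth$inv_dosage)
inv$individual <- d$manifest$individual
data.table::fwrite(inv, file.path(SCRATCH, "truth_inversions.tsv"), sep = "\t")

summ <- data.frame(
  quantity = c("n_sites", "n_individuals", "n_locations", "mean_coverage",
               "min_coverage", "max_coverage"),
  value = c(nrow(d$sites), nrow(d$manifest), cfg$n_locations,
            round(mean(d$lambda), 3), round(min(d$lambda), 3),
            round(max(d$lambda), 3)))
data.table::fwrite(summ, file.path(RESULTS, "01_simulation_summary.tsv"),
                   sep = "\t")
msg("wrote %s", file.path(RESULTS, "01_simulation_summary.tsv"))
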