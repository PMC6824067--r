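#!/usr/bin/env Rscript
# Genotype likelihoods, allele-frequency EM and SNP calling with the
# standard site filters (MAF >= 1%, LRT p <= 1e-6, >= 3 individuals with
# data per location, total depth <= 1000).
source("analysis/_common.R")

cc <- read_counts(file.path(SCRATCH, "counts.tsv.gz"))
man <- read_manifest(file.path(SCRATCH, "manifest.tsv"))
gl <- compute_gl(cc$counts, error_rate = 0.01, sites = cc$sites,
                 individuals = cc$individuals)

pops <- split(seq_len(nrow(man)), man$location)
snps <- apply_site_filters(cc$counts, gl, populations = pops, min_ind = 3,
                           max_total_depth = 1000, min_maf = 0.01,
                           snp_p_cutoff = 1e-6)
msg("retained %d of %d sites after filtering (%.1f%%)",
    nrow(snps), nrow(cc$sites), 100 * nrow(snps) / nrow(cc$sites))

gls <- gl_subset(gl, sites = snps$site)
# the simulator emits only A/C style biallelic sites; re-attach bases for the
# beagle export
gls$sites$major <- "A"; gls$sites$minor <- "C"
write_beagle(gls, file.path(SCRATCH, "genolike.beagle.gz"))
data.table::fwrite(as.data.frame(snps), file.path(SCRATCH, "snp_table.tsv"),
                   sep = "\t")

summ <- data.frame(
  quantity = c("n_input_sites", "n_retained_snps", "median_maf",
               "median_lrt_p"),
  value = c(nrow(cc$sites), nrow(snps), round(stats::median(snps$maf), 4),
            signif(stats::median(snps$p), 3)))
data.table::fwrite(summ, file.path(RESULTS, "02_snp_calling_summary.tsv"),
                   sep = "\t")
msg("wrote %s", file.path(RESULTS, "02_snp_calling_summary.tsv"))
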