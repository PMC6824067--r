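#!/usr/bin/env Rscript
# Population structure: pairwise weighted FST among the eight groups (28
# comparisons), classical MDS of the FST matrix, GL-based individual PCA,
# and 15-kb windowed FST scans for every comparison.
source("analysis/_common.R")

gl <- read_beagle(file.path(SCRATCH, "genolike.beagle.gz"))
man <- read_manifest(file.path(SCRATCH, "manifest.tsv"))

res <- pairwise_fst_matrix(gl, man, by = "group", min_ind = 3,
                           return_components = TRUE)
write_matrix_tsv(res$fst, file.path(RESULTS, "03_fst_matrix_groups.tsv"))
msg("pairwise FST among %d groups: median %.4f, max %.4f",
    nrow(res$fst), stats::median(res$fst[upper.tri(res$fst)]),
    max(res$fst[upper.tri(res$fst)]))

mds <- classical_mds(res$fst, k = 2)
msg("MDS axis 1 explains %.1f%% of the FST variation",
    100 * mds$var_explained[1])
data.table::fwrite(data.frame(label = rownames(mds$points), mds$points,
                              check.names = FALSE),
                   file.path(RESULTS, "03_mds_coords.tsv"), sep = "\t")

pca <- gl_covariance_pca(gl, K = 2, n_iter = 10)
sc <- data.frame(individual = rownames(pca$scores), location = man$location,
                 group = man$group, pca$scores[, 1:4], check.names = FALSE)
data.table::fwrite(sc, file.path(RESULTS, "03_pca_scores.tsv"), sep = "\t")
msg("individual PCA: PC1 %.1f%%, PC2 %.1f%%",
    100 * pca$var_explained[1], 100 * pca$var_explained[2])

win_dir <- file.path(RESULTS, "03_windows")
dir.create(win_dir, showWarnings = FALSE)
windows <- lapply(res$components, function(fc)
  windowed_stat(gl$sites[fc$site, ], 15000, min_sites = 10,
                alpha = fc$alpha, beta = fc$beta,
                chrom_lengths = CHROM_LENGTHS))
for (nm in names(windows))
  write_windows(windows[[nm]], file.path(win_dir, paste0(nm, ".tsv")))
msg("wrote %d windowed FST scans to %s", length(windows), win_dir)

# large intermediates for the downstream scripts
saveRDS(res, file.path(SCRATCH, "fst_components.rds"))
saveRDS(windows, file.path(SCRATCH, "windows.rds"))
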