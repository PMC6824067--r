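#!/usr/bin/env Rscript
# Neutral SNP set (inversions +/- 1 Mb plus the top 5% of 15-kb windows in
# all 28 comparisons), neutral-set FST/MDS, 99.9th-percentile outlier
# windows, and peak-SNP selection within each merged outlier locus.
source("analysis/_common.R")

gl <- read_beagle(file.path(SCRATCH, "genolike.beagle.gz"))
res <- readRDS(file.path(SCRATCH, "fst_components.rds"))
windows <- readRDS(file.path(SCRATCH, "windows.rds"))
regions <- read_bed(file.path(SCRATCH, "truth_regions.bed"))
inv_regions <- regions[grepl("^inv", regions$name), , drop = FALSE]

ns <- build_neutral_set(windows, gl$sites, inversions = inv_regions,
                        buffer = 1e6, top_fraction = 0.05, min_sites = 10)
msg("neutral set: %d of %d SNPs retained", length(ns$retained),
    nrow(gl$sites))

labs <- rownames(res$fst)
nfst <- res$fst
for (a in seq_len(length(labs) - 1)) for (b in (a + 1):length(labs)) {
  fc <- res$components[[paste(labs[a], labs[b], sep = "__")]]
  nfst[a, b] <- nfst[b, a] <- weighted_fst(fc, fc$site %in% ns$retained)
}
write_matrix_tsv(nfst, file.path(RESULTS, "05_fst_matrix_neutral.tsv"))
msg("neutral-set FST: median %.4f (full-set median %.4f)",
    stats::median(nfst[upper.tri(nfst)]),
    stats::median(res$fst[upper.tri(res$fst)]))

all_regions <- list()
for (nm in names(windows)) {
  reg <- suppressWarnings(
    detect_outlier_windows(windows[[nm]], percentile = 99.9, merge_gap = 1,
                           exclude = inv_regions))
  if (nrow(reg)) {
    reg$comparison <- nm
    all_regions[[nm]] <- as.data.frame(reg)
  }
}
regions_df <- do.call(rbind, all_regions)
rownames(regions_df) <- NULL
data.table::fwrite(regions_df, file.path(RESULTS, "05_outlier_windows.tsv"),
                   sep = "\t")
msg("%d outlier windows across %d comparisons", nrow(regions_df),
    length(unique(regions_df$comparison)))

# collapse overlapping regions into loci and select peak SNPs
loci <- list()
for (ch in unique(regions_df$chrom)) {
  rr <- regions_df[regions_df$chrom == ch, , drop = FALSE]
  rr <- rr[order(rr$start), , drop = FALSE]
  cs <- rr$start[1]; ce <- rr$end[1]
  for (i in seq_len(nrow(rr))[-1]) {
    if (rr$start[i] <= ce) ce <- max(ce, rr$end[i])
    else {
      loci[[length(loci) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
      cs <- rr$start[i]; ce <- rr$end[i]
    }
  }
  loci[[length(loci) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
}
loci <- do.call(rbind, loci)
loci$name <- sprintf("peak_%s_%d", loci$chrom, as.integer(loci$start))

peaks <- list()
for (i in seq_len(nrow(loci))) {
  in_reg <- which(gl$sites$chrom == loci$chrom[i] &
                    gl$sites$pos >= loci$start[i] & gl$sites$pos < loci$end[i])
  src <- regions_df[regions_df$chrom == loci$chrom[i] &
                      regions_df$start < loci$end[i] &
                      regions_df$end > loci$start[i], , drop = FALSE]
  comps <- unique(src$comparison)
  persnp <- vapply(comps, function(nm) {
    fc <- res$components[[nm]]
    v <- rep(-Inf, length(in_reg))
    m <- match(in_reg, fc$site)
    ok <- !is.na(m) & fc$beta[ifelse(is.na(m), 1, m)] > 0
    v[ok] <- fc$alpha[m[ok]] / fc$beta[m[ok]]
    v
  }, numeric(length(in_reg)))
  persnp <- matrix(persnp, ncol = length(comps), dimnames = list(NULL, comps))
  mean_fst <- vapply(comps, function(nm) {
    wv <- windows[[nm]]
    m <- wv$chrom == loci$chrom[i] & wv$start < loci$end[i] &
      wv$end > loci$start[i] & !is.na(wv$value)
    if (any(m)) mean(wv$value[m]) else -Inf
  }, 0)
  sel <- suppressWarnings(
    select_peak_snps(gl$sites$pos[in_reg], persnp, mean_fst,
                     top_fraction = 0.01, min_snps = 10))
  peaks[[loci$name[i]]] <- data.frame(
    region = loci$name[i], comparison = sel$comparison,
    chrom = gl$sites$chrom[in_reg[sel$snps]],
    pos = gl$sites$pos[in_reg[sel$snps]])
}
pk <- do.call(rbind, peaks)
write_bed(loci[, c("chrom", "start", "end", "name")],
          file.path(RESULTS, "05_outlier_loci.bed"))
data.table::fwrite(pk, file.path(RESULTS, "05_peak_snps.tsv"), sep = "\t")
msg("%d outlier loci; %d peak SNPs selected", nrow(loci), nrow(pk))

saveRDS(list(neutral = ns, loci = loci, peaks = peaks),
        file.path(SCRATCH, "scan.rds"))
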