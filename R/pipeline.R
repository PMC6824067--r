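#' Full-pipeline configuration
#'
#' Bundles the simulation configuration with every analysis threshold so a
#' whole run is reproducible from one object and one seed. Defaults follow
#' the standard low-coverage workflow: MAF >= 1%, SNP LRT p <= 1e-6, minimum
#' three individuals with data per population, total depth <= 1000, 15-kb
#' FST windows, 5-kb diversity windows, neutral set = top 5% of windows per
#' comparison plus inversions +/- 1 Mb, 99.9th-percentile outlier windows,
#' top 1% peak SNPs.
#'
#' @param sim a [sim_config()].
#' @param min_maf,snp_p,min_ind,min_ind_frac,max_total_depth site filters
#'   (see [apply_site_filters()]).
#' @param fst_window,theta_window window sizes in bp.
#' @param fst_window_min_sites,theta_window_min_sites minimum sites per
#'   window.
#' @param neutral_top_fraction,neutral_buffer neutral-set parameters.
#' @param outlier_percentile,merge_gap outlier-window parameters.
#' @param peak_top_fraction,peak_min_snps peak-SNP selection.
#' @param pca_K,pca_iter individual-PCA parameters.
#' @param gff optional GFF3 path for gene annotation of outlier regions.
#' @param seed master seed (defaults to the simulation seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, min_maf = 0.01, snp_p = 1e-6, min_ind = 3L,
                            min_ind_frac = NULL, max_total_depth = 1000,
                            fst_window = 15000L, theta_window = 5000L,
                            fst_window_min_sites = 10L,
                            theta_window_min_sites = 5L,
                            neutral_top_fraction = 0.05, neutral_buffer = 1e6,
                            outlier_percentile = 99.9, merge_gap = 1L,
                            peak_top_fraction = 0.01, peak_min_snps = 10L,
                            pca_K = 2L, pca_iter = 10L, gff = NULL,
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  if (snp_p <= 0 || snp_p > 1) stop("snp_p must lie in (0, 1]")
  if (max_total_depth <= 0) stop("max_total_depth must be positive")
  if (outlier_percentile < 0 || outlier_percentile > 100)
    stop("outlier_percentile must lie in [0, 100]")
  if (neutral_top_fraction < 0 || neutral_top_fraction > 1)
    stop("neutral_top_fraction must lie in [0, 1]")
  if (peak_top_fraction <= 0 || peak_top_fraction > 1)
    stop("peak_top_fraction must lie in (0, 1]")
  if (fst_window < 1 || theta_window < 1) stop("window sizes must be positive")
  if (!is.null(gff) && !file.exists(gff)) stop("gff file does not exist: ", gff)
  structure(c(list(sim = sim), as.list(environment())[-1]),
            class = "pipeline_config")
}

# run one stage with timing and failure attribution
run_stage <- function(name, state, fn) {
  t0 <- proc.time()[["elapsed"]]
  outputs <- tryCatch(fn(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  data.frame(stage = name,
             seconds = round(proc.time()[["elapsed"]] - t0, 2),
             outputs = paste(basename(outputs), collapse = ";"),
             md5 = paste(unname(tools::md5sum(outputs)), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run the complete analysis pipeline
#'
#' Executes every stage in dependency order under one output directory:
#' simulate -> genotype likelihoods + SNP calling -> population structure
#' (pairwise FST, MDS, individual PCA) -> inversion genotyping -> windowed
#' FST scans -> neutral SNP set -> outlier regions (+ peak SNPs, optional
#' gene annotation) -> windowed Tajima's D and per-SNP dxy -> rescaled PC1
#' heat map. All outputs are plain text; reruns with the same configuration
#' and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the run manifest: data.frame with one row per stage (`stage`,
#'   `seconds`, `outputs`, `md5`), invisibly also written to
#'   `run_manifest.tsv`. The in-memory results are attached as attribute
#'   `state`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  st <- new.env(parent = emptyenv())
  manifest_rows <- list()
  add <- function(row) manifest_rows[[length(manifest_rows) + 1L]] <<- row

  # log every threshold actually applied
  params <- config[setdiff(names(config), c("sim", "gff"))]
  params <- params[!vapply(params, is.null, TRUE)]
  pdf_ <- data.frame(parameter = names(params),
                     value = vapply(params, function(x) format(x, digits = 15), ""))
  data.table::fwrite(pdf_, fp("params.tsv"), sep = "\t", quote = FALSE)

  add(run_stage("simulate", st, function() {
    st$sim <- simulate_dataset(config$sim)
    write_counts(st$sim$counts, st$sim$sites, st$sim$manifest$individual,
                 fp("counts.tsv.gz"))
    write_manifest(st$sim$manifest, fp("manifest.tsv"))
    tr <- st$sim$truth$regions
    if (nrow(tr)) write_bed(data.frame(chrom = tr$chrom, start = tr$start,
                                       end = tr$end, name = tr$name),
                            fp("truth_regions.bed"))
    else cat("", file = fp("truth_regions.bed"))
    inv <- as.data.frame(st$sim$truth$inv_dosage)
    inv$individual <- st$sim$manifest$individual
    data.table::fwrite(inv, fp("truth_inversions.tsv"), sep = "\t")
    data.table::fwrite(data.frame(individual = st$sim$manifest$individual,
                                  lambda = st$sim$lambda),
                       fp("truth_coverage.tsv"), sep = "\t")
    c(fp("counts.tsv.gz"), fp("manifest.tsv"), fp("truth_regions.bed"),
      fp("truth_inversions.tsv"), fp("truth_coverage.tsv"))
  }))

  add(run_stage("genotype_likelihoods", st, function() {
    sim <- st$sim
    st$gl_all <- compute_gl(sim$counts, config$sim$error_rate, sim$sites,
                            sim$manifest$individual)
    pops <- split(seq_len(nrow(sim$manifest)), sim$manifest$location)
    st$snps <- apply_site_filters(sim$counts, st$gl_all, populations = pops,
                                  min_ind = config$min_ind,
                                  min_ind_frac = config$min_ind_frac,
                                  max_total_depth = config$max_total_depth,
                                  min_maf = config$min_maf,
                                  snp_p_cutoff = config$snp_p)
    st$gl <- gl_subset(st$gl_all, sites = st$snps$site)
    write_beagle(st$gl, fp("genolike.beagle.gz"))
    data.table::fwrite(as.data.frame(st$snps), fp("snp_table.tsv"), sep = "\t")
    c(fp("genolike.beagle.gz"), fp("snp_table.tsv"))
  }))

  add(run_stage("structure", st, function() {
    man <- st$sim$manifest
    res <- pairwise_fst_matrix(st$gl, man, by = "group",
                               min_ind = config$min_ind,
                               min_ind_frac = config$min_ind_frac,
                               return_components = TRUE)
    st$fst_group <- res
    write_matrix_tsv(res$fst, fp("fst_matrix_groups.tsv"))
    mds <- classical_mds(res$fst, k = min(2L, nrow(res$fst) - 1L))
    st$mds <- mds
    data.table::fwrite(data.frame(label = rownames(mds$points),
                                  mds$points, check.names = FALSE),
                       fp("mds_coords.tsv"), sep = "\t")
    st$pca <- gl_covariance_pca(st$gl, K = config$pca_K,
                                n_iter = config$pca_iter)
    sc <- data.frame(individual = rownames(st$pca$scores),
                     location = man$location, group = man$group,
                     st$pca$scores[, 1:min(4, ncol(st$pca$scores))],
                     check.names = FALSE)
    data.table::fwrite(sc, fp("pca_scores.tsv"), sep = "\t")
    c(fp("fst_matrix_groups.tsv"), fp("mds_coords.tsv"), fp("pca_scores.tsv"))
  }))

  add(run_stage("inversions", st, function() {
    tr <- st$sim$truth$regions
    invr <- tr[tr$type == "inversion", , drop = FALSE]
    outs <- character(0)
    if (nrow(invr)) {
      calls <- do.call(rbind, lapply(seq_len(nrow(invr)), function(i)
        genotype_inversion(st$gl, invr[i, ], region_id = invr$name[i],
                           K = config$pca_K, n_iter = config$pca_iter)))
      st$inv_calls <- calls
      data.table::fwrite(calls, fp("inversion_calls.tsv"), sep = "\t")
      hf <- haplotype_frequencies(calls, st$sim$manifest)
      st$hap_freq <- hf
      write_matrix_tsv(hf$freq, fp("haplotype_frequencies.tsv"))
      outs <- c(fp("inversion_calls.tsv"), fp("haplotype_frequencies.tsv"))
      if (nrow(invr) >= 2) {
        ld <- inter_inversion_ld(calls, st$sim$manifest)
        if (!is.null(ld)) {
          data.table::fwrite(ld, fp("inversion_ld.tsv"), sep = "\t")
          outs <- c(outs, fp("inversion_ld.tsv"))
        }
        if (nrow(hf$freq) >= 3) {
          fpc <- frequency_pca(hf$freq)
          data.table::fwrite(data.frame(location = rownames(fpc$scores),
                                        fpc$scores, check.names = FALSE),
                             fp("haplotype_freq_pca.tsv"), sep = "\t")
          outs <- c(outs, fp("haplotype_freq_pca.tsv"))
        }
      }
    } else {
      cat("", file = fp("inversion_calls.tsv"))
      outs <- fp("inversion_calls.tsv")
    }
    outs
  }))

  add(run_stage("windowed_fst", st, function() {
    chrom_lengths <- stats::setNames(rep(config$sim$chrom_length,
                                         config$sim$n_chromosomes),
                                     config$sim$chroms)
    st$chrom_lengths <- chrom_lengths
    comps <- st$fst_group$components
    st$windows <- lapply(comps, function(fc) {
      sites <- st$gl$sites[fc$site, , drop = FALSE]
      windowed_stat(sites, config$fst_window,
                    min_sites = config$fst_window_min_sites,
                    alpha = fc$alpha, beta = fc$beta,
                    chrom_lengths = chrom_lengths)
    })
    dir.create(fp("windows"), showWarnings = FALSE)
    outs <- vapply(names(st$windows), function(nm) {
      write_windows(st$windows[[nm]], fp("windows", paste0(nm, ".tsv")))
    }, "")
    unname(outs)
  }))

  add(run_stage("neutral_set", st, function() {
    tr <- st$sim$truth$regions
    invr <- tr[tr$type == "inversion", , drop = FALSE]
    ns <- build_neutral_set(st$windows, st$gl$sites, inversions = invr,
                            buffer = config$neutral_buffer,
                            top_fraction = config$neutral_top_fraction,
                            min_sites = config$fst_window_min_sites)
    st$neutral <- ns
    data.table::fwrite(data.frame(chrom = st$gl$sites$chrom[ns$retained],
                                  pos = st$gl$sites$pos[ns$retained]),
                       fp("neutral_snps.tsv"), sep = "\t")
    # neutral-set pairwise FST reuses the per-pair components
    labs <- rownames(st$fst_group$fst)
    nfst <- st$fst_group$fst
    for (a in seq_len(length(labs) - 1)) for (b in (a + 1):length(labs)) {
      fc <- st$fst_group$components[[paste(labs[a], labs[b], sep = "__")]]
      keep <- fc$site %in% ns$retained
      nfst[a, b] <- nfst[b, a] <- weighted_fst(fc, keep)
    }
    st$fst_neutral <- nfst
    write_matrix_tsv(nfst, fp("fst_matrix_neutral.tsv"))
    c(fp("neutral_snps.tsv"), fp("fst_matrix_neutral.tsv"))
  }))

  add(run_stage("outlier_scan", st, function() {
    tr <- st$sim$truth$regions
    invr <- tr[tr$type == "inversion", , drop = FALSE]
    genes <- if (!is.null(config$gff)) read_gff3_genes(config$gff) else NULL
    all_regions <- list()
    for (nm in names(st$windows)) {
      reg <- detect_outlier_windows(st$windows[[nm]],
                                    percentile = config$outlier_percentile,
                                    merge_gap = config$merge_gap,
                                    exclude = invr)
      if (nrow(reg)) {
        reg$comparison <- nm
        all_regions[[nm]] <- as.data.frame(reg)
      }
    }
    regions <- if (length(all_regions)) do.call(rbind, all_regions) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 n_windows = integer(), max_value = numeric(),
                 comparison = character())
    rownames(regions) <- NULL
    # merge regions found in several comparisons into unique loci
    st$outlier_regions <- regions
    peaks <- list()
    if (nrow(regions)) {
      # collapse overlapping intervals per chromosome
      loci <- list()
      for (ch in unique(regions$chrom)) {
        rr <- regions[regions$chrom == ch, , drop = FALSE]
        rr <- rr[order(rr$start), , drop = FALSE]
        cs <- rr$start[1]; ce <- rr$end[1]
        for (i in seq_len(nrow(rr))[-1]) {
          if (rr$start[i] <= ce) ce <- max(ce, rr$end[i])
          else { loci[[length(loci) + 1L]] <- c(ch, cs, ce); cs <- rr$start[i]; ce <- rr$end[i] }
        }
        loci[[length(loci) + 1L]] <- c(ch, cs, ce)
      }
      loci <- data.frame(chrom = vapply(loci, `[`, "", 1),
                         start = as.numeric(vapply(loci, `[`, "", 2)),
                         end = as.numeric(vapply(loci, `[`, "", 3)),
                         stringsAsFactors = FALSE)
      loci$name <- sprintf("peak_%s_%d", loci$chrom, as.integer(loci$start))
      st$outlier_loci <- loci
      # per-SNP FST by comparison (site components), peak SNP selection
      for (i in seq_len(nrow(loci))) {
        in_reg <- which(st$gl$sites$chrom == loci$chrom[i] &
                          in_interval(st$gl$sites$pos, loci$start[i], loci$end[i]))
        src <- regions[regions$chrom == loci$chrom[i] &
                         regions$start < loci$end[i] &
                         regions$end > loci$start[i], , drop = FALSE]
        comps <- unique(src$comparison)
        persnp <- sapply(comps, function(nm) {
          fc <- st$fst_group$components[[nm]]
          v <- rep(NA_real_, length(in_reg))
          m <- match(in_reg, fc$site)
          ok <- !is.na(m)
          v[ok] <- ifelse(fc$beta[m[ok]] > 0,
                          fc$alpha[m[ok]] / fc$beta[m[ok]], NA_real_)
          v
        })
        persnp <- matrix(persnp, ncol = length(comps),
                         dimnames = list(NULL, comps))
        persnp[is.na(persnp)] <- -Inf
        mean_fst <- vapply(comps, function(nm) {
          wv <- st$windows[[nm]]
          m <- wv$chrom == loci$chrom[i] & wv$start < loci$end[i] &
            wv$end > loci$start[i] & !is.na(wv$value)
          if (any(m)) mean(wv$value[m]) else -Inf
        }, 0)
        sel <- select_peak_snps(st$gl$sites$pos[in_reg], persnp, mean_fst,
                                top_fraction = config$peak_top_fraction,
                                min_snps = config$peak_min_snps)
        peaks[[loci$name[i]]] <- list(comparison = sel$comparison,
                                      snps = in_reg[sel$snps])
      }
    } else st$outlier_loci <- NULL
    st$peaks <- peaks
    outs <- fp("outlier_regions.tsv")
    data.table::fwrite(regions, outs, sep = "\t")
    if (!is.null(st$outlier_loci)) {
      loci_out <- st$outlier_loci
      if (!is.null(genes))
        loci_out <- annotate_regions(loci_out, st$windows[[1]][0, ], genes)
      write_bed(loci_out[, c("chrom", "start", "end", "name")],
                fp("outlier_loci.bed"))
      pk <- do.call(rbind, lapply(names(peaks), function(nm)
        data.frame(region = nm, comparison = peaks[[nm]]$comparison,
                   chrom = st$gl$sites$chrom[peaks[[nm]]$snps],
                   pos = st$gl$sites$pos[peaks[[nm]]$snps])))
      data.table::fwrite(pk, fp("peak_snps.tsv"), sep = "\t")
      outs <- c(outs, fp("outlier_loci.bed"), fp("peak_snps.tsv"))
    }
    outs
  }))

  add(run_stage("diversity", st, function() {
    man <- st$sim$manifest
    groups <- split(seq_len(nrow(man)), man$group)
    dir.create(fp("theta"), showWarnings = FALSE)
    outs <- character(0)
    st$tajima <- list()
    for (g in names(groups)) {
      saf <- st$fst_group$saf[[g]]
      td <- windowed_tajima(saf, st$gl$sites, window_size = config$theta_window,
                            min_sites = config$theta_window_min_sites,
                            chrom_lengths = st$chrom_lengths)
      st$tajima[[g]] <- td
      outs <- c(outs, write_windows(td, fp("theta", paste0(g, ".tsv"))))
    }
    # per-SNP dxy for each outlier locus in its most significant comparison
    if (length(st$peaks)) {
      dx <- list()
      for (nm in names(st$peaks)) {
        pk <- st$peaks[[nm]]
        pair <- strsplit(pk$comparison, "__", fixed = TRUE)[[1]]
        i1 <- groups[[pair[1]]]; i2 <- groups[[pair[2]]]
        loci <- st$outlier_loci[st$outlier_loci$name == nm, ]
        in_reg <- which(st$gl$sites$chrom == loci$chrom &
                          in_interval(st$gl$sites$pos, loci$start, loci$end))
        glr <- gl_subset(st$gl, sites = in_reg)
        f1 <- suppressWarnings(estimate_maf_em(glr, individuals = i1,
                                               fold = FALSE))$raw_f
        f2 <- suppressWarnings(estimate_maf_em(glr, individuals = i2,
                                               fold = FALSE))$raw_f
        ok <- !is.na(f1) & !is.na(f2)
        dx[[nm]] <- data.frame(region = nm, comparison = pk$comparison,
                               chrom = st$gl$sites$chrom[in_reg][ok],
                               pos = st$gl$sites$pos[in_reg][ok],
                               dxy = dxy_snp(f1[ok], f2[ok]))
      }
      st$dxy <- do.call(rbind, dx)
      data.table::fwrite(st$dxy, fp("dxy_persnp.tsv"), sep = "\t")
      outs <- c(outs, fp("dxy_persnp.tsv"))
    }
    outs
  }))

  add(run_stage("heatmap", st, function() {
    tr <- st$sim$truth$regions
    invr <- tr[tr$type == "inversion", , drop = FALSE]
    region_snps <- list()
    for (i in seq_len(nrow(invr))) {
      idx <- which(st$gl$sites$chrom == invr$chrom[i] &
                     in_interval(st$gl$sites$pos, invr$start[i], invr$end[i]))
      if (length(idx) >= 2) region_snps[[invr$name[i]]] <- idx
    }
    for (nm in names(st$peaks))
      if (length(st$peaks[[nm]]$snps) >= 2)
        region_snps[[nm]] <- st$peaks[[nm]]$snps
    if (!length(region_snps)) {
      cat("", file = fp("heatmap.tsv"))
      return(fp("heatmap.tsv"))
    }
    hm <- region_pc1_heatmap(st$gl, region_snps, st$sim$manifest,
                             K = config$pca_K, n_iter = config$pca_iter)
    st$heatmap <- hm
    write_matrix_tsv(hm, fp("heatmap.tsv"))
    fp("heatmap.tsv")
  }))

  manifest <- do.call(rbind, manifest_rows)
  data.table::fwrite(manifest, fp("run_manifest.tsv"), sep = "\t")
  attr(manifest, "state") <- st
  invisible(manifest)
}
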