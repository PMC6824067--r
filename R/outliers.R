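#' Build the putatively neutral SNP set
#'
#' Removal set = (union over all pairwise comparisons of the top
#' `top_fraction` of 15-kb windows, ranked by windowed FST among windows
#' with at least `min_sites` sites) plus every inversion interval expanded
#' by `buffer` bp on each side. Retained SNPs are those intersecting none of
#' the removal intervals (all intervals 0-based half-open).
#'
#' @param windows_by_comparison named list of windowed-FST data.frames
#'   (`chrom`, `start`, `end`, `n_sites`, `value`), one per pairwise group
#'   comparison; a `NULL` entry is an error naming the missing comparisons.
#' @param snp_sites data.frame of SNPs (`chrom`, `pos`).
#' @param inversions data.frame of inversion intervals (`chrom`, `start`,
#'   `end`); may be empty.
#' @param buffer bp added on each side of every inversion (default 1e6).
#' @param top_fraction fraction of eligible windows removed per comparison
#'   (default 0.05); the top `ceiling(top_fraction * n_eligible)` windows by
#'   value are removed, ties broken by (value, chrom, start) order.
#' @param min_sites minimum sites for a window to enter the ranking
#'   (default 10).
#' @return list (class `neutral_set`): `retained` (indices into
#'   `snp_sites`), `removed` (indices), and `ledger` (data.frame of removal
#'   intervals with their source).
#' @export
build_neutral_set <- function(windows_by_comparison, snp_sites,
                              inversions = NULL, buffer = 1e6,
                              top_fraction = 0.05, min_sites = 10L) {
  miss <- names(windows_by_comparison)[vapply(windows_by_comparison, is.null, TRUE)]
  if (length(miss))
    stop("missing windowed FST for comparison(s): ", paste(miss, collapse = ", "))
  ledger <- list()
  for (nm in names(windows_by_comparison)) {
    w <- windows_by_comparison[[nm]]
    elig <- which(!is.na(w$value) & w$n_sites >= min_sites)
    if (!length(elig) || top_fraction <= 0) next
    k <- ceiling(top_fraction * length(elig))
    ord <- elig[order(-w$value[elig], w$chrom[elig], w$start[elig])]
    top <- ord[seq_len(k)]
    ledger[[length(ledger) + 1L]] <-
      data.frame(chrom = w$chrom[top], start = w$start[top], end = w$end[top],
                 source = nm, stringsAsFactors = FALSE)
  }
  if (!is.null(inversions) && nrow(inversions)) {
    ledger[[length(ledger) + 1L]] <-
      data.frame(chrom = inversions$chrom,
                 start = pmax(0, inversions$start - buffer),
                 end = inversions$end + buffer,
                 source = "inversion_buffer", stringsAsFactors = FALSE)
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               source = character())
  removed <- rep(FALSE, nrow(snp_sites))
  for (ch in unique(ledger$chrom)) {
    iv <- ledger[ledger$chrom == ch, ]
    on_ch <- which(snp_sites$chrom == ch)
    if (!length(on_ch)) next
    p <- snp_sites$pos[on_ch]
    hit <- rep(FALSE, length(p))
    for (i in seq_len(nrow(iv))) hit <- hit | in_interval(p, iv$start[i], iv$end[i])
    removed[on_ch] <- removed[on_ch] | hit
  }
  structure(list(retained = which(!removed), removed = which(removed),
                 ledger = ledger), class = "neutral_set")
}

#' Detect outlier windows in a windowed FST scan
#'
#' The threshold is the given percentile of non-missing window values
#' (linear interpolation between order statistics, the default quantile
#' definition); a window qualifies when its value is strictly greater than
#' the threshold. Windows overlapping `exclude` intervals (e.g. inversions)
#' are dropped before the percentile is computed. Qualifying windows on the
#' same chromosome separated by at most `merge_gap` windows are merged into
#' one region.
#'
#' @param windows windowed FST data.frame (`chrom`, `start`, `end`,
#'   `n_sites`, `value`).
#' @param percentile percentile threshold (default 99.9).
#' @param merge_gap maximum number of intervening windows to merge across
#'   (default 1).
#' @param exclude optional data.frame of intervals to drop first.
#' @return data.frame (class `outlier_regions`): `chrom`, `start`, `end`,
#'   `n_windows`, `max_value`; attribute `threshold`. Zero rows when nothing
#'   qualifies.
#' @export
detect_outlier_windows <- function(windows, percentile = 99.9, merge_gap = 1L,
                                   exclude = NULL) {
  w <- windows
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- rep(FALSE, nrow(w))
    for (i in seq_len(nrow(exclude)))
      drop <- drop | (w$chrom == exclude$chrom[i] &
                        overlaps(w$start, w$end, exclude$start[i], exclude$end[i]))
    w <- w[!drop, , drop = FALSE]
  }
  vals <- w$value[!is.na(w$value)]
  if (percentile >= 99.9 && length(vals) < 1000)
    warning("fewer than 1,000 non-missing windows: ", percentile,
            "th percentile threshold is unstable")
  if (!length(vals)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), max_value = numeric())
    attr(out, "threshold") <- NA_real_
    class(out) <- c("outlier_regions", "data.frame")
    return(out)
  }
  thr <- unname(stats::quantile(vals, percentile / 100, type = 7))
  qual <- w[!is.na(w$value) & w$value > thr, , drop = FALSE]
  qual <- qual[order(qual$chrom, qual$start), , drop = FALSE]
  regions <- list()
  if (nrow(qual)) {
    win_size <- stats::median(windows$end - windows$start)
    gap_bp <- (merge_gap + 1) * win_size
    cur <- qual[1, ]
    cur$n_windows <- 1L; cur$max_value <- cur$value
    for (i in seq_len(nrow(qual))[-1]) {
      row <- qual[i, ]
      if (row$chrom == cur$chrom && row$start - cur$end <= gap_bp - win_size + 1e-9) {
        cur$end <- row$end
        cur$n_windows <- cur$n_windows + 1L
        cur$max_value <- max(cur$max_value, row$value)
      } else {
        regions[[length(regions) + 1L]] <- cur
        cur <- row; cur$n_windows <- 1L; cur$max_value <- cur$value
      }
    }
    regions[[length(regions) + 1L]] <- cur
  }
  out <- if (length(regions)) {
    r <- do.call(rbind, regions)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               n_windows = r$n_windows, max_value = r$max_value,
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    n_windows = integer(), max_value = numeric())
  attr(out, "threshold") <- thr
  class(out) <- c("outlier_regions", "data.frame")
  out
}

#' Annotate outlier regions with genes near window centers
#'
#' A gene is reported for a region iff its interval intersects
#' \[center - flank, center + flank) of any constituent window of the region
#' (default flank 15 kb: a 30-kb query window per 15-kb scan window).
#'
#' @param regions outlier regions (`chrom`, `start`, `end`).
#' @param windows the windowed scan the regions were called from (`chrom`,
#'   `start`, `end`); constituent windows are those inside a region.
#' @param genes gene table (`chrom`, `start`, `end`, `id`), 0-based
#'   half-open (see [read_gff3_genes()]).
#' @param flank half-width of the query window around each window center
#'   (default 15000).
#' @return `regions` with an added `genes` column (comma-separated ids,
#'   "" when none).
#' @export
annotate_regions <- function(regions, windows, genes, flank = 15000) {
  gene_col <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    wv <- windows[windows$chrom == regions$chrom[i] &
                    windows$start >= regions$start[i] &
                    windows$end <= regions$end[i], , drop = FALSE]
    if (!nrow(wv)) {
      wv <- regions[i, , drop = FALSE]
    }
    centers <- (wv$start + wv$end) / 2
    hit <- rep(FALSE, nrow(genes))
    gch <- genes$chrom == regions$chrom[i]
    for (ct in centers)
      hit <- hit | (gch & overlaps(genes$start, genes$end, ct - flank, ct + flank))
    gene_col[i] <- paste(genes$id[hit], collapse = ",")
  }
  regions$genes <- gene_col
  regions
}

#' Select peak SNPs within an outlier region
#'
#' The "most significant" comparison is the one with the largest mean
#' windowed FST over the region; within it, the `ceiling(top_fraction * n)`
#' SNPs with the highest per-SNP FST are selected (at least `min_snps`),
#' ties at the cutoff broken by ascending position. Regions with fewer than
#' `min_snps` SNPs return all SNPs with a warning.
#'
#' @param snp_pos positions of the region's SNPs.
#' @param persnp_fst matrix (length(snp_pos) x comparisons) of per-SNP FST
#'   (site alpha/beta ratios), columns named by comparison.
#' @param region_mean_fst named vector: mean windowed FST of the region in
#'   each comparison where it is an outlier.
#' @param top_fraction fraction of SNPs to keep (default 0.01).
#' @param min_snps minimum number selected (default 10).
#' @return list with `comparison` (the chosen one) and `snps` (indices into
#'   `snp_pos`, ascending position).
#' @export
select_peak_snps <- function(snp_pos, persnp_fst, region_mean_fst,
                             top_fraction = 0.01, min_snps = 10L) {
  comp <- names(region_mean_fst)[which.max(region_mean_fst)]
  n <- length(snp_pos)
  if (n < min_snps) {
    warning("region has only ", n, " SNPs (< min_snps = ", min_snps,
            "): selecting all")
    return(list(comparison = comp, snps = order(snp_pos)))
  }
  v <- persnp_fst[, comp]
  k <- max(min_snps, ceiling(top_fraction * n))
  sel <- order(-v, snp_pos)[seq_len(k)]
  list(comparison = comp, snps = sort(sel))
}

#' Rescale location scores to \[-1, 1\]
#'
#' Linear map x' = 2 (x - min) / (max - min) - 1, so the location with the
#' largest mean PC1 score gets exactly 1 and the smallest exactly -1. When
#' all scores are equal the rescaling is undefined: an all-zero vector is
#' returned with a warning.
#'
#' @param x numeric vector of per-location mean PC1 scores.
#' @return rescaled vector with max 1 and min -1 (given >= 2 distinct
#'   values).
#' @export
rescale_scores <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    warning("all location means equal: rescaling undefined, returning zeros")
    return(rep(0, length(x)))
  }
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Rescaled per-location PC1 heat-map matrix for outlier regions
#'
#' For each region, runs the GL-based individual PCA across all individuals
#' on the region's selected SNPs (all in-region SNPs for inversions; peak
#' SNPs for outlier regions), averages PC1 per sampling location, and
#' rescales the averages so the extreme locations get 1 and -1.
#'
#' @param gl a `gl_matrix` over all individuals.
#' @param region_snps named list: per region, integer site indices into
#'   `gl`.
#' @param manifest sample manifest.
#' @param K,n_iter passed to [gl_covariance_pca()].
#' @return matrix regions x locations of rescaled scores (attribute
#'   `var_explained`: PC1 variance fraction per region).
#' @export
region_pc1_heatmap <- function(gl, region_snps, manifest, K = 2, n_iter = 10L) {
  locations <- unique(manifest$location)
  out <- matrix(NA_real_, length(region_snps), length(locations),
                dimnames = list(names(region_snps), locations))
  ve <- numeric(length(region_snps))
  for (i in seq_along(region_snps)) {
    pca <- gl_covariance_pca(gl_subset(gl, sites = region_snps[[i]]),
                             K = K, n_iter = n_iter)
    pc1 <- pca$scores[, 1]
    loc <- manifest$location[match(gl$individuals, manifest$individual)]
    means <- tapply(pc1, factor(loc, levels = locations), mean)
    out[i, ] <- rescale_scores(as.numeric(means))
    ve[i] <- pca$var_explained[1]
  }
  attr(out, "var_explained") <- ve
  out
}
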