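#' Dosage correlation (LD) between two loci
#'
#' Rogers-Huff style LD from posterior expected dosages: signed Pearson
#' correlation r and r^2. Robust at low coverage because expected dosages
#' integrate over genotype uncertainty.
#'
#' @param d1,d2 expected dosages at the two loci (same individuals).
#' @param subset optional individual subset.
#' @return one-row data.frame: `r`, `r2`, `n`. `r` is `NA` when either locus
#'   has zero dosage variance.
#' @export
dosage_r2 <- function(d1, d2, subset = NULL) {
  if (!is.null(subset)) { d1 <- d1[subset]; d2 <- d2[subset] }
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  if (length(d1) < 3) stop("need at least 3 individuals with data at both loci")
  if (stats::var(d1) == 0 || stats::var(d2) == 0)
    return(data.frame(r = NA_real_, r2 = NA_real_, n = length(d1)))
  r <- stats::cor(d1, d2)
  data.frame(r = r, r2 = r^2, n = length(d1))
}

#' Detect a high-LD block on a chromosome
#'
#' Chooses an anchor SNP as the most-connected SNP in a thinned set (at most
#' one SNP per `thin_bp`; largest summed r^2 against the other thinned
#' SNPs), computes r^2 of every SNP on the chromosome against the anchor,
#' takes the per-`thin_bp`-bin maximum of that profile (inversions carry
#' within-orientation polymorphism, so only a subset of in-block SNPs tags
#' the orientation), smooths it with a running median, and reports the
#' maximal contiguous run of bins with smoothed r^2 >= `r2_threshold`
#' spanning at least `min_span` bp. Boundaries are the outermost SNPs with
#' r^2 >= threshold inside the qualifying bins.
#'
#' @param pos SNP positions (bp, sorted).
#' @param dosages individuals x SNPs matrix of expected dosages.
#' @param r2_threshold minimum smoothed r^2 (default 0.5).
#' @param min_span minimum block span in bp.
#' @param thin_bp thinning/bin interval (default 10000).
#' @param smooth_k running-median width (odd, default 5).
#' @return list with `start`, `end` (0-based half-open over the qualifying
#'   SNPs) and `n_snps` (qualifying SNPs inside the block), or `NULL` when
#'   no block qualifies.
#' @export
detect_ld_block <- function(pos, dosages, r2_threshold = 0.5, min_span = 1e5,
                            thin_bp = 1e4, smooth_k = 5L) {
  stopifnot(length(pos) == ncol(dosages))
  o <- order(pos); pos <- pos[o]; dosages <- dosages[, o, drop = FALSE]
  bin <- pos %/% thin_bp
  keep <- which(!duplicated(bin))
  if (length(keep) < 10) stop("fewer than 10 thinned SNPs on chromosome")
  thin <- dosages[, keep, drop = FALSE]
  v <- apply(thin, 2, stats::var)
  m <- length(keep)
  r2 <- matrix(0, m, m)
  cc <- suppressWarnings(stats::cor(thin[, v > 0, drop = FALSE]))
  r2[v > 0, v > 0] <- cc^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 0
  anchor_idx <- keep[which.max(colSums(r2))]

  av <- dosages[, anchor_idx]
  prof <- rep(0, length(pos))
  vv <- apply(dosages, 2, stats::var)
  ok <- vv > 0 & stats::var(av) > 0
  prof[ok] <- suppressWarnings(stats::cor(dosages[, ok, drop = FALSE], av))^2
  prof[is.na(prof)] <- 0
  prof[anchor_idx] <- 1

  bins <- sort(unique(bin))
  bmax <- vapply(bins, function(b) max(prof[bin == b]), 0)
  nb <- length(bmax)
  k <- min(smooth_k, nb - (1 - nb %% 2))
  sm <- if (k >= 3) stats::runmed(bmax, k = k) else bmax
  qual <- sm >= r2_threshold
  if (!any(qual)) return(NULL)
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  for (i in which(runs$values)) {
    s <- starts[i]; e <- ends[i]
    inb <- bin %in% bins[s:e] & prof >= r2_threshold
    if (!any(inb)) next
    span <- diff(range(pos[inb]))
    if (span >= min_span && (is.null(best) || span > best$span))
      best <- list(start = min(pos[inb]), end = max(pos[inb]) + 1L,
                   n_snps = sum(inb), span = span)
  }
  if (is.null(best)) return(NULL)
  best[c("start", "end", "n_snps")]
}

# deterministic 1-D 3-means: initialized at (min, midrange, max), Lloyd
# iterations, ties assigned to the lower-index cluster
kmeans3_1d <- function(x, max_iter = 100L) {
  if (length(unique(x)) < 3) stop("degenerate clustering: fewer than 3 distinct values")
  centers <- c(min(x), (min(x) + max(x)) / 2, max(x))
  assign <- rep(1L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    newassign <- max.col(-d, ties.method = "first")
    if (all(newassign == assign) && it > 1) break
    assign <- newassign
    for (k in 1:3) if (any(assign == k)) centers[k] <- mean(x[assign == k])
  }
  ord <- order(centers)
  list(cluster = match(assign, ord), centers = centers[ord])
}

# ratio of the smallest gap between (non-empty) adjacent cluster centers to
# the pooled within-cluster spread; small values mean 3-means merely carved
# up one continuous cloud of PC1 scores
cluster_separation <- function(x, km) {
  nonempty <- which(tabulate(km$cluster, 3) > 0)
  if (length(nonempty) < 2) return(0)
  wss <- sqrt(sum(vapply(1:3, function(k) {
    xs <- x[km$cluster == k]
    if (length(xs) > 1) sum((xs - km$centers[k])^2) else 0
  }, 0)) / length(x))
  min(diff(km$centers[nonempty])) / max(wss, 1e-12)
}

#' Genotype an inversion polymorphism by region-restricted PCA
#'
#' Runs the GL-based individual PCA on the SNPs inside the region; along PC1
#' individuals fall into three clusters (the two inversion homozygotes and
#' heterozygotes). PC1 scores are clustered by deterministic 1-D 3-means
#' (initial centers at min, midrange, max), clusters are ordered by
#' ascending PC1 center and labelled AA, AB, BB — the middle cluster is the
#' heterozygote class. Which homozygote is "A" is arbitrary (the ancestral
#' orientation is not identified), so comparisons to truth must be
#' label-swap aware. An empty middle cluster is allowed and reported.
#'
#' @param gl a `gl_matrix` over all individuals.
#' @param region list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param region_id identifier for the output (default "region").
#' @param K,n_iter passed to [gl_covariance_pca()].
#' @param min_separation minimum ratio of the smallest between-cluster-center
#'   gap to the pooled within-cluster spread; below it the PC1 scores are a
#'   single continuous cloud (e.g. all individuals share one orientation)
#'   and a degenerate-clustering error is raised. The default 3.8 separates
#'   monomorphic-region simulations (ratio ~ 2.5-3.3) from genuinely
#'   trimodal ones (>= 4) at 0.7X coverage.
#' @return data.frame (class `inversion_calls`): `individual`, `region`,
#'   `genotype` (AA/AB/BB), `pc1`; attribute `var_explained` for PC1.
#' @export
genotype_inversion <- function(gl, region, region_id = "region", K = 2,
                               n_iter = 10L, min_separation = 3.8) {
  idx <- which(gl$sites$chrom == region$chrom &
                 in_interval(gl$sites$pos, region$start, region$end))
  if (length(idx) < 20) stop("region contains fewer than 20 SNPs")
  pca <- gl_covariance_pca(gl_subset(gl, sites = idx), K = K, n_iter = n_iter)
  pc1 <- pca$scores[, 1]
  km <- kmeans3_1d(pc1)
  if (cluster_separation(pc1, km) < min_separation)
    stop("degenerate clustering: PC1 does not separate three inversion ",
         "genotype clusters in ", region_id)
  geno <- c("AA", "AB", "BB")[km$cluster]
  if (!any(km$cluster == 2))
    message("inversion ", region_id, ": empty heterozygote (middle) cluster")
  out <- data.frame(individual = gl$individuals, region = region_id,
                    genotype = geno, pc1 = unname(pc1),
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- pca$var_explained[1]
  class(out) <- c("inversion_calls", "data.frame")
  out
}

#' Haplotype frequencies per sampling location
#'
#' freq(B) = (2 nBB + nAB) / (2 n) per location and region.
#'
#' @param calls inversion calls (rows: individual x region) with columns
#'   `individual`, `region`, `genotype`.
#' @param manifest sample manifest.
#' @return list with `freq` (location x region matrix; `NA` for locations
#'   with no called individuals) and `counts` (long data.frame with nAA,
#'   nAB, nBB per cell).
#' @export
haplotype_frequencies <- function(calls, manifest) {
  loc <- manifest$location[match(calls$individual, manifest$individual)]
  if (any(is.na(loc))) stop("calls contain individuals absent from manifest")
  regions <- unique(calls$region)
  locations <- unique(manifest$location)
  freq <- matrix(NA_real_, length(locations), length(regions),
                 dimnames = list(locations, regions))
  counts <- list()
  for (r in regions) for (l in locations) {
    g <- calls$genotype[calls$region == r & loc == l]
    n <- length(g)
    cnt <- c(nAA = sum(g == "AA"), nAB = sum(g == "AB"), nBB = sum(g == "BB"))
    if (n > 0) freq[l, r] <- (2 * cnt["nBB"] + cnt["nAB"]) / (2 * n)
    counts[[length(counts) + 1L]] <-
      data.frame(location = l, region = r, nAA = cnt[[1]], nAB = cnt[[2]],
                 nBB = cnt[[3]], stringsAsFactors = FALSE)
  }
  list(freq = freq, counts = do.call(rbind, counts))
}

#' PCA biplot decomposition of the haplotype-frequency table
#'
#' Column-centered PCA (via [stats::prcomp()]) of the location x region
#' frequency matrix: location scores, per-region loadings (biplot arrows)
#' and variance explained. A constant column gets a zero loading.
#'
#' @param freq location x region matrix of freq(B).
#' @return list with `scores`, `loadings`, `var_explained`.
#' @export
frequency_pca <- function(freq) {
  if (nrow(freq) < 3 || ncol(freq) < 2)
    stop("need at least 3 locations and 2 regions")
  p <- stats::prcomp(freq, center = TRUE, scale. = FALSE)
  # drop zero-variance trailing components: their rotation vectors are
  # arbitrary orthonormal fill-in, which would give constant columns a
  # spurious unit loading
  keep <- p$sdev > max(p$sdev) * 1e-9
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, keep, drop = FALSE],
       loadings = p$rotation[, keep, drop = FALSE],
       var_explained = ve[keep])
}

#' Inter-chromosomal LD among inversions
#'
#' Inversion genotypes are mapped to dosages (AA = 0, AB = 1, BB = 2) and
#' signed r plus r^2 are computed for every region pair within each group
#' separately (avoiding population-structure-induced LD). A region
#' monomorphic within a group yields `NA`.
#'
#' @param calls inversion calls covering >= 2 regions.
#' @param manifest sample manifest (uses the `group` column).
#' @param min_n minimum individuals per group called at both regions
#'   (default 5).
#' @return data.frame: `group`, `region1`, `region2`, `r`, `r2`, `n`.
#' @export
inter_inversion_ld <- function(calls, manifest, min_n = 5L) {
  regions <- unique(calls$region)
  if (length(regions) < 2) stop("need calls for at least two regions")
  dos <- matrix(NA_real_, nrow(manifest), length(regions),
                dimnames = list(manifest$individual, regions))
  code <- c(AA = 0, AB = 1, BB = 2)
  for (i in seq_len(nrow(calls)))
    dos[calls$individual[i], calls$region[i]] <- code[[calls$genotype[i]]]
  out <- list()
  for (g in unique(manifest$group)) {
    ids <- manifest$individual[manifest$group == g]
    for (a in seq_len(length(regions) - 1)) for (b in (a + 1):length(regions)) {
      d1 <- dos[ids, a]; d2 <- dos[ids, b]
      ok <- !is.na(d1) & !is.na(d2)
      if (sum(ok) < min_n) next
      res <- dosage_r2(d1[ok], d2[ok])
      out[[length(out) + 1L]] <-
        data.frame(group = g, region1 = regions[a], region2 = regions[b],
                   r = res$r, r2 = res$r2, n = res$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
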