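#' Pairwise weighted FST matrix among populations
#'
#' For every pair of populations (sampling locations or groups), computes SAF
#' likelihoods, estimates the joint 2D SFS by EM, and takes the weighted
#' Hudson/Bhatia FST (ratio of summed per-site components) over the sites
#' where both populations have data for at least `min_ind` individuals.
#' Negative estimates are kept as-is (not clamped).
#'
#' @param gl a `gl_matrix` (already restricted to the retained SNP set).
#' @param manifest sample manifest (`individual`, `location`, `group`).
#' @param by `"location"` or `"group"`: which manifest column defines
#'   populations.
#' @param min_ind minimum individuals with data per population per site.
#' @param min_ind_frac optional fraction of the population size overriding
#'   `min_ind` (e.g. 2/3).
#' @param return_components also return per-pair per-site components and the
#'   site masks (needed for windowed scans).
#' @return symmetric matrix of weighted FST (class `fst_matrix`); when
#'   `return_components`, a list with `fst`, `components` (named list per
#'   pair: data.frame site/alpha/beta) and `saf` per population.
#' @export
pairwise_fst_matrix <- function(gl, manifest, by = c("location", "group"),
                                min_ind = 3L, min_ind_frac = NULL,
                                return_components = FALSE) {
  by <- match.arg(by)
  pops <- split(seq_len(nrow(manifest)), manifest[[by]])
  if (any(lengths(pops) == 0)) stop("population with 0 individuals")
  if (length(pops) < 2) stop("need at least two populations")
  labels <- names(pops)
  info <- gl_informative(gl)
  n_info <- sapply(pops, function(p) rowSums(info[, p, drop = FALSE]))
  thr <- vapply(pops, function(p)
    if (is.null(min_ind_frac)) min_ind else ceiling(min_ind_frac * length(p)),
    0)
  pop_ok <- sweep(n_info, 2, thr, ">=")

  saf <- lapply(labels, function(l) saf_site(gl_subset(gl, individuals = pops[[l]])))
  names(saf) <- labels

  K <- length(labels)
  fst <- matrix(0, K, K, dimnames = list(labels, labels))
  comps <- list()
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    mask <- pop_ok[, a] & pop_ok[, b]
    if (!any(mask)) stop("no shared sites for ", labels[a], " vs ", labels[b])
    s1 <- structure(unclass(saf[[a]])[mask, , drop = FALSE],
                    n_chrom = attr(saf[[a]], "n_chrom"),
                    class = c("saf_matrix", "matrix"))
    s2 <- structure(unclass(saf[[b]])[mask, , drop = FALSE],
                    n_chrom = attr(saf[[b]], "n_chrom"),
                    class = c("saf_matrix", "matrix"))
    q2 <- sfs_em(s1, s2)
    fc <- fst_components(s1, s2, q2)
    fst[a, b] <- fst[b, a] <- weighted_fst(fc)
    if (return_components) {
      fc$site <- which(mask)
      comps[[paste(labels[a], labels[b], sep = "__")]] <- fc
    }
  }
  class(fst) <- c("fst_matrix", "matrix")
  if (return_components) list(fst = fst, components = comps, saf = saf) else fst
}

#' Classical (Torgerson) multidimensional scaling of an FST matrix
#'
#' Double-centers the squared-distance matrix and eigendecomposes it
#' (via [stats::cmdscale()]); coordinates are the top-k eigenvectors scaled
#' by the square root of their eigenvalues, and variance explained per axis
#' is its eigenvalue over the sum of positive eigenvalues.
#'
#' @param d symmetric matrix of pairwise distances (e.g. weighted FST;
#'   negative entries are used as-is).
#' @param k number of output dimensions (< number of labels).
#' @return list with `points` (labels x k), `eig` and `var_explained`.
#' @export
classical_mds <- function(d, k = 2) {
  d <- unclass(d)
  if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-12))
    stop("input must be a symmetric distance matrix")
  if (k >= nrow(d)) stop("k must be smaller than the number of labels")
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- sum(fit$eig[fit$eig > 0])
  list(points = fit$points, eig = fit$eig,
       var_explained = fit$eig[seq_len(k)] / pos)
}

# deterministic eigendecomposition sign convention: the largest-magnitude
# entry of each eigenvector is made positive
fix_signs <- function(V) {
  s <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(V, 2, s, "*")
}

#' Individual covariance matrix and PCA from genotype likelihoods
#'
#' PCAngsd-style iterative estimator. Starting from the global allele
#' frequency per site, each iteration (1) computes posterior expected
#' dosages under the current per-individual site frequencies, (2) forms the
#' standardized covariance C = (1/S) sum_s (E\[g_s\] - 2 f_s)(E\[g_s\] -
#' 2 f_s)' / (2 f_s (1 - f_s)), and (3) predicts individual allele
#' frequencies from the top-K PCs (rank-K reconstruction of the standardized
#' dosage matrix, mapped back to frequency scale and clipped to
#' \[1/2n, 1 - 1/2n\]). With `K = 0` or `n_iter = 0` this reduces to the
#' single-pass standardized dosage-covariance estimator. Sites whose global
#' frequency estimate is 0 or 1 are dropped. Eigenvectors follow a
#' deterministic sign convention (largest-magnitude entry positive); scores
#' are scaled so that, for exact dosages, they match standard PCA scores of
#' the centered standardized dosage matrix.
#'
#' @param gl a `gl_matrix` (restricted to the SNP set of interest).
#' @param K number of PCs used for individual-frequency prediction
#'   (default 2).
#' @param n_iter maximum update iterations (default 10); iteration stops
#'   early when the covariance changes by less than `tol` (sup norm).
#' @param tol convergence tolerance on the covariance (default 1e-6).
#' @return list (class `gl_pca`): `cov` (n x n), `eigval` (non-increasing),
#'   `vectors`, `scores` (n x n, PC scores), `var_explained`, `n_sites`,
#'   `iterations`.
#' @export
gl_covariance_pca <- function(gl, K = 2, n_iter = 10L, tol = 1e-6) {
  n <- length(gl$individuals)
  if (n < 2) stop("need at least two individuals")
  f <- suppressWarnings(estimate_maf_em(gl, fold = FALSE))$raw_f
  keep <- !is.na(f) & f > 0 & f < 1
  if (!any(keep)) stop("no usable sites (all frequencies 0, 1 or undefined)")
  gl <- gl_subset(gl, sites = keep)
  f <- f[keep]
  S <- length(f)
  sd_s <- sqrt(2 * f * (1 - f))

  L0 <- exp(gl$logl[[1]]); L1 <- exp(gl$logl[[2]]); L2 <- exp(gl$logl[[3]])
  post_e <- function(P) { # P: S x n individual allele frequencies
    a0 <- (1 - P)^2 * L0; a1 <- 2 * P * (1 - P) * L1; a2 <- P^2 * L2
    (a1 + 2 * a2) / (a0 + a1 + a2)
  }
  covar_of <- function(E) {
    Z <- (E - 2 * f) / sd_s
    crossprod(Z) / S
  }

  P <- matrix(f, S, n)
  E <- post_e(P)
  C <- covar_of(E)
  iters <- 0L
  if (K > 0 && n_iter > 0) {
    lo <- 1 / (2 * n); hi <- 1 - lo
    for (it in seq_len(n_iter)) {
      Z <- (E - 2 * f) / sd_s
      eg <- eigen(C, symmetric = TRUE)
      U <- eg$vectors[, seq_len(min(K, n)), drop = FALSE]  # n x K
      # rank-K reconstruction of t(Z) (n x S): U U' t(Z)
      Zhat <- t(U %*% crossprod(U, t(Z)))
      P <- clip((Zhat * sd_s + 2 * f) / 2, lo, hi)
      E <- post_e(P)
      Cnew <- covar_of(E)
      delta <- max(abs(Cnew - C))
      C <- Cnew
      iters <- it
      if (delta < tol) break
    }
  }
  eg <- eigen(C, symmetric = TRUE)
  V <- fix_signs(eg$vectors)
  lam <- eg$values
  scores <- sweep(V, 2, sqrt(pmax(lam, 0) * S), "*")
  rownames(scores) <- rownames(V) <- gl$individuals
  rownames(C) <- colnames(C) <- gl$individuals
  structure(list(cov = C, eigval = lam, vectors = V, scores = scores,
                 var_explained = pmax(lam, 0) / sum(pmax(lam, 0)),
                 n_sites = S, iterations = iters),
            class = "gl_pca")
}

#' Randomly down-sample individuals per location
#'
#' Robustness helper mirroring a down-sampling check: keeps a seeded random
#' subset of at most `n` individuals per sampling location.
#'
#' @param manifest sample manifest.
#' @param n maximum individuals per location (default 8).
#' @param seed integer seed.
#' @return row indices into `manifest` of the kept individuals.
#' @export
downsample_manifest <- function(manifest, n = 8L, seed = 1L) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(manifest)), manifest$location),
                       function(i) if (length(i) <= n) i else sort(sample(i, n))))
  sort(unname(idx))
}

#' Enumerate pairwise population comparisons
#'
#' @param labels population/group labels (duplicates collapsed, order kept).
#' @return data.frame with columns `a`, `b` and `name` ("a__b"), one row per
#'   unordered pair.
#' @export
group_pairs <- function(labels) {
  u <- unique(labels)
  if (length(u) < 2) stop("need at least two groups")
  cmb <- utils::combn(u, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ],
             name = paste(cmb[1, ], cmb[2, ], sep = "__"),
             stringsAsFactors = FALSE)
}
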