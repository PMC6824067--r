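#' Compute biallelic genotype likelihoods from read counts
#'
#' Implements the samtools-style biallelic count model with a single scalar
#' error rate. For minor-allele dosage g in \{0, 1, 2\}, per-read category
#' probabilities are
#' P(minor) = (g/2)(1-e) + (1-g/2)(e/3),
#' P(major) = (1-g/2)(1-e) + (g/2)(e/3),
#' and each of the two other bases e/3 (a genotype-independent constant).
#' The site likelihood is the product over reads; each site x individual
#' triplet is renormalized so its maximum log-likelihood is 0. Individuals
#' with zero reads get the uninformative triplet (0, 0, 0).
#'
#' With `error_rate = 0`, conflicting reads give likelihood 0 for every
#' genotype; such degenerate sites raise an error.
#'
#' @param counts list with matrices `n_major`, `n_minor`, `n_other`
#'   (sites x individuals), e.g. from [simulate_reads()].
#' @param error_rate per-base miscall probability, in \[0, 0.25\].
#' @param sites optional site metadata data.frame (chrom, pos, major, minor).
#' @param individuals optional individual ids.
#' @return an object of class `gl_matrix`: list with `logl` (list of three
#'   sites x individuals matrices, dosage 0/1/2, max of each triplet = 0),
#'   `sites` and `individuals`.
#' @export
compute_gl <- function(counts, error_rate, sites = NULL, individuals = NULL) {
  if (error_rate < 0 || error_rate > 0.25) stop("error_rate must lie in [0, 0.25]")
  nmaj <- counts$n_major; nmin <- counts$n_minor; noth <- counts$n_other
  stopifnot(is.matrix(nmaj), all(dim(nmaj) == dim(nmin)),
            all(dim(nmaj) == dim(noth)))
  if (any(nmaj < 0 | nmin < 0 | noth < 0)) stop("read counts must be non-negative")
  e <- error_rate
  p_min <- (0:2) / 2 * (1 - e) + (1 - (0:2) / 2) * (e / 3)
  p_maj <- (2:0) / 2 * (1 - e) + (1 - (2:0) / 2) * (e / 3)

  # n * log(p) with the convention 0 * log(0) = 0
  xlogp <- function(nmat, p) {
    if (p > 0) return(nmat * log(p))
    out <- matrix(0, nrow(nmat), ncol(nmat))
    out[nmat > 0] <- -Inf
    out
  }
  oth_term <- xlogp(noth, e / 3)
  logl <- lapply(1:3, function(gi)
    xlogp(nmaj, p_maj[gi]) + xlogp(nmin, p_min[gi]) + oth_term)

  m <- pmax_list(logl)
  if (any(!is.finite(m)))
    stop("degenerate site(s): zero likelihood for every genotype ",
         "(conflicting reads with error_rate = 0)")
  logl <- lapply(logl, function(x) x - m)
  structure(list(logl = logl,
                 sites = sites %||% data.frame(chrom = "chr01",
                                               pos = seq_len(nrow(nmaj)) - 1L),
                 individuals = individuals %||% sprintf("ind%03d", seq_len(ncol(nmaj)))),
            class = "gl_matrix")
}

#' @export
dim.gl_matrix <- function(x) dim(x$logl[[1]])

# linear-space likelihoods (max of each triplet = 1)
gl_linear <- function(gl, sites = NULL, individuals = NULL) {
  L <- lapply(gl$logl, exp)
  if (!is.null(sites)) L <- lapply(L, function(m) m[sites, , drop = FALSE])
  if (!is.null(individuals)) L <- lapply(L, function(m) m[, individuals, drop = FALSE])
  L
}

# TRUE where an individual has information at a site (triplet not all equal)
gl_informative <- function(gl) {
  (gl$logl[[1]] != gl$logl[[2]]) | (gl$logl[[2]] != gl$logl[[3]])
}

#' Subset a GL matrix by sites and/or individuals
#'
#' @param gl a `gl_matrix`.
#' @param sites integer/logical site index.
#' @param individuals integer/logical/character individual index.
#' @return a `gl_matrix`.
#' @export
gl_subset <- function(gl, sites = NULL, individuals = NULL) {
  if (is.character(individuals)) individuals <- match(individuals, gl$individuals)
  L <- gl$logl
  sdf <- gl$sites; ids <- gl$individuals
  if (!is.null(sites)) {
    L <- lapply(L, function(m) m[sites, , drop = FALSE])
    sdf <- sdf[sites, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    L <- lapply(L, function(m) m[, individuals, drop = FALSE])
    ids <- ids[individuals]
  }
  structure(list(logl = L, sites = sdf, individuals = ids), class = "gl_matrix")
}

#' Estimate minor-allele frequencies by EM
#'
#' Per site, iterates f <- sum_i E\[g_i | data_i, HWE(f)\] / (2n) under the
#' Hardy-Weinberg prior \{(1-f)^2, 2f(1-f), f^2\}, starting from f = 0.25,
#' until |delta f| < `tol` or `max_iter` iterations. Uninformative individuals
#' contribute their prior mean and so do not bias the estimate. With
#' `fold = TRUE` the estimate is folded to \[0, 0.5\] and the implied
#' major/minor swap recorded.
#'
#' Sites where every individual is uninformative get `NA` with a warning
#' (the frequency is undefined there).
#'
#' @param gl a `gl_matrix`.
#' @param individuals optional subset of individuals (index or names).
#' @param fold fold the estimate to \[0, 0.5\]? (default TRUE).
#' @param tol convergence tolerance on f (default 1e-8).
#' @param max_iter maximum EM iterations (default 100).
#' @return data.frame with columns `f` (the folded MAF if `fold`), `raw_f`
#'   (unfolded, on the fixed major/minor polarization) and `swapped`.
#' @export
estimate_maf_em <- function(gl, individuals = NULL, fold = TRUE,
                            tol = 1e-8, max_iter = 100L) {
  if (!is.null(individuals)) gl <- gl_subset(gl, individuals = individuals)
  L0 <- exp(gl$logl[[1]]); L1 <- exp(gl$logl[[2]]); L2 <- exp(gl$logl[[3]])
  S <- nrow(L0); n <- ncol(L0)
  if (n < 1) stop("no individuals")
  info <- gl_informative(gl)
  none <- rowSums(info) == 0
  if (all(none)) warning("all sites uninformative: frequency undefined")
  else if (any(none)) warning(sum(none), " site(s) with no informative ",
                              "individual: frequency undefined (NA)")
  f <- rep(0.25, S)
  active <- !none
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    fa <- f[active]
    w0 <- (1 - fa)^2; w1 <- 2 * fa * (1 - fa); w2 <- fa^2
    a0 <- w0 * L0[active, , drop = FALSE]
    a1 <- w1 * L1[active, , drop = FALSE]
    a2 <- w2 * L2[active, , drop = FALSE]
    eg <- (a1 + 2 * a2) / (a0 + a1 + a2)
    fnew <- rowSums(eg) / (2 * n)
    conv <- abs(fnew - fa) < tol
    f[active] <- fnew
    active[active] <- !conv
  }
  f[none] <- NA_real_
  swapped <- !is.na(f) & f > 0.5
  data.frame(f = if (fold) ifelse(swapped, 1 - f, f) else f,
             raw_f = f, swapped = swapped)
}

# log-likelihood of the data at each site under HWE with frequency f
site_loglik_hwe <- function(gl, f) {
  L0 <- exp(gl$logl[[1]]); L1 <- exp(gl$logl[[2]]); L2 <- exp(gl$logl[[3]])
  w0 <- (1 - f)^2; w1 <- 2 * f * (1 - f); w2 <- f^2
  lik <- w0 * L0 + w1 * L1 + w2 * L2
  rowSums(log(lik))
}

#' Likelihood-ratio test for polymorphism (SNP calling)
#'
#' Statistic = 2\[lnL(f_hat) - lnL(f = 0)\] where lnL(f) sums, over
#' individuals, the log of the HWE-weighted likelihood mixture; the p-value
#' is the upper tail of chi-square with 1 df. The statistic is invariant to
#' rescaling a site's likelihoods by a constant and non-negative by
#' construction (f = 0 lies in the constrained space; tiny negative values
#' from finite EM convergence are clamped to 0).
#'
#' @param gl a `gl_matrix`.
#' @param f per-site frequency estimates on the fixed polarization (unfolded);
#'   if `NULL`, estimated with [estimate_maf_em()].
#' @return data.frame with columns `stat` and `p`.
#' @export
snp_lrt <- function(gl, f = NULL) {
  if (is.null(f)) f <- estimate_maf_em(gl, fold = FALSE)$raw_f
  ll0 <- rowSums(gl$logl[[1]])
  llf <- ll0
  ok <- !is.na(f) & f > 0
  if (any(ok)) llf[ok] <- site_loglik_hwe(gl_subset(gl, sites = ok), f[ok])
  stat <- pmax(0, 2 * (llf - ll0))
  stat[is.na(f)] <- NA_real_
  data.frame(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Apply per-site retention filters (SNP calling)
#'
#' A site is retained iff (a) at least `min_ind` individuals have >= 1 read in
#' every population (globally if `populations` is `NULL`); (b) total summed
#' depth <= `max_total_depth` (repetitive-region guard); (c) folded MAF >=
#' `min_maf` (inclusive); and (d) polymorphism LRT p <= `snp_p_cutoff`.
#' Filters commute; site order is preserved.
#'
#' @param counts read-count list (for depth); same dimensions as `gl`.
#' @param gl a `gl_matrix`.
#' @param populations optional named list of individual indices (or names),
#'   one per population, for the per-population minimum-individual rule.
#' @param min_ind minimum individuals with data (per population if
#'   `populations` given). Either a count or, if `min_ind_frac` is supplied,
#'   the per-population threshold is `ceiling(min_ind_frac * n_pop)`.
#' @param min_ind_frac optional fraction of individuals per population
#'   (e.g. 2/3 for a stringent set).
#' @param max_total_depth maximum summed depth across individuals.
#' @param min_maf minimum folded minor-allele frequency (inclusive).
#' @param snp_p_cutoff LRT p-value cutoff for calling a SNP.
#' @return an object of class `snp_set`: data.frame of retained sites with
#'   columns `site` (index into `gl`), `chrom`, `pos`, `maf`, `raw_f`,
#'   `swapped`, `p`; the logical retention mask is in `attr(, "retained")`.
#' @export
apply_site_filters <- function(counts, gl, populations = NULL,
                               min_ind = 3L, min_ind_frac = NULL,
                               max_total_depth = 1000, min_maf = 0.01,
                               snp_p_cutoff = 1e-6) {
  depth <- counts$n_major + counts$n_minor + counts$n_other
  stopifnot(all(dim(depth) == dim(gl)))
  S <- nrow(depth)
  if (S == 0) {
    out <- data.frame(site = integer(), chrom = character(), pos = integer(),
                      maf = numeric(), raw_f = numeric(), swapped = logical(),
                      p = numeric())
    attr(out, "retained") <- logical(0)
    class(out) <- c("snp_set", "data.frame")
    return(out)
  }
  has_read <- depth > 0
  if (is.null(populations)) {
    ok_ind <- rowSums(has_read) >= min_ind
  } else {
    ok_ind <- rep(TRUE, S)
    for (p in populations) {
      if (is.character(p)) p <- match(p, gl$individuals)
      thr <- if (is.null(min_ind_frac)) min_ind else ceiling(min_ind_frac * length(p))
      ok_ind <- ok_ind & rowSums(has_read[, p, drop = FALSE]) >= thr
    }
  }
  ok_depth <- rowSums(depth) <= max_total_depth
  maf <- suppressWarnings(estimate_maf_em(gl))
  lrt <- snp_lrt(gl, maf$raw_f)
  ok_maf <- !is.na(maf$f) & maf$f >= min_maf
  ok_p <- !is.na(lrt$p) & lrt$p <= snp_p_cutoff
  retained <- ok_ind & ok_depth & ok_maf & ok_p
  out <- data.frame(site = which(retained),
                    chrom = gl$sites$chrom[retained],
                    pos = gl$sites$pos[retained],
                    maf = maf$f[retained], raw_f = maf$raw_f[retained],
                    swapped = maf$swapped[retained], p = lrt$p[retained])
  attr(out, "retained") <- retained
  class(out) <- c("snp_set", "data.frame")
  out
}

#' Posterior expected minor-allele dosage
#'
#' E\[g\] = sum_g g HWE_f(g) L(g) / sum_g HWE_f(g) L(g), in \[0, 2\].
#' Uninformative individuals get the prior mean 2f. Monotone in f for fixed
#' likelihoods.
#'
#' @param gl a `gl_matrix`.
#' @param f per-site allele frequency on the fixed polarization, in \[0, 1\].
#' @return sites x individuals matrix of expected dosages.
#' @export
posterior_dosage <- function(gl, f) {
  stopifnot(length(f) == nrow(gl$logl[[1]]), all(f >= 0 & f <= 1, na.rm = TRUE))
  # keep f strictly inside (0,1) so certain genotypes that contradict a
  # degenerate prior do not produce 0/0
  f <- clip(f, 1e-12, 1 - 1e-12)
  L0 <- exp(gl$logl[[1]]); L1 <- exp(gl$logl[[2]]); L2 <- exp(gl$logl[[3]])
  a0 <- (1 - f)^2 * L0; a1 <- 2 * f * (1 - f) * L1; a2 <- f^2 * L2
  (a1 + 2 * a2) / (a0 + a1 + a2)
}
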