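#' Site allele frequency (SAF) likelihoods for one population
#'
#' For each site, the likelihood of observing j copies of the minor allele
#' among the population's 2N chromosomes, marginalizing over individual
#' genotypes. Computed by dynamic programming over individuals:
#' h^0 = \[1\]; h^i\[j\] = sum_g C(2,g) L_i(g) h^(i-1)\[j-g\]; finally
#' SAF\[j\] = h^N\[j\] / C(2N, j). Rows are renormalized (max = 1) at every
#' step to avoid underflow; the SAF is likelihood-scale, so the per-site
#' scale constant is irrelevant downstream.
#'
#' @param gl a `gl_matrix` restricted to the population's individuals.
#' @return sites x (2N+1) matrix (class `saf_matrix`) with attribute
#'   `n_chrom` = 2N; each row's maximum is 1.
#' @export
saf_site <- function(gl) {
  L0 <- exp(gl$logl[[1]]); L1 <- exp(gl$logl[[2]]); L2 <- exp(gl$logl[[3]])
  S <- nrow(L0); N <- ncol(L0)
  if (N < 1) stop("need at least one individual")
  h <- matrix(1, S, 1)
  zero <- function(k) matrix(0, S, k)
  for (i in seq_len(N)) {
    w <- ncol(h)
    # padded shifts: j, j-1, j-2
    h <- cbind(h, zero(2)) * L0[, i] +
         cbind(zero(1), h, zero(1)) * (2 * L1[, i]) +
         cbind(zero(2), h) * L2[, i]
    h <- h / pmax(rowSums(h), .Machine$double.xmin)
  }
  j <- 0:(2 * N)
  saf <- sweep(h, 2, choose(2 * N, j), "/")
  saf <- saf / apply(saf, 1, max)
  structure(saf, n_chrom = 2L * N, class = c("saf_matrix", "matrix"))
}

#' Estimate the (joint) site frequency spectrum by EM
#'
#' Maximum-likelihood SFS from SAF likelihoods, with a uniform start. Each
#' iteration computes the per-site posterior over allele counts
#' (proportional to SFS x SAF1 \[outer SAF2\]), sums posteriors across sites,
#' and renormalizes; the log-likelihood is non-decreasing and iteration stops
#' when its change falls below `tol` or after `max_iter` iterations. The
#' returned spectrum is in units of expected site counts (total = number of
#' sites).
#'
#' @param saf1 `saf_matrix` for population 1.
#' @param saf2 optional `saf_matrix` for population 2 (same sites); if given
#'   the joint 2D spectrum is estimated.
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @return vector (1D) or matrix (2D) of expected site counts, class `sfs`,
#'   with attributes `loglik` (trace) and `iterations`.
#' @export
sfs_em <- function(saf1, saf2 = NULL, tol = 1e-6, max_iter = 200L,
                   accel = TRUE) {
  A <- unclass(saf1)
  S <- nrow(A)
  if (S < 1) stop("need at least one site")
  one_d <- is.null(saf2)
  B <- if (one_d) matrix(1, S, 1) else unclass(saf2)
  stopifnot(nrow(B) == S)
  J <- ncol(A); K <- ncol(B)

  # one EM update; returns the new spectrum and the log-likelihood of the
  # input spectrum
  em_step <- function(Q) {
    w <- rowSums((A %*% Q) * B)
    list(Q = Q * crossprod(A, B / w) / S, ll = sum(log(w)))
  }
  loglik_of <- function(Q) sum(log(rowSums((A %*% Q) * B)))
  project <- function(Q) { Q[Q < 0] <- 0; Q / sum(Q) }

  Q <- matrix(1 / (J * K), J, K)
  ll_trace <- numeric(0)
  evals <- 0L
  repeat {
    if (!accel) {
      s <- em_step(Q); evals <- evals + 1L
      Q <- s$Q; ll <- s$ll
    } else {
      # SQUAREM-style acceleration: extrapolate along two EM steps, with a
      # fallback to the plain EM result whenever the likelihood would drop,
      # so the trace stays non-decreasing
      s1 <- em_step(Q); s2 <- em_step(s1$Q); evals <- evals + 2L
      ll <- s1$ll
      r <- s1$Q - Q; v <- (s2$Q - s1$Q) - r
      nv <- sqrt(sum(v^2))
      if (nv > 0) {
        a <- max(1, sqrt(sum(r^2)) / nv)
        Qx <- project(Q + 2 * a * r + a^2 * v)
        if (loglik_of(Qx) >= loglik_of(s2$Q)) Q <- Qx else Q <- s2$Q
        evals <- evals + 1L
      } else Q <- s2$Q
    }
    ll_trace <- c(ll_trace, ll)
    n <- length(ll_trace)
    if ((n > 1 && abs(ll_trace[n] - ll_trace[n - 1]) < tol) ||
        evals >= max_iter) break
  }
  out <- Q * S
  if (one_d) out <- structure(as.numeric(out), loglik = ll_trace,
                              iterations = evals, class = "sfs")
  else out <- structure(out, loglik = ll_trace, iterations = evals,
                        class = c("sfs", "matrix"))
  out
}

# Hudson/Bhatia per-grid-cell FST numerator (alpha) and denominator (beta)
fst_grid <- function(n1, n2) {
  p1 <- (0:n1) / n1
  p2 <- (0:n2) / n2
  P1 <- matrix(p1, n1 + 1, n2 + 1)
  P2 <- matrix(p2, n1 + 1, n2 + 1, byrow = TRUE)
  alpha <- (P1 - P2)^2 - P1 * (1 - P1) / (n1 - 1) - P2 * (1 - P2) / (n2 - 1)
  beta <- P1 * (1 - P2) + P2 * (1 - P1)
  list(alpha = alpha, beta = beta)
}

#' Per-site Hudson/Bhatia FST components
#'
#' Posterior expectations of the per-site FST numerator alpha and
#' denominator beta under the joint allele-count posterior
#' P(j,k) proportional to SFS2D(j,k) SAF1(j) SAF2(k). With p1 = j/2N1,
#' p2 = k/2N2:
#' alpha = (p1-p2)^2 - p1(1-p1)/(2N1-1) - p2(1-p2)/(2N2-1),
#' beta = p1(1-p2) + p2(1-p1).
#'
#' @param saf1,saf2 `saf_matrix` objects on the same sites.
#' @param sfs2d joint spectrum from [sfs_em()] on the same sites.
#' @return data.frame with per-site columns `alpha` and `beta`.
#' @export
fst_components <- function(saf1, saf2, sfs2d) {
  A <- unclass(saf1); B <- unclass(saf2)
  n1 <- attr(saf1, "n_chrom"); n2 <- attr(saf2, "n_chrom")
  if (is.null(n1)) n1 <- ncol(A) - 1L
  if (is.null(n2)) n2 <- ncol(B) - 1L
  if (n1 < 2 || n2 < 2) stop("FST estimator undefined for 2N < 2")
  Q <- unclass(sfs2d)
  stopifnot(nrow(Q) == ncol(A), ncol(Q) == ncol(B), nrow(A) == nrow(B))
  g <- fst_grid(n1, n2)
  w <- rowSums((A %*% Q) * B)
  ea <- rowSums((A %*% (Q * g$alpha)) * B) / w
  eb <- rowSums((A %*% (Q * g$beta)) * B) / w
  data.frame(alpha = ea, beta = eb)
}

#' Weighted (ratio-of-sums) FST
#'
#' @param components data.frame from [fst_components()].
#' @param subset optional logical/integer site subset.
#' @return scalar weighted FST = sum(alpha)/sum(beta).
#' @export
weighted_fst <- function(components, subset = NULL) {
  a <- components$alpha; b <- components$beta
  if (!is.null(subset)) { a <- a[subset]; b <- b[subset] }
  sb <- sum(b)
  if (!length(a) || sb <= 0) stop("weighted FST undefined: no sites with beta > 0")
  sum(a) / sb
}

#' Tile per-site statistics into non-overlapping genomic windows
#'
#' Windows tile each chromosome from position 0 in fixed `window_size` steps
#' (0-based half-open: a site at position `window_size` belongs to the second
#' window). For FST, supply `alpha`/`beta` and the window value is the
#' ratio-of-sums within the window; otherwise supply `values` and the window
#' value is their mean. Windows with fewer than `min_sites` sites get `NA`.
#'
#' @param sites data.frame with `chrom` and `pos`, sorted within chromosome.
#' @param window_size window size in bp.
#' @param min_sites minimum sites for a non-missing window value.
#' @param values per-site values (mean mode).
#' @param alpha,beta per-site FST components (ratio mode).
#' @param chrom_lengths optional named vector of chromosome lengths; if
#'   given, windows cover every chromosome fully (empty chromosomes yield
#'   all-missing windows), else windows extend to the last site.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
windowed_stat <- function(sites, window_size, min_sites = 1L, values = NULL,
                          alpha = NULL, beta = NULL, chrom_lengths = NULL) {
  ratio_mode <- !is.null(alpha)
  if (ratio_mode) stopifnot(length(alpha) == nrow(sites), length(beta) == nrow(sites))
  else stopifnot(!is.null(values), length(values) == nrow(sites))
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(sites$chrom)
  out <- lapply(chroms, function(ch) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (is.unsorted(pos)) stop("sites must be sorted by position within ", ch)
    last <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (length(pos)) max(pos) + 1 else 0
    n_win <- max(1L, ceiling(last / window_size))
    start <- (seq_len(n_win) - 1L) * window_size
    wi <- (pos %/% window_size) + 1L
    ns <- tabulate(wi, nbins = n_win)
    val <- rep(NA_real_, n_win)
    if (length(pos)) {
      if (ratio_mode) {
        sa <- rep(0, n_win); sb <- rep(0, n_win)
        ra <- rowsum(alpha[idx], wi); rb <- rowsum(beta[idx], wi)
        sa[as.integer(rownames(ra))] <- ra[, 1]
        sb[as.integer(rownames(rb))] <- rb[, 1]
        val <- ifelse(sb > 0, sa / sb, NA_real_)
      } else {
        sv <- rep(0, n_win)
        rv <- rowsum(values[idx], wi)
        sv[as.integer(rownames(rv))] <- rv[, 1]
        val <- ifelse(ns > 0, sv / ns, NA_real_)
      }
    }
    val[ns < min_sites] <- NA_real_
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size,
                          if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
                            start + window_size),
               n_sites = ns, value = val, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# standard Tajima's D constants for n chromosomes
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D and diversity estimators from a window spectrum
#'
#' theta_pi = sum_j j (n-j) SFS\[j\] / C(n, 2); theta_W = S / a1 with
#' S the (possibly fractional, for posterior-expected spectra) count of
#' segregating sites; D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1))
#' with the standard constants. D is `NA` when S = 0 (undefined).
#'
#' @param sfs spectrum over allele counts 0..n (length n+1).
#' @param n number of chromosomes (2 x diploid individuals); must be >= 4.
#' @return one-row data.frame: `theta_pi`, `theta_w`, `S`, `D`.
#' @export
tajimas_d <- function(sfs, n) {
  if (n < 4) stop("Tajima's D requires n >= 4 chromosomes")
  stopifnot(length(sfs) == n + 1)
  k <- tajima_constants(n)
  j <- 0:n
  theta_pi <- sum(j * (n - j) * sfs) / choose(n, 2)
  S <- sum(sfs[j > 0 & j < n])
  theta_w <- S / k$a1
  D <- if (S > 0) {
    v <- k$e1 * S + k$e2 * S * (S - 1)
    if (v > 0) (theta_pi - theta_w) / sqrt(v) else NA_real_
  } else NA_real_
  data.frame(theta_pi = theta_pi, theta_w = theta_w, S = S, D = D)
}

#' Windowed Tajima's D from SAF likelihoods (empirical Bayes)
#'
#' Per-site posterior allele-count probabilities under the global
#' per-population SFS prior (P_s(j) proportional to SFS\[j\] SAF_s\[j\]) are
#' summed within non-overlapping windows to give a window spectrum, from
#' which theta_pi, theta_W, S and D are computed. Alternatively
#' (`per_window_em = TRUE`) a separate EM spectrum is fit per window.
#'
#' @param saf `saf_matrix` for the population.
#' @param sites site data.frame (`chrom`, `pos`) matching `saf` rows.
#' @param sfs global 1D spectrum from [sfs_em()]; ignored when
#'   `per_window_em`.
#' @param window_size window size in bp (default 5000).
#' @param min_sites minimum sites per window (default 5).
#' @param chrom_lengths optional named chromosome lengths.
#' @param per_window_em fit a separate spectrum per window instead of the
#'   empirical-Bayes posterior sum.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `theta_pi`,
#'   `theta_w`, `S`, `D`, plus `value` (= D, for generic window plumbing).
#' @export
windowed_tajima <- function(saf, sites, sfs = NULL, window_size = 5000,
                            min_sites = 5L, chrom_lengths = NULL,
                            per_window_em = FALSE) {
  A <- unclass(saf)
  n <- attr(saf, "n_chrom") %||% (ncol(A) - 1L)
  stopifnot(nrow(A) == nrow(sites))
  if (!per_window_em) {
    if (is.null(sfs)) sfs <- sfs_em(saf)
    q <- as.numeric(sfs) / sum(sfs)
    post <- sweep(A, 2, q, "*")
    post <- post / rowSums(post)
  }
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(sites$chrom)
  out <- lapply(chroms, function(ch) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (is.unsorted(pos)) stop("sites must be sorted by position within ", ch)
    last <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (length(pos)) max(pos) + 1 else 0
    n_win <- max(1L, ceiling(last / window_size))
    wi <- (pos %/% window_size) + 1L
    rows <- lapply(seq_len(n_win), function(w) {
      sidx <- idx[wi == w]
      if (length(sidx) < min_sites)
        return(data.frame(theta_pi = NA_real_, theta_w = NA_real_,
                          S = NA_real_, D = NA_real_))
      wsfs <- if (per_window_em) as.numeric(sfs_em(structure(
        A[sidx, , drop = FALSE], n_chrom = n, class = c("saf_matrix", "matrix"))))
      else colSums(post[sidx, , drop = FALSE])
      tajimas_d(wsfs, n)
    })
    start <- (seq_len(n_win) - 1L) * window_size
    cbind(data.frame(chrom = ch, start = start,
                     end = pmin(start + window_size, last),
                     n_sites = tabulate(wi, nbins = n_win)),
          do.call(rbind, rows))
  })
  res <- do.call(rbind, out)
  res$value <- res$D
  res
}

#' Per-SNP absolute divergence dxy
#'
#' dxy = f1 (1 - f2) + f2 (1 - f1): the probability that one sequence drawn
#' from each population differs at the site. Both frequency vectors must be
#' on the same major/minor polarization.
#'
#' @param f1,f2 per-SNP allele frequencies in \[0, 1\] (unfolded, shared
#'   polarization).
#' @param minor1,minor2 optional per-SNP minor-allele labels; if both are
#'   supplied they must agree (mismatched polarization is an error).
#' @return numeric vector of per-SNP dxy in \[0, 1\].
#' @export
dxy_snp <- function(f1, f2, minor1 = NULL, minor2 = NULL) {
  stopifnot(length(f1) == length(f2))
  if (!is.null(minor1) && !is.null(minor2) && any(minor1 != minor2))
    stop("mismatched major/minor polarization between populations")
  if (any(f1 < 0 | f1 > 1 | f2 < 0 | f2 > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  f1 * (1 - f2) + f2 * (1 - f1)
}
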