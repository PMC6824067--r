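# shared fixtures: small GL builders and truth-based estimators

# gl_matrix from three linear-likelihood matrices (renormalized so the
# per-triplet max log-likelihood is 0)
gl_from_linear <- function(L0, L1, L2, chrom = "chr01", pos = NULL) {
  L0 <- as.matrix(L0); L1 <- as.matrix(L1); L2 <- as.matrix(L2)
  m <- pmax(L0, pmax(L1, L2))
  logl <- lapply(list(L0, L1, L2),
                 function(x) log(pmax(x, 1e-300)) - log(m))
  logl <- lapply(logl, function(x) { x[m == 0] <- 0; x })
  structure(list(logl = logl,
                 sites = data.frame(chrom = chrom,
                                    pos = pos %||% (seq_len(nrow(L0)) - 1L)),
                 individuals = sprintf("ind%03d", seq_len(ncol(L0)))),
            class = "gl_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# point-mass genotype likelihoods from a dosage matrix (0/1/2)
certain_gl <- function(geno, chrom = "chr01", pos = NULL) {
  mk <- function(g) {
    m <- matrix(-1000, nrow(geno), ncol(geno))
    m[geno == g] <- 0
    m
  }
  pos <- pos %||% (seq_len(nrow(geno)) - 1L)
  structure(list(logl = list(mk(0), mk(1), mk(2)),
                 sites = data.frame(chrom = rep_len(chrom, nrow(geno)),
                                    pos = pos),
                 individuals = sprintf("ind%03d", seq_len(ncol(geno)))),
            class = "gl_matrix")
}

# Hudson/Bhatia weighted FST from true genotype matrices (the independent
# genotype-truth oracle): sample frequencies with the finite-sample
# correction, ratio of sums over polymorphic sites
hudson_truth_fst <- function(g1, g2) {
  n1 <- 2 * ncol(g1); n2 <- 2 * ncol(g2)
  p1 <- rowSums(g1) / n1; p2 <- rowSums(g2) / n2
  alpha <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  beta <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- beta > 0
  sum(alpha[ok]) / sum(beta[ok])
}

# Hudson FST from true population frequencies (infinite-sample form)
hudson_freq_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

# genotypes drawn with allele counts following the neutral 1/j spectrum:
# certain-genotype input for Tajima's D null checks
neutral_spectrum_genotypes <- function(n_ind, n_sites, seed) {
  set.seed(seed)
  nchr <- 2L * n_ind
  j <- sample(1:(nchr - 1), n_sites, replace = TRUE, prob = 1 / (1:(nchr - 1)))
  t(vapply(j, function(jj) {
    h <- sample(rep(c(1L, 0L), c(jj, nchr - jj)))
    h[seq(1, nchr, 2)] + h[seq(2, nchr, 2)]
  }, integer(n_ind)))
}

# brute-force SAF by enumerating all 3^N genotype configurations
saf_enumerate <- function(gl_one_site) {
  L <- vapply(gl_one_site$logl, function(m) exp(m[1, ]), numeric(length(gl_one_site$individuals)))
  N <- nrow(L) # individuals x 3
  grid <- expand.grid(rep(list(0:2), N))
  saf <- numeric(2 * N + 1)
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    w <- prod(vapply(seq_len(N), function(i) choose(2, g[i]) * L[i, g[i] + 1], 0))
    saf[sum(g) + 1] <- saf[sum(g) + 1] + w
  }
  saf <- saf / choose(2 * N, 0:(2 * N))
  saf / max(saf)
}

# swap-aware inversion genotyping accuracy against true B-dosages
swap_aware_accuracy <- function(called_genotypes, truth_dosage) {
  called <- c(AA = 0, AB = 1, BB = 2)[called_genotypes]
  max(mean(called == truth_dosage), mean((2 - called) == truth_dosage))
}

# standard small simulated dataset -> filtered GL set (cached per test file)
sim_filtered_gl <- function(cfg, min_ind = 3L, max_total_depth = 1000) {
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, cfg$error_rate, d$sites, d$manifest$individual)
  pops <- split(seq_len(nrow(d$manifest)), d$manifest$location)
  snps <- apply_site_filters(d$counts, gl, populations = pops,
                             min_ind = min_ind,
                             max_total_depth = max_total_depth)
  list(data = d, gl_all = gl, snps = snps,
       gl = gl_subset(gl, sites = snps$site))
}
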