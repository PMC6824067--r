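test_that("SAF dynamic programming equals exhaustive enumeration for N <= 4", {
  # N = 1: SAF proportional to the GL triplet (hypergeometric weights cancel)
  set.seed(30)
  L <- runif(3)
  gl1 <- gl_from_linear(matrix(L[1], 1, 1), matrix(L[2], 1, 1), matrix(L[3], 1, 1))
  saf1 <- saf_site(gl1)
  expect_equal(as.numeric(saf1[1, ]), L / max(L), tolerance = 1e-12)

  # N = 2..4: DP equals brute-force enumeration of all 3^N configurations
  for (N in 2:4) {
    L0 <- matrix(runif(N), 1); L1 <- matrix(runif(N), 1); L2 <- matrix(runif(N), 1)
    gl <- gl_from_linear(L0, L1, L2)
    expect_equal(as.numeric(saf_site(gl)[1, ]), saf_enumerate(gl),
                 tolerance = 1e-10, info = paste("N =", N))
  }

  # all individuals certainly dosage 1 -> all mass at j = N
  glh <- certain_gl(matrix(1L, 1, 3))
  safh <- saf_site(glh)
  expect_equal(which.max(safh[1, ]) - 1L, 3L)
  expect_lt(max(safh[1, -4]) / safh[1, 4], 1e-100)
})

test_that("SFS EM conserves mass, increases likelihood and recovers certain counts", {
  # certain allele counts -> SFS equals the exact histogram
  set.seed(31)
  geno <- matrix(rbinom(400 * 5, 2, 0.3), 400, 5)
  gl <- certain_gl(geno)
  saf <- saf_site(gl)
  sfs <- sfs_em(saf, tol = 1e-12, max_iter = 2000)
  hist_true <- tabulate(rowSums(geno) + 1L, nbins = 11)
  expect_equal(as.numeric(sfs), hist_true, tolerance = 1e-3)

  # mass conservation and monotone log-likelihood for noisy input
  cts <- simulate_reads(geno, rep(1.5, 5), 0.01, seed = 32)
  gl2 <- compute_gl(cts, 0.01)
  saf2 <- saf_site(gl2)
  sfs2 <- sfs_em(saf2)
  expect_equal(sum(sfs2), 400, tolerance = 1e-6)
  expect_true(all(diff(attr(sfs2, "loglik")) >= -1e-9))

  # joint spectrum: mass conservation too
  sfs2d <- sfs_em(saf2, saf_site(certain_gl(geno)))
  expect_equal(sum(sfs2d), 400, tolerance = 1e-6)
})

test_that("2D SFS marginals match the separately estimated 1D SFS when data are informative", {
  cfg <- sim_config(n_locations = 2, n_per_location = 5, n_chromosomes = 1,
                    chrom_length = 1e5, snp_density = 5e-3, F_neutral = 0.02,
                    coverage_mean = 20, error_rate = 0.005, seed = 3)
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.005, d$sites, d$manifest$individual)
  saf1 <- saf_site(gl_subset(gl, individuals = 1:5))
  saf2 <- saf_site(gl_subset(gl, individuals = 6:10))
  s1 <- sfs_em(saf1, tol = 1e-10, max_iter = 5000)
  s2 <- sfs_em(saf1, saf2, tol = 1e-10, max_iter = 5000)
  expect_lt(sum(abs(rowSums(s2) - as.numeric(s1))), 1e-3 * nrow(d$sites))
})

test_that("FST components match a brute-force grid sum and behave at the extremes", {
  # certain fixed difference with large samples: alpha = beta = 1
  gA <- matrix(2L, 1, 50); gB <- matrix(0L, 1, 50)
  sA <- saf_site(certain_gl(gA)); sB <- saf_site(certain_gl(gB))
  Q <- matrix(0, 101, 101); Q[101, 1] <- 1
  fc <- fst_components(sA, sB, structure(Q, class = c("sfs", "matrix")))
  expect_equal(fc$alpha, 1, tolerance = 1e-9)
  expect_equal(fc$beta, 1, tolerance = 1e-9)
  expect_equal(weighted_fst(fc), 1, tolerance = 1e-9)

  # arbitrary SAFs: expectations equal the explicit double sum over (j,k)
  set.seed(33)
  N1 <- 3; N2 <- 4
  gl1 <- gl_from_linear(matrix(runif(2 * N1), 2), matrix(runif(2 * N1), 2),
                        matrix(runif(2 * N1), 2))
  gl2 <- gl_from_linear(matrix(runif(2 * N2), 2), matrix(runif(2 * N2), 2),
                        matrix(runif(2 * N2), 2))
  s1 <- saf_site(gl1); s2 <- saf_site(gl2)
  q2 <- sfs_em(s1, s2)
  fc2 <- fst_components(s1, s2, q2)
  Qp <- unclass(q2) / sum(q2)
  for (s in 1:2) {
    post <- Qp * outer(as.numeric(s1[s, ]), as.numeric(s2[s, ]))
    post <- post / sum(post)
    ea <- 0; eb <- 0
    for (j in 0:(2 * N1)) for (k in 0:(2 * N2)) {
      p1 <- j / (2 * N1); p2 <- k / (2 * N2)
      a <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * N1 - 1) - p2 * (1 - p2) / (2 * N2 - 1)
      b <- p1 * (1 - p2) + p2 * (1 - p1)
      ea <- ea + post[j + 1, k + 1] * a
      eb <- eb + post[j + 1, k + 1] * b
    }
    expect_equal(fc2$alpha[s], ea, tolerance = 1e-10)
    expect_equal(fc2$beta[s], eb, tolerance = 1e-10)
  }

  # identical frequencies, huge samples: alpha ~ 0
  gE <- matrix(rep(c(0L, 1L, 2L), c(30, 40, 30)), 1, 100)
  sE <- saf_site(certain_gl(gE))
  QE <- matrix(0, 201, 201); QE[101, 101] <- 1
  fcE <- fst_components(sE, sE, structure(QE, class = c("sfs", "matrix")))
  expect_lt(abs(fcE$alpha), 0.01)

  expect_error(weighted_fst(data.frame(alpha = numeric(), beta = numeric())),
               "undefined")
})

test_that("windows tile half-open from zero and aggregate by ratio-of-sums", {
  # boundary convention: a site at 15,000 belongs to [15000, 30000)
  sites <- data.frame(chrom = "chr01", pos = c(0L, 14999L, 15000L))
  w <- windowed_stat(sites, 15000, min_sites = 1, values = c(1, 2, 9))
  expect_equal(w$value, c(1.5, 9))
  expect_equal(w$start, c(0, 15000))

  # hand-built 3-window FST toy: window values are ratios of sums
  sites2 <- data.frame(chrom = "chr01", pos = c(1000L, 2000L, 16000L, 31000L, 32000L))
  a <- c(1, 2, 3, 4, 5); b <- c(2, 2, 4, 8, 8)
  w2 <- windowed_stat(sites2, 15000, min_sites = 1, alpha = a, beta = b)
  expect_equal(w2$value, c(3 / 4, 3 / 4, 9 / 16))
  expect_equal(w2$n_sites, c(2L, 1L, 2L))

  # empty chromosome -> all-missing windows; unsorted input errors
  w3 <- windowed_stat(data.frame(chrom = character(), pos = integer()),
                      10000, values = numeric(),
                      chrom_lengths = c(chrEmpty = 50000))
  expect_equal(nrow(w3), 5)
  expect_true(all(is.na(w3$value)))
  expect_error(windowed_stat(data.frame(chrom = "c", pos = c(5L, 1L)),
                             1000, values = c(1, 2)), "sorted")

  # windows below min_sites are reported missing
  w4 <- windowed_stat(sites2, 15000, min_sites = 2, alpha = a, beta = b)
  expect_true(is.na(w4$value[2]) && !is.na(w4$value[1]))
})

test_that("Tajima's D matches direct constant-by-constant evaluation", {
  # theta_pi = theta_W -> D = 0: build a window spectrum that balances them
  n <- 8
  a1 <- sum(1 / 1:(n - 1))
  # choose S so the singleton-only spectrum gives theta_pi = theta_W:
  # pi = S (n-1) / C(n,2) ... instead balance with a two-entry spectrum
  sfs <- rep(0, n + 1)
  # spectrum proportional to 1/j has E[pi] = E[W]; use it exactly
  sfs[2:n] <- 1 / (1:(n - 1))
  td <- tajimas_d(sfs, n)
  expect_equal(td$theta_pi, td$theta_w, tolerance = 1e-12)
  expect_equal(td$D, 0, tolerance = 1e-9)

  # n = 4, SFS = (0, 3, 0, 0, 0): every constant evaluated directly
  td4 <- tajimas_d(c(0, 3, 0, 0, 0), 4)
  a1_4 <- 1 + 1 / 2 + 1 / 3; a2_4 <- 1 + 1 / 4 + 1 / 9
  b1 <- 5 / 9; b2 <- 2 * (16 + 4 + 3) / (9 * 4 * 3)
  c1 <- b1 - 1 / a1_4; c2 <- b2 - 6 / (4 * a1_4) + a2_4 / a1_4^2
  e1 <- c1 / a1_4; e2 <- c2 / (a1_4^2 + a2_4)
  S <- 3
  expect_equal(td4$theta_pi, 3 * (1 * 3) / 6, tolerance = 1e-12)
  expect_equal(td4$theta_w, 3 / a1_4, tolerance = 1e-12)
  expect_equal(td4$D, (1.5 - 3 / a1_4) / sqrt(e1 * S + e2 * S * (S - 1)),
               tolerance = 1e-12)

  # no segregating sites -> D undefined
  expect_true(is.na(tajimas_d(c(5, 0, 0, 0, 0), 4)$D))
  expect_error(tajimas_d(c(1, 1, 1), 2), "n >= 4")
})

test_that("windowed Tajima's D is near zero for a neutral-spectrum simulation", {
  n_ind <- 10
  geno <- neutral_spectrum_genotypes(n_ind, 100 * 40, seed = 77)
  gl <- certain_gl(geno, pos = seq(0, by = 125, length.out = nrow(geno)))
  saf <- saf_site(gl)
  td <- windowed_tajima(saf, gl$sites, window_size = 5000, min_sites = 5)
  expect_equal(sum(!is.na(td$D)), 100)
  expect_gt(mean(td$D, na.rm = TRUE), -0.3)
  expect_lt(mean(td$D, na.rm = TRUE), 0.3)
})

test_that("dxy is the symmetric mismatch probability with shared polarization", {
  expect_equal(dxy_snp(0.5, 0.5), 0.5)
  expect_equal(dxy_snp(1, 0), 1)
  set.seed(34)
  f1 <- runif(50); f2 <- runif(50)
  expect_equal(dxy_snp(f1, f2), dxy_snp(f2, f1))
  expect_true(all(dxy_snp(f1, f2) >= 0 & dxy_snp(f1, f2) <= 1))
  p <- runif(20)
  expect_equal(dxy_snp(p, p), 2 * p * (1 - p))
  expect_error(dxy_snp(0.5, 0.5, minor1 = "A", minor2 = "C"), "polarization")
})

test_that("GL-based FST converges to genotype-truth FST as coverage grows", {
  bias <- vapply(c(0.7, 2, 20), function(cov) {
    cfg <- sim_config(n_locations = 2, n_per_location = 15, n_chromosomes = 1,
                      chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.05,
                      coverage_mean = cov, error_rate = 0.01, seed = 13)
    d <- simulate_dataset(cfg)
    truth <- hudson_truth_fst(d$truth$genotypes[, 1:15],
                              d$truth$genotypes[, 16:30])
    gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
    snps <- apply_site_filters(d$counts, gl, min_ind = 5, max_total_depth = 1e9)
    gls <- gl_subset(gl, sites = snps$site)
    sa <- saf_site(gl_subset(gls, individuals = 1:15))
    sb <- saf_site(gl_subset(gls, individuals = 16:30))
    fc <- fst_components(sa, sb, sfs_em(sa, sb))
    abs(weighted_fst(fc) - truth)
  }, 0)
  expect_true(all(diff(bias) < 0))
})
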