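test_that("dosage LD has the expected exact and null behavior", {
  expect_equal(dosage_r2(c(0, 1, 2, 1), c(0, 1, 2, 1))$r2, 1)
  expect_equal(dosage_r2(c(0, 1, 2), c(2, 1, 0))$r, -1)
  expect_true(is.na(dosage_r2(c(1, 1, 1), c(0, 1, 2))$r))
  expect_error(dosage_r2(c(0, 1), c(1, 0)), "3 individuals")

  # independent loci: E[r^2] = 1/(n-1); mean over 1,000 pairs within 3 SE
  set.seed(50)
  n <- 300
  r2 <- vapply(1:1000, function(i)
    dosage_r2(rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))$r2, 0)
  se <- stats::sd(r2) / sqrt(1000)
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * se)
})

test_that("high-LD blocks are detected at the planted boundaries", {
  cfg <- sim_config(n_locations = 4, n_per_location = 15, n_chromosomes = 1,
                    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.01,
                    coverage_mean = 20, error_rate = 0.01, seed = 31,
                    inversions = list(inversion_spec("chr01", 5e5, 15e5, 100,
                      stats::setNames(rep(0.5, 4), sprintf("loc%02d", 1:4)))))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl, min_ind = 10, max_total_depth = 1e9)
  gls <- gl_subset(gl, sites = snps$site)
  f <- estimate_maf_em(gls, fold = FALSE)$raw_f
  E <- posterior_dosage(gls, f)
  blk <- detect_ld_block(gls$sites$pos, t(E), min_span = 2e5)
  expect_lt(abs(blk$start - 5e5), 3e4)   # within 3 bins of truth
  expect_lt(abs(blk$end - 15e5), 3e4)

  # no planted block -> nothing detected
  cfg0 <- sim_config(n_locations = 2, n_per_location = 15, n_chromosomes = 1,
                     chrom_length = 1e6, snp_density = 2e-3, F_neutral = 0.01,
                     coverage_mean = 2, seed = 32)
  d0 <- simulate_dataset(cfg0)
  gl0 <- compute_gl(d0$counts, 0.01, d0$sites, d0$manifest$individual)
  f0 <- estimate_maf_em(gl0, fold = FALSE)$raw_f
  E0 <- posterior_dosage(gl0, f0)
  expect_null(detect_ld_block(d0$sites$pos, t(E0), min_span = 2e5))

  # block spanning the whole chromosome -> full extent returned
  set.seed(51)
  inv <- rbinom(40, 2, 0.5)
  pos <- seq(0L, 990000L, by = 10000L)
  dos <- matrix(rep(inv, length(pos)), 40) + matrix(rnorm(40 * length(pos), 0, 0.05), 40)
  blk_full <- detect_ld_block(pos, dos, min_span = 5e5)
  expect_equal(blk_full$start, 0L)
  expect_equal(blk_full$end, 990001L)

  expect_error(detect_ld_block(pos[1:5], dos[, 1:5], min_span = 1e4),
               "fewer than 10")
})

test_that("in-region diagnostic LD is strong and off-region LD near the null", {
  cfg <- sim_config(n_locations = 4, n_per_location = 15, n_chromosomes = 1,
                    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.01,
                    coverage_mean = 20, error_rate = 0.01, seed = 31,
                    inversions = list(inversion_spec("chr01", 5e5, 15e5, 100,
                      stats::setNames(rep(0.5, 4), sprintf("loc%02d", 1:4)))))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl, min_ind = 10, max_total_depth = 1e9)
  gls <- gl_subset(gl, sites = snps$site)
  f <- estimate_maf_em(gls, fold = FALSE)$raw_f
  E <- posterior_dosage(gls, f)
  inv_dos <- d$truth$inv_dosage[, 1]
  pos <- gls$sites$pos
  in_reg <- pos >= 5e5 & pos < 15e5
  r2_inv <- apply(E, 1, function(x) suppressWarnings(stats::cor(x, inv_dos)))^2
  diag_idx <- which(in_reg & r2_inv > 0.9)
  expect_gte(length(diag_idx), 50)
  sub <- diag_idx[seq(1, length(diag_idx), length.out = 25)]
  pr2 <- stats::cor(t(E[sub, ]))^2
  expect_gte(mean(pr2[upper.tri(pr2)]), 0.8)
  # off-region pairs sit near the null level 1/(n-1)
  off <- which(pos >= 17e5)[1:25]
  pr2_off <- stats::cor(t(E[off, ]))^2
  expect_lt(mean(pr2_off[upper.tri(pr2_off)]), 5 / (60 - 1))
})

test_that("inversion genotyping recovers planted genotypes up to label swap", {
  # clean, well-separated case at 2X
  locs <- sprintf("loc%02d", 1:8)
  cfg <- sim_config(n_locations = 8, n_per_location = 12, n_chromosomes = 1,
                    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.005,
                    coverage_mean = 2, error_rate = 0.01, seed = 52,
                    inversions = list(inversion_spec("chr01", 5e5, 15e5, 200,
                      stats::setNames(seq(0.2, 0.8, length.out = 8), locs))))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl, min_ind = 10)
  gls <- gl_subset(gl, sites = snps$site)
  calls <- genotype_inversion(gls, list(chrom = "chr01", start = 5e5, end = 15e5),
                              "inv1")
  expect_equal(swap_aware_accuracy(calls$genotype, d$truth$inv_dosage[, 1]), 1)

  # genotyping accuracy increases with the number of diagnostic sites at 0.7X
  acc <- vapply(c(20, 50, 200), function(nd) {
    cfg_i <- sim_config(n_locations = 8, n_per_location = 12, n_chromosomes = 1,
                        chrom_length = 2e6, snp_density = 5e-3,
                        F_neutral = 0.005, coverage_mean = 0.7,
                        error_rate = 0.01, seed = 55,
                        inversions = list(inversion_spec("chr01", 5e5, 15e5, nd,
                          stats::setNames(seq(0.2, 0.8, length.out = 8), locs))))
    di <- simulate_dataset(cfg_i)
    gli <- compute_gl(di$counts, 0.01, di$sites, di$manifest$individual)
    si <- apply_site_filters(di$counts, gli, min_ind = 10)
    glsi <- gl_subset(gli, sites = si$site)
    ci <- genotype_inversion(glsi, list(chrom = "chr01", start = 5e5, end = 15e5),
                             "inv1", min_separation = 3)
    swap_aware_accuracy(ci$genotype, di$truth$inv_dosage[, 1])
  }, 0)
  expect_true(all(diff(acc) > 0))
  expect_gte(acc[3], 0.98)

  # all individuals truly AA -> degenerate clustering error
  cfg0 <- sim_config(n_locations = 8, n_per_location = 12, n_chromosomes = 1,
                     chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.005,
                     coverage_mean = 0.7, error_rate = 0.01, seed = 56,
                     inversions = list(inversion_spec("chr01", 5e5, 15e5, 200,
                       stats::setNames(rep(0, 8), locs))))
  d0 <- simulate_dataset(cfg0)
  gl0 <- compute_gl(d0$counts, 0.01, d0$sites, d0$manifest$individual)
  s0 <- apply_site_filters(d0$counts, gl0, min_ind = 10)
  gls0 <- gl_subset(gl0, sites = s0$site)
  expect_error(genotype_inversion(gls0, list(chrom = "chr01", start = 5e5,
                                             end = 15e5), "inv0"),
               "degenerate clustering")

  expect_error(genotype_inversion(gls, list(chrom = "chr01", start = 0,
                                            end = 2000), "tiny"),
               "fewer than 20")
})

test_that("haplotype frequencies and their convergence to the planted cline", {
  man <- data.frame(individual = sprintf("i%02d", 1:12),
                    location = rep("locA", 12), group = rep("g", 12))
  mk_calls <- function(geno) data.frame(individual = man$individual,
                                        region = "inv1", genotype = geno)
  expect_equal(haplotype_frequencies(mk_calls(rep("AA", 12)), man)$freq[1, 1], 0)
  expect_equal(haplotype_frequencies(mk_calls(rep("BB", 12)), man)$freq[1, 1], 1)
  g <- rep(c("AA", "AB", "BB"), c(3, 6, 3))
  expect_equal(haplotype_frequencies(mk_calls(g), man)$freq[1, 1], 0.5)

  # frequencies from calls converge to the simulator's q within binomial error
  locs <- sprintf("loc%02d", 1:8)
  q <- seq(0.2, 0.8, length.out = 8)
  cfg <- sim_config(n_locations = 8, n_per_location = 12, n_chromosomes = 1,
                    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.005,
                    coverage_mean = 2, error_rate = 0.01, seed = 52,
                    inversions = list(inversion_spec("chr01", 5e5, 15e5, 200,
                      stats::setNames(q, locs))))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl, min_ind = 10)
  gls <- gl_subset(gl, sites = snps$site)
  calls <- genotype_inversion(gls, list(chrom = "chr01", start = 5e5, end = 15e5),
                              "inv1")
  hf <- haplotype_frequencies(calls, d$manifest)
  est <- hf$freq[locs, 1]
  if (stats::cor(est, q) < 0) est <- 1 - est  # label swap
  se <- sqrt(q * (1 - q) / 24)
  expect_true(all(abs(est - q) <= 3 * se + 1e-9))
})

test_that("haplotype-frequency PCA gives scores, loadings and handles degenerate columns", {
  set.seed(57)
  freq <- matrix(runif(24), 6, 4,
                 dimnames = list(sprintf("loc%d", 1:6), sprintf("inv%d", 1:4)))
  freq[, 2] <- 0.4 # constant column
  p <- frequency_pca(freq)
  expect_lt(max(abs(p$loadings["inv2", ])), 1e-12)

  # rank-1 table: one gradient shared by all regions -> PC1 explains ~100%
  grad <- seq(0, 1, length.out = 6)
  f1 <- outer(grad, c(1, 0.5, 0.25, 2))
  p1 <- frequency_pca(f1)
  expect_gte(p1$var_explained[1], 0.999)

  # scores equal an independent SVD-based PCA up to sign
  sv <- svd(scale(freq, center = TRUE, scale = FALSE))
  sc <- sv$u %*% diag(sv$d)
  for (k in 1:3)
    expect_lt(min(max(abs(p$scores[, k] - sc[, k])),
                  max(abs(p$scores[, k] + sc[, k]))), 1e-9)

  expect_error(frequency_pca(freq[1:2, ]), "at least 3")
})

test_that("inter-inversion LD is null for independent inversions and exact for co-inherited ones", {
  # group sizes large enough for |r| <= 0.3 to be a ~3-sigma null bound
  # (null sd of r is ~ 1/sqrt(n-1))
  locs <- sprintf("loc%02d", 1:4)
  q1 <- stats::setNames(rep(0.5, 4), locs)
  cfg <- sim_config(n_locations = 4, n_per_location = 60, n_chromosomes = 2,
                    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.005,
                    coverage_mean = 2, error_rate = 0.01, seed = 58,
                    inversions = list(
                      inversion_spec("chr01", 5e5, 15e5, 200, q1),
                      inversion_spec("chr02", 5e5, 15e5, 200, q1)))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl, min_ind = 10)
  gls <- gl_subset(gl, sites = snps$site)
  calls <- rbind(
    genotype_inversion(gls, list(chrom = "chr01", start = 5e5, end = 15e5), "inv1"),
    genotype_inversion(gls, list(chrom = "chr02", start = 5e5, end = 15e5), "inv2"))
  ld <- inter_inversion_ld(calls, d$manifest)
  expect_true(all(abs(ld$r) <= 0.3))

  # perfectly co-inherited regions -> r^2 = 1; label swap flips r only
  man <- data.frame(individual = sprintf("i%02d", 1:10),
                    location = "locA", group = "g")
  g <- rep(c("AA", "AB", "BB"), c(3, 4, 3))
  calls2 <- rbind(data.frame(individual = man$individual, region = "r1", genotype = g),
                  data.frame(individual = man$individual, region = "r2", genotype = g))
  ld2 <- inter_inversion_ld(calls2, man)
  expect_equal(ld2$r2, 1)
  swap <- c(AA = "BB", AB = "AB", BB = "AA")
  calls3 <- calls2
  calls3$genotype[calls3$region == "r2"] <- swap[calls3$genotype[calls3$region == "r2"]]
  ld3 <- inter_inversion_ld(calls3, man)
  expect_equal(ld3$r, -ld2$r)
  expect_equal(ld3$r2, ld2$r2)
})
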