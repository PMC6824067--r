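# small deterministic window scaffold: 100 windows of 15 kb on one chromosome
mk_windows <- function(values, chrom = "chr01", size = 15000L) {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * size,
             end = seq_len(n) * size, n_sites = 20L, value = values)
}

test_that("neutral set removes exactly the top windows and buffered inversions", {
  set.seed(60)
  v1 <- runif(100); v2 <- runif(100)
  v1[c(10, 30, 50, 70, 90)] <- 2 + runif(5)  # planted extremes, comparison 1
  v2[c(15, 30, 85, 95, 99)] <- 2 + runif(5)  # comparison 2
  wins <- list(c1 = mk_windows(v1), c2 = mk_windows(v2))
  snp_sites <- data.frame(chrom = "chr01", pos = seq(0L, 1499999L, by = 500L))
  ns <- build_neutral_set(wins, snp_sites, top_fraction = 0.05)

  # oracle: hand enumeration of the top-5% union
  top_idx <- union(order(-v1)[1:5], order(-v2)[1:5])
  removed_iv <- mk_windows(rep(0, 100))[top_idx, c("start", "end")]
  in_removed <- rowSums(vapply(seq_len(nrow(removed_iv)), function(i)
    snp_sites$pos >= removed_iv$start[i] & snp_sites$pos < removed_iv$end[i],
    logical(nrow(snp_sites)))) > 0
  expect_equal(sort(ns$retained), which(!in_removed))

  # every retained SNP avoids every ledger interval (exhaustive)
  for (i in seq_len(nrow(ns$ledger)))
    expect_false(any(snp_sites$pos[ns$retained] >= ns$ledger$start[i] &
                       snp_sites$pos[ns$retained] < ns$ledger$end[i] &
                       snp_sites$chrom[ns$retained] == ns$ledger$chrom[i]))

  # inversion +/- buffer boundaries are half-open at single-bp resolution
  inv <- data.frame(chrom = "chr01", start = 600000L, end = 700000L)
  snp_edge <- data.frame(chrom = "chr01",
                         pos = c(499999L, 500000L, 799999L, 800000L))
  ns2 <- build_neutral_set(list(c1 = mk_windows(rep(0.1, 100))), snp_edge,
                           inversions = inv, buffer = 1e5, top_fraction = 0)
  expect_equal(ns2$retained, c(1L, 4L))

  # top_fraction = 0 and no inversions -> everything retained
  ns3 <- build_neutral_set(wins, snp_sites, top_fraction = 0)
  expect_equal(ns3$retained, seq_len(nrow(snp_sites)))

  # missing comparison errors by name
  expect_error(build_neutral_set(list(c1 = wins$c1, c2 = NULL), snp_sites),
               "c2")
})

test_that("neutral-set FST between planted groups drops relative to the full set", {
  locs <- sprintf("loc%02d", 1:4)
  groups <- stats::setNames(rep(c("spring", "winter"), each = 2), locs)
  cfg <- sim_config(n_locations = 4, n_per_location = 12, n_chromosomes = 2,
                    chrom_length = 2e6, snp_density = 5e-3, F_neutral = 0.002,
                    coverage_mean = 1, groups = groups, seed = 61,
                    outlier_regions = list(
                      outlier_spec("chr01", 8e5, 9.5e5, "spring", "winter", 0.5)))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl,
                             populations = split(seq_len(48), d$manifest$location),
                             min_ind = 3)
  gls <- gl_subset(gl, sites = snps$site)
  res <- pairwise_fst_matrix(gls, d$manifest, by = "group", min_ind = 3,
                             return_components = TRUE)
  fc <- res$components[["spring__winter"]]
  wins <- windowed_stat(gls$sites[fc$site, ], 15000, min_sites = 10,
                        alpha = fc$alpha, beta = fc$beta,
                        chrom_lengths = c(chr01 = 2e6, chr02 = 2e6))
  ns <- build_neutral_set(list(spring__winter = wins), gls$sites,
                          top_fraction = 0.05)
  full_fst <- weighted_fst(fc)
  neut_fst <- weighted_fst(fc, fc$site %in% ns$retained)
  expect_lte(neut_fst, full_fst / 2)
})

test_that("outlier windows are flagged at the percentile and merged across small gaps", {
  set.seed(62)
  v <- runif(10000)
  planted <- c(101, 102, 2000, 2002, 5000, 5500, 6000, 7777, 9000, 9999)
  v[planted] <- 5 + runif(10)
  wins <- mk_windows(v)
  reg <- detect_outlier_windows(wins, percentile = 99.9, merge_gap = 1)
  flagged <- unlist(lapply(seq_len(nrow(reg)), function(i)
    which(wins$start >= reg$start[i] & wins$end <= reg$end[i])))
  # exactly the planted windows qualify (merged regions may span gap windows)
  thr <- attr(reg, "threshold")
  expect_equal(which(v > thr), sort(planted))
  # adjacency merging: 101+102 merge, 2000+2002 merge (gap of one window)
  expect_equal(nrow(reg), 8)

  # all-equal values: nothing strictly exceeds the threshold
  expect_equal(nrow(detect_outlier_windows(mk_windows(rep(1, 2000)))), 0)

  # percentile = 0 flags every window strictly above the minimum; the three
  # adjacent qualifying windows merge into one region spanning them
  v0 <- c(1, 2, 3, 4)
  reg0 <- detect_outlier_windows(mk_windows(v0), percentile = 0, merge_gap = 0)
  expect_equal(which(v0 > attr(reg0, "threshold")), 2:4)
  expect_equal(nrow(reg0), 1)
  expect_equal(c(reg0$start, reg0$end), c(15000, 60000))

  # few windows -> threshold-instability warning
  expect_warning(detect_outlier_windows(mk_windows(runif(100))), "unstable")

  # inversion-overlapping windows are excluded before the percentile
  v2 <- runif(2000)
  v2[100] <- 10
  excl <- data.frame(chrom = "chr01", start = 99 * 15000L, end = 100 * 15000L)
  reg2 <- detect_outlier_windows(mk_windows(v2), percentile = 99.9,
                                 exclude = excl)
  expect_false(any(reg2$start <= 99 * 15000 & reg2$end >= 100 * 15000))
})

test_that("gene annotation reports exactly the genes near window centers", {
  genes <- data.frame(chrom = "chr01",
                      start = c(7000L, 40000L, 100000L, 22000L, 23000L),
                      end = c(8000L, 41000L, 101000L, 23000L, 24000L),
                      id = sprintf("g%d", 1:5))
  wins <- mk_windows(rep(0, 3))           # [0,15000), [15000,30000), [30000,45000)
  regions <- data.frame(chrom = "chr01", start = 0L, end = 15000L)
  ann <- annotate_regions(regions, wins, genes, flank = 15000)
  # window center 7500: query [‑7500, 22500): genes g1 (at the center) and g4
  expect_equal(ann$genes, "g1,g4")

  # gene entirely farther than flank from every center -> not reported
  far <- data.frame(chrom = "chr01", start = 3e6, end = 3.1e6, id = "far")
  ann2 <- annotate_regions(regions, wins, far, flank = 15000)
  expect_equal(ann2$genes, "")

  # brute-force intersection oracle over all 5 genes x 3 windows
  for (w in 1:3) {
    reg_w <- data.frame(chrom = "chr01", start = wins$start[w], end = wins$end[w])
    ann_w <- annotate_regions(reg_w, wins, genes, flank = 15000)
    ctr <- (wins$start[w] + wins$end[w]) / 2
    oracle <- genes$id[genes$start < ctr + 15000 & genes$end > ctr - 15000]
    got <- strsplit(ann_w$genes, ",")[[1]]
    expect_setequal(got %||% character(0), oracle)
  }
})

test_that("peak SNP selection keeps the planted extremes with stated tie rules", {
  set.seed(63)
  n <- 1000
  pos <- sort(sample.int(5e5, n))
  fstv <- runif(n, 0, 0.1)
  planted <- sample.int(n, 10)
  fstv[planted] <- 0.9 + runif(10) / 10
  m <- cbind(compA = fstv, compB = runif(n, 0, 0.1))
  sel <- select_peak_snps(pos, m, c(compA = 0.5, compB = 0.1),
                          top_fraction = 0.01, min_snps = 10)
  expect_equal(sel$comparison, "compA")
  expect_setequal(sel$snps, planted)

  # fewer SNPs than min_snps -> all selected with a warning
  expect_warning(
    sel2 <- select_peak_snps(pos[1:5], m[1:5, , drop = FALSE],
                             c(compA = 0.5), min_snps = 10), "selecting all")
  expect_equal(length(sel2$snps), 5)

  # exact tie at the cutoff -> the lower-position SNP is kept
  pos3 <- c(100L, 200L, 300L)
  m3 <- cbind(compA = c(0.5, 0.9, 0.5))
  sel3 <- select_peak_snps(pos3, m3, c(compA = 1), top_fraction = 0.5,
                           min_snps = 2)
  expect_equal(sel3$snps, c(1L, 2L))
})

test_that("heat-map rescaling maps location means onto [-1, 1] exactly", {
  expect_equal(rescale_scores(c(2, 0, -3)), c(1, 0.2, -1))
  x <- rnorm(8)
  r <- rescale_scores(x)
  expect_equal(max(r), 1)
  expect_equal(min(r), -1)
  expect_warning(r0 <- rescale_scores(rep(1, 4)), "undefined")
  expect_equal(r0, rep(0, 4))
})

test_that("planted outlier regions put the two spawning groups at opposite heat-map extremes", {
  locs <- sprintf("loc%02d", 1:6)
  groups <- stats::setNames(rep(c("spring", "winter", "other"), each = 2), locs)
  cfg <- sim_config(n_locations = 6, n_per_location = 12, n_chromosomes = 1,
                    chrom_length = 1e6, snp_density = 5e-3, F_neutral = 0.002,
                    coverage_mean = 2, groups = groups, seed = 64,
                    outlier_regions = list(
                      outlier_spec("chr01", 4e5, 6e5, "spring", "winter", 0.7)))
  d <- simulate_dataset(cfg)
  gl <- compute_gl(d$counts, 0.01, d$sites, d$manifest$individual)
  snps <- apply_site_filters(d$counts, gl, min_ind = 20)
  gls <- gl_subset(gl, sites = snps$site)
  idx <- which(gls$sites$pos >= 4e5 & gls$sites$pos < 6e5)
  hm <- region_pc1_heatmap(gls, list(peak1 = idx), d$manifest)
  spring_locs <- locs[groups[locs] == "spring"]
  winter_locs <- locs[groups[locs] == "winter"]
  s <- hm[1, spring_locs]; w <- hm[1, winter_locs]
  # the groups occupy opposite extremes with consistent signs within group
  expect_true(all(s > 0) && all(w < 0) || all(s < 0) && all(w > 0))
  expect_true(max(abs(c(s, w))) == 1)
})
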