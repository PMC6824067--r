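#' Specify a chromosomal inversion polymorphism for simulation
#'
#' An inversion is modelled as a non-recombining two-haplotype (A/B) locus.
#' `n_diagnostic_sites` SNPs inside the region are fixed-different between the
#' two haplotype classes (so they are in complete LD with the inversion), a
#' fraction `within_poly_frac` of the remaining in-region sites segregate
#' independently of haplotype class (within-class polymorphism), and the rest
#' are monomorphic, mimicking reduced diversity inside inversions.
#'
#' @param chrom chromosome name.
#' @param start,end region bounds in bp, 0-based half-open.
#' @param n_diagnostic_sites number of fixed-different diagnostic SNPs.
#' @param q_by_location named numeric vector: frequency of haplotype B per
#'   sampling location, each in \[0, 1\].
#' @param within_poly_frac fraction of non-diagnostic in-region sites that are
#'   polymorphic within haplotype class (default 0.05).
#' @return an object of class `inversion_spec`.
#' @export
inversion_spec <- function(chrom, start, end, n_diagnostic_sites, q_by_location,
                           within_poly_frac = 0.05) {
  stopifnot(length(chrom) == 1L, start >= 0, end > start,
            n_diagnostic_sites >= 1, within_poly_frac >= 0, within_poly_frac <= 1)
  if (any(q_by_location < 0 | q_by_location > 1))
    stop("inversion haplotype frequencies q must lie in [0, 1]")
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end),
                 n_diagnostic_sites = as.integer(n_diagnostic_sites),
                 q_by_location = q_by_location,
                 within_poly_frac = within_poly_frac),
            class = "inversion_spec")
}

#' Specify a planted outlier region
#'
#' Inside the region, per-location allele frequencies of the two affected
#' group sets are shifted apart: locations in `groups_a` get `-delta/2`,
#' locations in `groups_b` get `+delta/2`, clipped to \[0, 1\], so the
#' between-group-set frequency difference is `delta` wherever clipping does
#' not bind.
#'
#' @param chrom chromosome name.
#' @param start,end region bounds in bp, 0-based half-open.
#' @param groups_a,groups_b character vectors of group labels (disjoint).
#' @param delta allele-frequency shift between the two group sets, in (0, 1\].
#' @return an object of class `outlier_spec`.
#' @export
outlier_spec <- function(chrom, start, end, groups_a, groups_b, delta) {
  stopifnot(length(chrom) == 1L, start >= 0, end > start,
            delta > 0, delta <= 1, length(groups_a) >= 1, length(groups_b) >= 1)
  if (length(intersect(groups_a, groups_b)) > 0)
    stop("outlier group sets must be disjoint")
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), groups_a = groups_a,
                 groups_b = groups_b, delta = delta),
            class = "outlier_spec")
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic low-coverage dataset:
#' sampling design, Balding-Nichols neutral differentiation, planted
#' inversions and outlier regions, and the sequencing model (per-individual
#' mean coverage drawn from a Gamma distribution; scalar per-base miscall
#' rate). Defaults emulate a low-coverage marine population-genomic design:
#' many locations with ~12 diploids each, mean coverage ~0.7X, very low
#' neutral differentiation.
#'
#' @param n_locations number of sampling locations.
#' @param n_per_location diploid individuals per location.
#' @param groups named character vector mapping location -> group label;
#'   default: each location is its own group.
#' @param n_chromosomes,chrom_length genome layout (chromosome count, bp).
#' @param snp_density expected SNPs per bp.
#' @param F_neutral Balding-Nichols differentiation parameter, in (0, 1).
#' @param inversions list of [inversion_spec()] objects.
#' @param outlier_regions list of [outlier_spec()] objects.
#' @param coverage_mean mean fold-coverage lambda; per-individual lambda_i ~
#'   Gamma(shape = `coverage_shape`, scale = `coverage_mean`/`coverage_shape`),
#'   giving an overdispersed 0.16-1.93X-style spread at the default shape 4.
#' @param coverage_shape Gamma shape for the coverage distribution.
#' @param error_rate per-base miscall probability epsilon, in \[0, 0.25\].
#' @param seed master integer seed; all stages derive child seeds from it via
#'   [derive_seed()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_locations = 20, n_per_location = 12, groups = NULL,
                       n_chromosomes = 5, chrom_length = 2e6,
                       snp_density = 5e-3, F_neutral = 0.005,
                       inversions = list(), outlier_regions = list(),
                       coverage_mean = 0.7, coverage_shape = 4,
                       error_rate = 0.01, seed = 1) {
  locations <- sprintf("loc%02d", seq_len(n_locations))
  if (is.null(groups)) {
    groups <- stats::setNames(locations, locations)
  } else {
    if (!all(locations %in% names(groups)))
      stop("groups must name every location")
    groups <- groups[locations]
  }
  if (!(F_neutral > 0 && F_neutral < 1)) stop("F_neutral must lie in (0, 1)")
  if (error_rate < 0 || error_rate > 0.25) stop("error_rate must lie in [0, 0.25]")
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  if (snp_density <= 0 || n_chromosomes < 1 || chrom_length < 1)
    stop("invalid genome layout")
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))

  regions <- c(inversions, outlier_regions)
  for (r in regions) {
    if (!r$chrom %in% chroms) stop("region chromosome not in genome: ", r$chrom)
    if (r$end > chrom_length) stop("region exceeds chromosome bounds")
  }
  if (length(regions) > 1) {
    for (i in seq_len(length(regions) - 1)) for (j in (i + 1):length(regions)) {
      a <- regions[[i]]; b <- regions[[j]]
      if (a$chrom == b$chrom && overlaps(a$start, a$end, b$start, b$end))
        stop("simulated regions must not overlap (regions ", i, " and ", j, ")")
    }
  }
  for (inv in inversions) {
    if (!all(names(inv$q_by_location) %in% locations) &&
        length(inv$q_by_location) != n_locations)
      stop("inversion q_by_location must cover all locations")
  }
  grp <- unique(unname(groups))
  for (o in outlier_regions) {
    if (!all(c(o$groups_a, o$groups_b) %in% grp))
      stop("outlier group sets must be existing group labels")
  }

  structure(list(
    n_locations = n_locations, n_per_location = n_per_location,
    locations = locations, groups = groups,
    n_chromosomes = n_chromosomes, chroms = chroms,
    chrom_length = as.integer(chrom_length), snp_density = snp_density,
    F_neutral = F_neutral, inversions = inversions,
    outlier_regions = outlier_regions, coverage_mean = coverage_mean,
    coverage_shape = coverage_shape, error_rate = error_rate,
    seed = as.integer(seed)), class = "sim_config")
}

#' Sample manifest for a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `individual`, `location`, `group`.
#' @export
sim_manifest <- function(config) {
  loc <- rep(config$locations, each = config$n_per_location)
  data.frame(
    individual = sprintf("%s_i%02d", loc,
                         rep(seq_len(config$n_per_location), config$n_locations)),
    location = loc,
    group = unname(config$groups[loc]),
    stringsAsFactors = FALSE)
}

#' Simulate per-location allele frequencies (Balding-Nichols)
#'
#' Ancestral minor-allele frequencies are drawn Uniform(0.05, 0.95) per site;
#' each location's frequency is an independent draw from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose expected Hudson FST against a second
#' such location is F. Planted outlier regions then shift the frequencies of
#' the two affected group sets by -delta/2 / +delta/2 (clipped to \[0, 1\]).
#' Sites inside inversions are left at their Balding-Nichols values here;
#' the inversion stage overrides them (frequencies inside inversions are a
#' property of haplotype class, not location).
#'
#' @param config a [sim_config()].
#' @param sites data.frame with columns `chrom`, `pos` (0-based). If `NULL`,
#'   positions are drawn from the configured SNP density.
#' @param seed integer seed (default derived from the config seed).
#' @return list with `sites`, `p_anc` (length-S vector) and `freq`
#'   (S x n_locations matrix).
#' @export
simulate_frequencies <- function(config, sites = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sites)) sites <- sim_sites(config)
  S <- nrow(sites)
  set.seed(seed %||% derive_seed(config$seed, 2L))
  p <- stats::runif(S, 0.05, 0.95)
  F <- config$F_neutral
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  freq <- matrix(NA_real_, S, config$n_locations,
                 dimnames = list(NULL, config$locations))
  for (l in seq_len(config$n_locations))
    freq[, l] <- stats::rbeta(S, a, b)

  for (o in config$outlier_regions) {
    idx <- which(sites$chrom == o$chrom & in_interval(sites$pos, o$start, o$end))
    if (!length(idx)) next
    la <- config$locations[unname(config$groups) %in% o$groups_a]
    lb <- config$locations[unname(config$groups) %in% o$groups_b]
    freq[idx, la] <- clip(freq[idx, la] - o$delta / 2, 0, 1)
    freq[idx, lb] <- clip(freq[idx, lb] + o$delta / 2, 0, 1)
  }
  list(sites = sites, p_anc = p, freq = freq)
}

# Draw SNP positions for each chromosome.
sim_sites <- function(config, seed = NULL) {
  set.seed(seed %||% derive_seed(config$seed, 1L))
  out <- lapply(config$chroms, function(ch) {
    n <- max(1L, round(config$chrom_length * config$snp_density))
    data.frame(chrom = ch,
               pos = sort(sample.int(config$chrom_length, n) - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate inversion genotypes and within-region site genotypes
#'
#' Each individual carries two haplotype copies; each copy is class B with
#' probability `q_by_location[location]` (so the inversion genotype is
#' Binomial(2, q)). Diagnostic sites are fixed-different between classes
#' (minor allele fixed on B), hence in complete mutual LD. A fraction of the
#' remaining region sites is polymorphic within class (frequencies supplied
#' via `bg_freq`); the rest are monomorphic.
#'
#' @param spec an [inversion_spec()].
#' @param manifest sample manifest (see [sim_manifest()]).
#' @param region_positions positions (bp) of SNP-grid sites inside the region.
#' @param bg_freq matrix (length(region_positions) x n_locations) of
#'   background Balding-Nichols frequencies for within-class polymorphic
#'   sites.
#' @param seed integer seed.
#' @return list with `inv_dosage` (count of B haplotypes per individual),
#'   `geno` (sites x individuals minor-allele dosage), `diagnostic` (logical
#'   per site), `polymorphic` (logical per site), and `site_freq` (true
#'   per-location frequencies implied for the region sites).
#' @export
simulate_inversion_genotypes <- function(spec, manifest, region_positions,
                                         bg_freq, seed) {
  stopifnot(inherits(spec, "inversion_spec"))
  q <- spec$q_by_location[manifest$location]
  if (any(is.na(q))) stop("q_by_location missing some locations")
  nR <- length(region_positions)
  if (nR < spec$n_diagnostic_sites)
    stop("region contains fewer grid sites than n_diagnostic_sites")
  set.seed(seed)
  n <- nrow(manifest)
  inv_dosage <- stats::rbinom(n, 2, q)

  diagnostic <- rep(FALSE, nR)
  diagnostic[unique(round(seq(1, nR, length.out = spec$n_diagnostic_sites)))] <- TRUE
  rest <- which(!diagnostic)
  n_poly <- round(spec$within_poly_frac * length(rest))
  polymorphic <- rep(FALSE, nR)
  if (n_poly > 0) polymorphic[sample(rest, n_poly)] <- TRUE

  geno <- matrix(0L, nR, n)
  geno[diagnostic, ] <- matrix(rep(inv_dosage, each = sum(diagnostic)),
                               sum(diagnostic), n)
  if (any(polymorphic)) {
    loc_idx <- match(manifest$location, colnames(bg_freq))
    for (i in seq_len(n)) {
      f <- bg_freq[polymorphic, loc_idx[i]]
      geno[polymorphic, i] <- stats::rbinom(sum(polymorphic), 2, f)
    }
  }
  site_freq <- matrix(0, nR, ncol(bg_freq), dimnames = dimnames(bg_freq))
  site_freq[diagnostic, ] <- matrix(rep(spec$q_by_location[colnames(bg_freq)],
                                        each = sum(diagnostic)),
                                    sum(diagnostic), ncol(bg_freq))
  site_freq[polymorphic, ] <- bg_freq[polymorphic, , drop = FALSE]
  list(inv_dosage = inv_dosage, geno = geno, diagnostic = diagnostic,
       polymorphic = polymorphic, site_freq = site_freq)
}

#' Simulate read counts from true genotypes
#'
#' Per site and individual, depth ~ Poisson(lambda_i). Each read derives from
#' one of the individual's two allele copies (minor with probability g/2) and
#' is miscalled to each of the three other bases with probability
#' epsilon/3, so the observed category probabilities are
#' P(minor) = (g/2)(1-e) + (1-g/2)(e/3), P(other, 2 bases) = 2e/3 and
#' P(major) the remainder.
#'
#' @param genotypes sites x individuals matrix of minor-allele dosages
#'   (0/1/2).
#' @param lambda per-individual mean coverage (length = n individuals).
#' @param error_rate per-base miscall probability epsilon.
#' @param seed integer seed.
#' @return list of three sites x individuals integer matrices: `n_major`,
#'   `n_minor`, `n_other`.
#' @export
simulate_reads <- function(genotypes, lambda, error_rate, seed) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (error_rate < 0 || error_rate > 0.25) stop("error_rate must lie in [0, 0.25]")
  if (!all(genotypes %in% 0:2)) stop("dosages must be 0, 1 or 2")
  S <- nrow(genotypes); N <- ncol(genotypes)
  set.seed(seed)
  depth <- matrix(stats::rpois(S * N, rep(lambda, each = S)), S, N)
  e <- error_rate
  p_min_g <- (0:2) / 2 * (1 - e) + (1 - (0:2) / 2) * (e / 3)
  p_oth <- 2 * e / 3

  n_minor <- matrix(0L, S, N); n_other <- matrix(0L, S, N)
  for (g in 0:2) {
    m <- genotypes == g
    k <- sum(m)
    if (!k) next
    d <- depth[m]
    nm <- stats::rbinom(k, d, p_min_g[g + 1])
    rem <- d - nm
    p2 <- if (p_min_g[g + 1] >= 1) 0 else p_oth / (1 - p_min_g[g + 1])
    no <- stats::rbinom(k, rem, p2)
    n_minor[m] <- nm; n_other[m] <- no
  }
  n_major <- depth - n_minor - n_other
  list(n_major = n_major, n_minor = n_minor, n_other = n_other)
}

#' Simulate a complete low-coverage population-genomic dataset
#'
#' Runs all simulation stages (site placement, Balding-Nichols frequencies
#' with planted outliers, inversion genotypes, per-individual coverage, read
#' sampling) from the single master seed in the configuration and returns the
#' observed data together with full truth tables for parameter-recovery
#' checks. Reproducible bit-for-bit given (config, seed).
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_data`: list with `config`, `sites`
#'   (chrom, pos, major, minor), `manifest`, `lambda`, `counts`
#'   (n_major/n_minor/n_other matrices) and `truth` (p_anc, freq, genotypes,
#'   inv_dosage, regions).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- sim_manifest(config)
  n <- nrow(manifest)

  sites <- sim_sites(config, derive_seed(config$seed, 1L))
  fr <- simulate_frequencies(config, sites, derive_seed(config$seed, 2L))
  freq <- fr$freq
  S <- nrow(sites)

  # neutral genotypes
  set.seed(derive_seed(config$seed, 3L))
  geno <- matrix(0L, S, n)
  loc_idx <- match(manifest$location, config$locations)
  for (i in seq_len(n))
    geno[, i] <- stats::rbinom(S, 2, freq[, loc_idx[i]])

  # inversions override in-region genotypes and truth frequencies
  n_inv <- length(config$inversions)
  inv_dosage <- matrix(NA_integer_, n, n_inv,
                       dimnames = list(manifest$individual,
                                       names(config$inversions) %||%
                                         sprintf("inv%d", seq_len(n_inv))))
  regions <- list()
  for (k in seq_len(n_inv)) {
    inv <- config$inversions[[k]]
    idx <- which(sites$chrom == inv$chrom & in_interval(sites$pos, inv$start, inv$end))
    sim <- simulate_inversion_genotypes(inv, manifest, sites$pos[idx],
                                        freq[idx, , drop = FALSE],
                                        derive_seed(config$seed, 100L + k))
    geno[idx, ] <- sim$geno
    freq[idx, ] <- sim$site_freq
    inv_dosage[, k] <- sim$inv_dosage
    regions[[length(regions) + 1L]] <-
      data.frame(chrom = inv$chrom, start = inv$start, end = inv$end,
                 type = "inversion", name = colnames(inv_dosage)[k],
                 stringsAsFactors = FALSE)
  }
  for (k in seq_along(config$outlier_regions)) {
    o <- config$outlier_regions[[k]]
    regions[[length(regions) + 1L]] <-
      data.frame(chrom = o$chrom, start = o$start, end = o$end,
                 type = "outlier", name = sprintf("outlier%d", k),
                 stringsAsFactors = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               type = character(), name = character())

  set.seed(derive_seed(config$seed, 4L))
  lambda <- stats::rgamma(n, shape = config$coverage_shape,
                          scale = config$coverage_mean / config$coverage_shape)
  names(lambda) <- manifest$individual

  counts <- simulate_reads(geno, lambda, config$error_rate,
                           derive_seed(config$seed, 5L))

  set.seed(derive_seed(config$seed, 6L))
  bases <- c("A", "C", "G", "T")
  major <- sample(bases, S, replace = TRUE)
  minor <- vapply(major, function(b) sample(setdiff(bases, b), 1L), character(1))
  sites$major <- major; sites$minor <- unname(minor)

  structure(list(config = config, sites = sites, manifest = manifest,
                 lambda = lambda, counts = counts,
                 truth = list(p_anc = fr$p_anc, freq = freq, genotypes = geno,
                              inv_dosage = inv_dosage, regions = regions)),
            class = "sim_data")
}
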