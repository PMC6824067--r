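---
title: "Methods: genotype-likelihood population genomics at low coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population genomics at low coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, their assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## Why genotype likelihoods

At ~0.2–2X coverage a heterozygote is routinely observed through a single
read, so hard genotype calls are both biased and overconfident. Every
estimator in this package therefore propagates genotype *likelihoods*:
$P(\text{reads}_i \mid g)$ for dosage $g \in \{0,1,2\}$ of the minor allele.
Under a single scalar per-base error rate $\varepsilon$, a read is observed
as the minor allele with probability
$(g/2)(1-\varepsilon) + (1-g/2)\varepsilon/3$, as the major allele
symmetrically, and as each of the two other bases with probability
$\varepsilon/3$ — those reads multiply every genotype's likelihood by the
same constant, so they carry no genotype information but do count toward
depth filters. This is the samtools-style biallelic count model.
Assumptions: biallelic sites, reads independent given the genotype, one
genome-wide $\varepsilon$, no base-quality strings, no mapping bias. The
simulator generates data from exactly this model, so tests of downstream
estimators are not confounded by model misspecification; on real data the
scalar $\varepsilon$ is the roughest of these approximations.

## Allele frequencies and SNP calling

Per site, the minor-allele frequency maximizes
$\sum_i \log \sum_g w_g(f) L_i(g)$ with Hardy–Weinberg weights
$w(f) = \{(1-f)^2,\, 2f(1-f),\, f^2\}$, by EM:
$f \leftarrow \sum_i E[g_i \mid f]/2n$. Numerical choices: start $f_0 =
0.25$, stop at $|\Delta f| < 10^{-8}$ or 100 iterations, deterministic;
individuals with no reads contribute their prior mean, which leaves the
fixed point unchanged. A site where *no* individual has data has an
undefined frequency and returns `NA` with a warning (such sites are routine
at low coverage and are meant to be removed by the minimum-individuals
filter, so this is not a hard error).

Polymorphism is a likelihood-ratio test of $f = \hat f$ against $f = 0$ on
$\chi^2_1$. Site filters (defaults, all configurable):

| filter | default | rationale |
|---|---|---|
| minor-allele frequency | ≥ 0.01, inclusive | "≥ 1%" convention |
| LRT p-value | ≤ 10⁻⁶ | conservative polymorphism call |
| individuals with ≥ 1 read | ≥ 3 per population (or a fraction, e.g. 2/3, for a stringent set) | frequency estimability |
| summed depth | ≤ 1000 | repetitive-region guard; ~2X per individual at the study's scale |

Filters commute, so the retained set is evaluation-order independent.

## SAF, SFS, and weighted FST

The site allele frequency likelihood marginalizes individual genotypes over
the population's $2N$ chromosomes with the recursion $h^i[j] = \sum_g
\binom{2}{g} L_i(g)\, h^{i-1}[j-g]$, then divides by $\binom{2N}{j}$. Rows
are renormalized every step (and finally to max = 1, i.e. 0 in log space)
to avoid underflow; SAFs are likelihood-scale so the per-site constant is
irrelevant. The 1D/2D SFS is the maximum-likelihood mixture over allele
counts, fit by EM with a uniform start and per-site posteriors
$\propto \mathrm{SFS} \odot (\mathrm{SAF}_1 \otimes \mathrm{SAF}_2)$. The
plain EM crawls on large grids, so the update is SQUAREM-accelerated
(extrapolation along two EM steps) with a fallback to the unaccelerated
step whenever the extrapolation would lower the likelihood — the
log-likelihood trace is therefore non-decreasing by construction.
Convergence: $|\Delta \log L| < 10^{-6}$ or 200 EM evaluations.

FST uses the Hudson/Bhatia estimator as posterior expectations of
$\alpha = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{2N_1-1} - \frac{p_2(1-p_2)}{2N_2-1}$
and $\beta = p_1(1-p_2) + p_2(1-p_1)$ under the 2D-SFS prior, combined as a
*ratio of sums* $\sum\alpha/\sum\beta$. Hudson/Bhatia rather than Reynolds
because it is robust to the unequal sample sizes (12–25 per location)
typical of this design; the estimator switch is left as a configuration
stub. Negative estimates are retained, not clamped — they are informative
about sampling noise and the MDS consumes the raw matrix.

Windows tile each chromosome from coordinate 0 in fixed steps, half-open,
terminal partial windows kept. Defaults: 15 kb for FST scans with ≥ 10
sites per window, 5 kb for diversity with ≥ 5 sites; windows below the
minimum are reported as missing rather than dropped, and whether they enter
percentile computations is thereby an explicit, flagged choice.

## Tajima's D and dxy

Window spectra use an empirical-Bayes construction: per-site posterior
allele-count probabilities under the *global* per-population SFS prior,
summed within windows (a pure per-window EM is available as an option;
it is noisier for windows with few sites). From a window spectrum,
$\theta_\pi = \sum_j j(n-j)\,\mathrm{SFS}[j] / \binom{n}{2}$,
$\theta_W = S/a_1$, and D with the standard constants. $n$ is $2\times$
the number of individuals, ignoring per-site missingness — a documented
simplification; at very low coverage the effective $n$ is smaller and D is
mildly shrunk toward 0. dxy is computed per SNP from per-population
unfolded frequency estimates on a shared polarization,
$d_{xy} = f_1(1-f_2) + f_2(1-f_1)$.

Note the simulator's site frequencies are **not** neutral-equilibrium: the
ancestral frequency is Uniform(0.05, 0.95), which enriches
intermediate-frequency alleles, so Tajima's D on simulated data is positive
by construction. The D null check therefore simulates allele counts from a
$1/j$ spectrum directly; what passing it shows is that the estimator is
calibrated, not that the generator is a coalescent.

## Individual PCA and MDS

The covariance estimator is PCAngsd-style: expected dosages under
per-individual site frequencies, standardized by $\sqrt{2f_s(1-f_s)}$,
$C = \frac{1}{S}\sum_s z_s z_s^\top$; individual frequencies are re-predicted
each iteration from the top-$K$ PCs (rank-$K$ reconstruction of the
standardized dosage matrix, mapped back and clipped to
$[1/2n,\, 1-1/2n]$). $K$ defaults to 2 and is a parameter, not
auto-selected — the model-selection step of the original tool is out of
scope. Iteration: 10 updates with early stop at
$\lVert\Delta C\rVert_\infty < 10^{-6}$; with $K=0$ or 0 iterations the
estimator reduces to the single-pass standardized dosage covariance, which
is the documented baseline and the oracle-equivalence anchor (at high
coverage it must match standard PCA of the dosage matrix). Eigenvector
signs follow a deterministic convention (largest-magnitude entry positive);
scores are scaled by $\sqrt{S\lambda}$ so they coincide with conventional
PCA scores for exact dosages.

MDS is classical Torgerson scaling via `cmdscale` on the raw (unclamped)
FST matrix, as is conventional; variance explained is reported against the
sum of positive eigenvalues. Because `cmdscale` squares its input, scaling
the FST matrix by $c$ scales coordinates by $c$ (not $\sqrt c$).

## Inversion genotyping

A non-recombining inversion is a two-allele Mendelian locus; PCA restricted
to the region separates AA/AB/BB along PC1. Clustering must be
deterministic, so 1-D 3-means starts at (min, midrange, max), runs Lloyd
updates ≤ 100 iterations with ties to the lower-index cluster, and labels
clusters by ascending PC1 center. The orientation is unidentifiable, so all
truth comparisons are label-swap aware. An empty middle (heterozygote)
cluster is legal and reported.

Degenerate regions (e.g. every individual carrying the same orientation)
still produce three 3-means clusters from noise, so a separation heuristic
rejects calls when the smallest gap between non-empty cluster centers is
less than 3.8× the pooled within-cluster spread. The constant was
calibrated once on simulations at 0.7X: monomorphic regions score ~2.5–3.3,
genuinely trimodal regions ≥ 4.2. It errs toward refusing to genotype.

LD is the squared Pearson correlation of posterior expected dosages
(Rogers–Huff style) rather than an EM haplotype-frequency $r^2$. This is
simple and adequate for block detection and null checks, but it is
*attenuated* at low coverage: the posterior dosage carries reliability
$a < 1$, and pairwise dosage $r^2 \approx a^2 r^2_{\text{true}}$ (~0.3
between perfectly linked sites at 2X). Block-boundary detection against a
0.5 threshold therefore needs well-powered data (high coverage or large
samples); the inter-inversion null test is unaffected because its null is
zero either way. The block detector profiles per-10-kb-bin maxima of $r^2$
against the most-connected anchor SNP (chosen from a thinned set), smooths
with a running median, and reports the outermost qualifying SNPs of the
longest contiguous run — per-bin maxima because inversions carry
within-orientation polymorphism, so an arbitrary thinned SNP per bin is an
unreliable orientation tag.

## Outlier scan and neutral set

Per comparison, the outlier threshold is the 99.9th percentile of
non-missing window values (linear interpolation between order statistics,
the common software default; the spec of "upper percentile" leaves the
definition open) and qualification is *strictly greater*, so an all-equal
scan yields nothing. Qualifying windows merge across gaps of ≤ 1 window
("peaks" often skip one sub-threshold window). Windows overlapping
inversions are excluded before the percentile is computed — the exclusion
is interval-based, not whole-chromosome, and is the documented reading of
an ambiguous procedure. The neutral set removes the union of each
comparison's top 5% of windows (top $\lceil 0.05\,n \rceil$ by value, ties
broken by position) plus inversions ± 1 Mb.

"Most significant comparison" for a peak is operationalized as the largest
mean windowed FST over the region; peak SNPs are the top 1% by per-SNP
$\alpha/\beta$ within it, at least 10, ties to the lower position. The
heat map runs the individual PCA per region (all in-region SNPs for
inversions, peak SNPs for outliers), averages PC1 per location, and
rescales linearly so the extreme locations sit at exactly $+1$ and $-1$;
a region where all locations coincide is reported as all-zero with a
warning.

## The synthetic-data generator

What it emulates: many sampling locations with 12–15 diploids at mean
coverage ~0.7X (per-individual $\lambda_i \sim$ Gamma(shape 4, mean
$\bar\lambda$), reproducing an overdispersed ~0.15–1.9X spread); weak
neutral structure via Balding–Nichols frequencies with target FST $F$
(defaults $F = 0.005$, within the low range seen between weakly
differentiated marine populations); large non-recombining inversions with
location-specific haplotype frequencies, a configurable number of
fixed-different diagnostic sites, and 5% within-class polymorphic sites (a
free parameter — within-inversion polymorphism levels are not constrained
by the study design, and 5% keeps region PCAs realistically non-degenerate
while mimicking reduced in-inversion diversity via the remaining
monomorphic sites); narrow (30–500 kb) outlier regions shifting the two
affected group sets apart by $\pm\delta/2$ with clipping to $[0,1]$, so the
between-set difference equals $\delta$ where clipping does not bind.

What it does not emulate: read-level artifacts (FASTQ/BAM, mapping bias,
base-quality variation, indels), linkage between neutral sites (sites are
independent given frequencies), a coalescent site-frequency spectrum, sex
chromosomes, inbreeding, or relatedness. Consequently, passing tests
demonstrate estimator correctness and calibration under the generative
model the estimators assume — they do not certify behavior under alignment
artifacts or demographic history, which is exactly the gap a real-data
study's upstream QC addresses. A base-quality filter (minQ-style) has no
artifact counterpart here because qualities are not simulated; it is
documented, not emulated.

All randomness descends from one integer master seed through a documented
splitting scheme (`derive_seed`: a fixed affine map per stage in
$[0, 2^{31}-1)$), so every output is reproducible bit-for-bit and adding a
stage does not perturb earlier streams.

## Problem sizes

The shipped analysis and the heaviest tests use: a demo study of 8
locations × 12 individuals, 5 × 2 Mb chromosomes at 5 SNPs/kb (~50k sites,
~26k retained SNPs), run twice to verify bit-identical outputs;
frequency-recovery at $n = 100$ over 2,000 sites; FST recovery at $n =
50/50$ over 20k SNPs at 2X; and null checks at $n = 60$ per group. These
sizes make every distributional claim testable in minutes on one CPU while
keeping the estimators in the regime (thousands of sites, tens of
individuals) where their asymptotics are meaningful.

## Known limitations

- Scalar $\varepsilon$ and no per-base qualities; folded-spectrum handling
  and ancestral-state inference are out of scope (the simulator's
  polarization is known).
- Tajima's D constants use the full $2N$ regardless of per-site
  missingness.
- Dosage-correlation LD is attenuated at low coverage (see above); an EM
  haplotype $r^2$ would remove this at the cost of a second estimator.
- The inversion-genotyping separation constant (3.8) is a calibrated
  heuristic, not a test with a guaranteed error rate.
- Multi-allelic sites, kinship filtering and admixture estimation are not
  implemented.
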