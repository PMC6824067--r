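Package: glscan
Title: Genome Scans and Population Structure from Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype-likelihood-based population genomics for low-coverage
    whole-genome sequencing data. Computes biallelic genotype likelihoods from
    per-site read counts under the samtools error model, estimates minor allele
    frequencies by EM, calls SNPs with a likelihood-ratio polymorphism test,
    estimates site allele frequency likelihoods and (joint) site frequency
    spectra, computes Hudson/Bhatia weighted FST genome-wide and in windows,
    performs MDS of FST matrices and PCAngsd-style individual PCA, genotypes
    chromosomal inversion polymorphisms by localized PCA, builds putatively
    neutral SNP sets, detects and annotates outlier regions, and computes
    windowed Tajima's D and per-SNP dxy. Includes a Balding-Nichols simulator
    of low-coverage population-genomic data with planted inversions and
    outlier regions for end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
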