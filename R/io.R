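# fread with transparent gzip support (decompress via a gzfile connection,
# so no optional decompression package is needed)
fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    inp <- gzfile(path, "rb")
    out <- file(tmp, "wb")
    while (length(chunk <- readBin(inp, "raw", 8e6)) > 0) writeBin(chunk, out)
    close(inp); close(out)
    path <- tmp
  }
  data.table::fread(path, ...)
}

#' Write genotype likelihoods in beagle format
#'
#' Standard beagle GL text: `marker`, `allele1`, `allele2` (0=A, 1=C, 2=G,
#' 3=T) then three columns per individual with likelihoods normalized to sum
#' to one per site x individual, written with 6 significant digits.
#' Gzipped automatically when `path` ends in `.gz`.
#'
#' @param gl a `gl_matrix`.
#' @param path output file.
#' @export
write_beagle <- function(gl, path) {
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  S <- nrow(gl$logl[[1]])
  L <- lapply(gl$logl, exp)
  tot <- L[[1]] + L[[2]] + L[[3]]
  L <- lapply(L, function(x) x / tot)
  marker <- paste(gl$sites$chrom, gl$sites$pos, sep = "_")
  cols <- list(marker = marker,
               allele1 = base_code[gl$sites$major %||% rep("A", S)],
               allele2 = base_code[gl$sites$minor %||% rep("C", S)])
  for (i in seq_along(gl$individuals)) {
    id <- gl$individuals[i]
    for (g in 1:3)
      cols[[paste0(id, c("", ".1", ".2")[g])]] <- signif(L[[g]][, i], 6)
  }
  dt <- data.table::as.data.table(cols)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a beagle genotype-likelihood file
#'
#' @param path beagle file (optionally gzipped). Markers must be
#'   `chrom_pos` with 0-based positions, as written by [write_beagle()].
#' @return a `gl_matrix` (log-likelihoods renormalized so each triplet's
#'   maximum is 0).
#' @export
read_beagle <- function(path) {
  dt <- fread_auto(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 6 || (ncol(dt) - 3) %% 3 != 0)
    stop("malformed beagle file: expected 3 + 3k columns, got ", ncol(dt))
  bases <- c("A", "C", "G", "T")
  mk <- dt[[1]]
  us <- regexpr("_[0-9]+$", mk)
  if (any(us < 0)) stop("malformed marker id at line ",
                        which(us < 0)[1] + 1L, ": expected chrom_pos")
  chrom <- substr(mk, 1, us - 1)
  pos <- as.integer(substring(mk, us + 1))
  n <- (ncol(dt) - 3) %/% 3
  ids <- names(dt)[3 + 3 * seq_len(n) - 2]
  L <- lapply(1:3, function(g)
    as.matrix(dt[, 3 + 3 * (seq_len(n) - 1) + g, with = FALSE]))
  m <- pmax_list(lapply(L, function(x) pmax(x, 0)))
  if (any(m <= 0)) stop("malformed beagle file: zero likelihood triplet")
  logl <- lapply(L, function(x) log(pmax(x, .Machine$double.xmin)) - log(m))
  logl <- lapply(logl, function(x) { dimnames(x) <- NULL; x })
  structure(list(logl = logl,
                 sites = data.frame(chrom = chrom, pos = pos,
                                    major = bases[dt[[2]] + 1],
                                    minor = bases[dt[[3]] + 1],
                                    stringsAsFactors = FALSE),
                 individuals = ids),
            class = "gl_matrix")
}

#' Write / read a read-count matrix as (gzipped) TSV
#'
#' Long format: `site`, `individual`, `n_major`, `n_minor`, `n_other`;
#' sites identified as `chrom:pos`.
#'
#' @param counts list of count matrices.
#' @param sites site data.frame (`chrom`, `pos`).
#' @param individuals individual ids.
#' @param path output/input file (`.gz` for gzip).
#' @return `read_counts`: list with `counts`, `sites`, `individuals`.
#' @export
write_counts <- function(counts, sites, individuals, path) {
  S <- nrow(counts$n_major); N <- ncol(counts$n_major)
  dt <- data.table::data.table(
    site = rep(paste(sites$chrom, sites$pos, sep = ":"), N),
    individual = rep(individuals, each = S),
    n_major = as.vector(counts$n_major),
    n_minor = as.vector(counts$n_minor),
    n_other = as.vector(counts$n_other))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  dt <- fread_auto(path, sep = "\t", header = TRUE)
  need <- c("site", "individual", "n_major", "n_minor", "n_other")
  if (!all(need %in% names(dt))) stop("malformed counts file: need columns ",
                                      paste(need, collapse = ", "))
  usite <- unique(dt$site)
  uind <- unique(dt$individual)
  S <- length(usite); N <- length(uind)
  si <- match(dt$site, usite); ii <- match(dt$individual, uind)
  mk <- function(v) { m <- matrix(0L, S, N); m[cbind(si, ii)] <- v; m }
  cp <- regexpr(":[0-9]+$", usite)
  list(counts = list(n_major = mk(dt$n_major), n_minor = mk(dt$n_minor),
                     n_other = mk(dt$n_other)),
       sites = data.frame(chrom = substr(usite, 1, cp - 1),
                          pos = as.integer(substring(usite, cp + 1)),
                          stringsAsFactors = FALSE),
       individuals = uind)
}

#' Write / read BED intervals (0-based half-open)
#'
#' Three required columns plus an optional `name`. `read_bed` validates
#' coordinates and reports the offending line on error.
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path file path.
#' @return `read_bed`: data.frame `chrom`, `start`, `end` (+ `name`).
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  data.table::fwrite(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3) stop("malformed BED: fewer than 3 columns")
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (ncol(dt) >= 4) names(dt)[4] <- "name"
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0 |
                 dt$start > dt$end)
  if (length(bad))
    stop("malformed BED record at line ", bad[1], ": start > end or negative")
  as.data.frame(dt[, seq_len(min(4, ncol(dt))), with = FALSE])
}

#' Read gene annotations from GFF3
#'
#' Parses via `rtracklayer::import` and converts the 1-based inclusive GFF3
#' intervals to the package's 0-based half-open convention (a gene at
#' positions 101-200 becomes \[100, 200)). Records without a usable id
#' (ID, Name or gene_id attribute) are skipped with a warning.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return data.frame: `chrom`, `start`, `end`, `id`.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  md <- S4Vectors::mcols(gr)
  id <- as.character(md$ID %||% NA)
  if (all(is.na(id)) && "Name" %in% names(md)) id <- as.character(md$Name)
  if (all(is.na(id)) && "gene_id" %in% names(md)) id <- as.character(md$gene_id)
  bad <- is.na(id)
  if (any(bad)) {
    warning(sum(bad), " ", feature, " record(s) without an id skipped")
    gr <- gr[!bad]; id <- id[!bad]
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             id = id, stringsAsFactors = FALSE)
}

#' Write / read an SFS as whitespace-separated text
#'
#' 1D spectra on one line; 2D spectra as a matrix with one row per allele
#' count in population 1.
#'
#' @param sfs numeric vector or matrix from [sfs_em()].
#' @param path file path.
#' @return `read_sfs`: numeric vector or matrix.
#' @export
write_sfs <- function(sfs, path) {
  x <- unclass(sfs)
  if (is.matrix(x)) utils::write.table(x, path, row.names = FALSE,
                                       col.names = FALSE)
  else cat(paste(format(x, digits = 15), collapse = " "), "\n", file = path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) == 1) as.numeric(m) else m
}

#' Write / read the sample manifest
#' @param manifest data.frame `individual`, `location`, `group`.
#' @param path TSV path.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("individual", "location", "group")
  if (!all(need %in% names(m))) stop("manifest needs columns ",
                                     paste(need, collapse = ", "))
  m
}

#' Write / read a labelled square matrix (FST, covariance) as TSV
#' @param m matrix with dimnames.
#' @param path TSV path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write windowed statistics as TSV
#' @param windows data.frame from [windowed_stat()] or [windowed_tajima()].
#' @param path TSV path.
#' @export
write_windows <- function(windows, path) {
  data.table::fwrite(windows, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}
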