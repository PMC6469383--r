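#' Construct a genotype panel
#'
#' A `genotype_data` object holds an m-samples by p-SNPs dosage matrix
#' (minor-allele counts 0/1/2, `NA` for missing) together with sample ids and
#' per-SNP metadata (id, chromosome, 1-based position). Missing dosages are
#' preserved here; downstream modules mean-impute per SNP when they need a
#' complete matrix.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector, length `nrow(dosages)`.
#' @param snp_ids unique character vector, length `ncol(dosages)`.
#' @param chrom per-SNP chromosome labels (recycled if length 1).
#' @param pos per-SNP 1-based integer coordinates.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                          chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  m <- nrow(dosages); p <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(m))
  if (is.null(snp_ids)) snp_ids <- if (!is.null(colnames(dosages))) colnames(dosages) else paste0("snp", seq_len(p))
  if (is.null(chrom)) chrom <- rep("1", p)
  if (length(chrom) == 1L) chrom <- rep(chrom, p)
  if (is.null(pos)) pos <- seq_len(p)
  stopifnot(length(sample_ids) == m, length(snp_ids) == p,
            length(chrom) == p, length(pos) == p)
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  if (any(pos < 1)) stop("positions must be >= 1 (1-based coordinates)")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && any(bad < 0 | bad > 2)) stop("dosages must lie in [0, 2]")
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids),
                 chrom = as.character(chrom),
                 pos = as.integer(pos)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d samples x %d SNPs, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

#' Subset a genotype panel by sample and/or SNP index
#' @param x a `genotype_data` object
#' @param i sample index (rows), `j` SNP index (columns)
#' @param j,... see `i`
#' @export
`[.genotype_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$snp_ids)
  genotype_data(x$dosages[i, j, drop = FALSE],
                sample_ids = x$sample_ids[i], snp_ids = x$snp_ids[j],
                chrom = x$chrom[j], pos = x$pos[j])
}

#' Read genotypes from a PLINK v1 triple or a TSV dosage matrix
#'
#' TSV layout: header row of SNP ids, first column sample ids, entries 0/1/2
#' or `NA`. PLINK layout: `<path>.bed` (SNP-major, 2-bit), `.bim`, `.fam`.
#'
#' @param path file path; for `format = "plink"` the common prefix of the
#'   `.bed/.bim/.fam` triple (a `.bed` extension is tolerated and stripped).
#' @param format `"tsv"` or `"plink"`.
#' @return A [genotype_data] object.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_plink(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = NA)
  sample_ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_data(dos, sample_ids = sample_ids, snp_ids = colnames(tab)[-1])
}

#' Write genotypes
#'
#' @param g a [genotype_data] object
#' @param path output path (prefix for PLINK)
#' @param format `"tsv"` or `"plink"`
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(sample_id = g$sample_ids, g$dosages,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_genotypes_plink(g, path)
  }
  invisible(path)
}

# PLINK v1 .bed is SNP-major: per SNP, ceil(m/4) bytes, 2 bits per sample,
# low bits first. Codes: 00 hom minor (dosage 2), 01 missing, 10 het, 11 hom
# major (dosage 0).
plink_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

read_genotypes_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("PLINK file missing: ", f)
  bimtab <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  famtab <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(famtab); p <- nrow(bimtab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bytes_per_snp <- ceiling(m / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * p)
    stop(sprintf(".bed size inconsistent with .bim/.fam: expected %d data bytes, found %d",
                 bytes_per_snp * p, length(body)))
  ints <- as.integer(body)
  # unpack 2-bit codes, sample-fastest within each SNP block
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = p)
  blk <- matrix(ints, nrow = bytes_per_snp, ncol = p)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bytes_per_snp, by = 4), ] <- blk %/% (4L^k) %% 4L
  }
  dos <- matrix(plink_code_to_dosage[as.character(codes[seq_len(m), , drop = FALSE])],
                nrow = m, ncol = p)
  genotype_data(dos,
                sample_ids = as.character(famtab[[2]]),
                snp_ids = as.character(bimtab[[2]]),
                chrom = as.character(bimtab[[1]]),
                pos = as.integer(bimtab[[4]]))
}

write_genotypes_plink <- function(g, prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  m <- length(g$sample_ids); p <- length(g$snp_ids)
  dosage_to_code <- function(d) {
    code <- integer(length(d))
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code
  }
  bytes_per_snp <- ceiling(m / 4)
  out <- raw(3 + bytes_per_snp * p)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(p)) {
    code <- c(dosage_to_code(g$dosages[, j]), rep(0L, 4 * bytes_per_snp - m))
    byte <- code[seq(1, length(code), 4)] +
      4L * code[seq(2, length(code), 4)] +
      16L * code[seq(3, length(code), 4)] +
      64L * code[seq(4, length(code), 4)]
    out[3 + (j - 1) * bytes_per_snp + seq_len(bytes_per_snp)] <- as.raw(byte)
  }
  writeBin(out, paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(g$chrom, g$snp_ids, 0, g$pos, "A", "B"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$sample_ids, g$sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a phenotype table and align it with a genotype panel
#'
#' Two-column TSV (`sample_id`, value), header optional via `header`.
#' Samples present in the phenotype file but absent from the panel are
#' dropped with a warning; panel samples without a phenotype are dropped from
#' the returned alignment (reported in the warning).
#'
#' @param path TSV path
#' @param g optional [genotype_data] to align against
#' @param header does the file carry a header row?
#' @return A tibble with columns `sample_id`, `value`, ordered to match `g`
#'   when given.
#' @export
read_phenotype <- function(path, g = NULL, header = TRUE) {
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE)
  ph <- tibble::tibble(sample_id = as.character(tab[[1]]),
                       value = as.numeric(tab[[2]]))
  if (!is.null(g)) {
    extra <- setdiff(ph$sample_id, g$sample_ids)
    if (length(extra))
      warning("dropping ", length(extra),
              " phenotyped sample(s) absent from the genotype panel: ",
              paste(utils::head(extra, 5), collapse = ", "))
    ph <- ph[match(g$sample_ids, ph$sample_id), , drop = FALSE]
    keep <- !is.na(ph$sample_id) & !is.na(ph$value)
    if (!all(keep))
      warning(sum(!keep), " genotyped sample(s) lack a phenotype and are dropped")
    ph <- ph[keep, , drop = FALSE]
  }
  ph
}

#' Write a phenotype table
#' @param ph tibble with `sample_id`, `value`
#' @param path output TSV path
#' @export
write_phenotype <- function(ph, path) {
  utils::write.table(as.data.frame(ph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
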