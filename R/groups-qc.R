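#' Non-overlapping SNP grouping
#'
#' Each SNP belongs to exactly one group (genes, with ungrouped SNPs as
#' singletons). Stored as a per-SNP group id aligned with the SNP order of
#' the genotype panel.
#'
#' @param membership character vector, one group id per SNP.
#' @param snp_ids optional SNP ids (names for `membership`).
#' @return An object of class `group_structure` with fields `groups`
#'   (ordered unique ids), `membership` (per-SNP id) and `sizes` (named
#'   per-group SNP counts).
#' @export
group_structure <- function(membership, snp_ids = NULL) {
  membership <- as.character(membership)
  if (!is.null(snp_ids)) {
    stopifnot(length(snp_ids) == length(membership))
    names(membership) <- snp_ids
  }
  groups <- unique(membership)
  sizes <- table(factor(membership, levels = groups))
  structure(list(groups = groups,
                 membership = membership,
                 sizes = stats::setNames(as.integer(sizes), groups)),
            class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("<group_structure> %d SNPs in %d groups (sizes %d-%d)\n",
              length(x$membership), length(x$groups),
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Integer group index per SNP (1..n_groups), used by the solver
#' @param gs a [group_structure]
#' @return integer vector aligned with SNPs.
#' @export
group_index <- function(gs) {
  match(gs$membership, gs$groups)
}

#' Read a SNP-to-group map
#'
#' Two-column TSV (`snp_id`, `group_id`). SNPs in the file but not the panel
#' are an error, as are duplicate SNP rows (groups may not overlap). Panel
#' SNPs absent from the file become singleton groups named after the SNP.
#'
#' @param path TSV path
#' @param g [genotype_data] the grouping must cover
#' @param header does the file carry a header row?
#' @return A [group_structure] aligned with `g`'s SNP order.
#' @export
read_groups <- function(path, g, header = TRUE) {
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE)
  snp <- as.character(tab[[1]]); grp <- as.character(tab[[2]])
  if (anyDuplicated(snp)) {
    dup <- unique(snp[duplicated(snp)])
    stop("duplicate snp_id rows (overlapping groups are unsupported): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  unknown <- setdiff(snp, g$snp_ids)
  if (length(unknown))
    stop("group file names SNPs absent from the genotype panel: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  membership <- stats::setNames(g$snp_ids, g$snp_ids)  # default: singletons
  membership[snp] <- grp
  group_structure(unname(membership[g$snp_ids]), snp_ids = g$snp_ids)
}

#' Write a SNP-to-group map
#' @param gs a [group_structure] with named membership
#' @param path output TSV path
#' @export
write_groups <- function(gs, path) {
  utils::write.table(
    data.frame(snp_id = names(gs$membership), group_id = gs$membership),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign SNPs to genes with a flanking buffer
#'
#' A SNP is assigned to a gene iff its position lies in
#' `[start - buffer_bp, end + buffer_bp]` (1-based inclusive) on the same
#' chromosome. A SNP inside several buffered genes goes to the gene whose
#' body is nearest (distance 0 inside the body); ties go to the
#' lexicographically smallest gene id. SNPs outside every buffered gene
#' become singleton groups, so grouping never changes the SNP panel.
#'
#' @param g [genotype_data]
#' @param annotation data frame with columns `chrom`, `start`, `end`,
#'   `gene_id` (1-based inclusive gene bodies)
#' @param buffer_bp flank added up- and downstream of each gene body (default
#'   10 kb)
#' @return A [group_structure] over `g`'s SNPs.
#' @export
map_snps_to_genes <- function(g, annotation, buffer_bp = 10000) {
  ann <- as.data.frame(annotation)
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(ann)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (nrow(ann) == 0) stop("empty annotation")
  ann$chrom <- as.character(ann$chrom); ann$gene_id <- as.character(ann$gene_id)
  missing_chr <- setdiff(unique(g$chrom), unique(ann$chrom))
  if (length(missing_chr))
    warning("no annotated genes on chromosome(s): ",
            paste(missing_chr, collapse = ", "))
  membership <- g$snp_ids  # default singleton named after the SNP
  for (i in seq_along(g$snp_ids)) {
    hit <- ann$chrom == g$chrom[i] &
      g$pos[i] >= ann$start - buffer_bp &
      g$pos[i] <= ann$end + buffer_bp
    if (!any(hit)) next
    cand <- ann[hit, , drop = FALSE]
    dist <- pmax(0, cand$start - g$pos[i], g$pos[i] - cand$end)
    cand <- cand[dist == min(dist), , drop = FALSE]
    membership[i] <- min(cand$gene_id)
  }
  group_structure(membership, snp_ids = g$snp_ids)
}

per_snp_stats <- function(dos) {
  m <- nrow(dos)
  n_obs <- colSums(!is.na(dos))
  miss_rate <- 1 - n_obs / m
  afreq <- colMeans(dos, na.rm = TRUE) / 2          # allele frequency of counted allele
  maf <- pmin(afreq, 1 - afreq)
  # 1-df chi-square goodness of fit of genotype counts vs HWE expectation
  n0 <- colSums(dos == 0, na.rm = TRUE)
  n1 <- colSums(dos == 1, na.rm = TRUE)
  n2 <- colSums(dos == 2, na.rm = TRUE)
  pA <- afreq
  e0 <- n_obs * (1 - pA)^2; e1 <- n_obs * 2 * pA * (1 - pA); e2 <- n_obs * pA^2
  chisq <- rep(0, length(pA))
  ok <- pA > 0 & pA < 1 & n_obs > 0
  chisq[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  hwe_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hwe_p[!ok] <- 1  # monomorphic: HWE trivially holds; caught by the MAF rule
  tibble::tibble(maf = unname(maf), miss_rate = unname(miss_rate),
                 hwe_p = unname(hwe_p))
}

#' Quality-control filter for a genotype panel
#'
#' Removes SNPs with minor allele frequency below `maf_min`, missing rate
#' above `miss_max`, or a Hardy-Weinberg 1-df chi-square goodness-of-fit
#' p-value below `hwe_p_min`. A SNP failing several rules is attributed to
#' the first in the order MAF, missingness, HWE, so the report is
#' deterministic. MAF denominators count observed alleles only.
#'
#' @param g [genotype_data]
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param miss_max maximum missing rate (default 0.05)
#' @param hwe_p_min minimum HWE p-value (default 1e-4)
#' @return A list with `genotypes` (filtered [genotype_data]) and `report`
#'   (one-row tibble of counts plus the per-SNP statistics in
#'   `attr(report, "per_snp")`).
#' @export
qc_filter <- function(g, maf_min = 0.05, miss_max = 0.05, hwe_p_min = 1e-4) {
  if (length(g$snp_ids) == 0) stop("empty genotype panel")
  st <- per_snp_stats(g$dosages)
  fail_maf <- st$maf < maf_min
  fail_miss <- !fail_maf & st$miss_rate > miss_max
  fail_hwe <- !fail_maf & !fail_miss & st$hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_miss | fail_hwe)
  if (!any(keep))
    stop("QC removed every SNP (", length(keep), " input SNPs); check thresholds")
  report <- tibble::tibble(
    n_input = length(keep),
    n_removed_maf = sum(fail_maf),
    n_removed_missing = sum(fail_miss),
    n_removed_hwe = sum(fail_hwe),
    n_kept = sum(keep))
  attr(report, "per_snp") <- dplyr::mutate(st, snp_id = g$snp_ids, kept = keep)
  list(genotypes = g[, which(keep)], report = report)
}
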