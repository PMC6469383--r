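#' Standardize a dosage matrix for kinship and model fitting
#'
#' Missing dosages are replaced by the per-SNP mean; each column is centered
#' and, when `scale = TRUE`, divided by its sample standard deviation
#' (denominator m-1). Constant columns carry no information and are dropped
#' with a warning. The per-SNP means and scales are kept so the identical
#' transform can be applied to held-out samples at prediction time.
#'
#' @param g a [genotype_data] object or a numeric dosage matrix
#' @param scale divide by the per-SNP standard deviation? (centering always
#'   happens)
#' @return A list: `Z` (m x p_used standardized matrix), `center`, `scale`
#'   (per retained SNP), `kept` (indices of retained columns).
#' @export
standardize_genotypes <- function(g, scale = TRUE) {
  dos <- if (inherits(g, "genotype_data")) g$dosages else as.matrix(g)
  if (ncol(dos) < 1) stop("need at least one SNP")
  mu <- colMeans(dos, na.rm = TRUE)
  # mean-impute missing entries
  if (anyNA(dos)) {
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  sds <- apply(dos, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all SNP columns are constant after imputation")
  if (!all(keep))
    warning("dropping ", sum(!keep), " constant SNP column(s)")
  Z <- sweep(dos[, keep, drop = FALSE], 2, mu[keep], "-")
  sc <- if (scale) sds[keep] else rep(1, sum(keep))
  Z <- sweep(Z, 2, sc, "/")
  list(Z = Z, center = mu[keep], scale = sc, kept = which(keep))
}

#' Apply stored standardization to new dosages
#'
#' Columns are subset to the SNPs retained at training, missing entries are
#' imputed with the *training* means, then the training center/scale is
#' applied — no information leaks from the new samples.
#'
#' @param std the list returned by [standardize_genotypes()]
#' @param g new [genotype_data] or dosage matrix over the same SNP panel
#' @return standardized matrix with `length(std$kept)` columns.
#' @export
apply_standardization <- function(std, g) {
  dos <- if (inherits(g, "genotype_data")) g$dosages else as.matrix(g)
  dos <- dos[, std$kept, drop = FALSE]
  if (anyNA(dos)) {
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- std$center[idx[, 2]]
  }
  sweep(sweep(dos, 2, std$center, "-"), 2, std$scale, "/")
}

#' Realized relationship matrix from standardized genotypes
#'
#' K = Z Z^T / p with p the number of SNPs used, so the diagonal averages
#' about 1. Symmetric positive semidefinite up to round-off.
#'
#' @param Z column-standardized matrix from [standardize_genotypes()]
#' @return m x m symmetric matrix.
#' @export
compute_rrm <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) == 0) stop("no SNPs to build the relationship matrix from")
  K <- tcrossprod(Z) / ncol(Z)
  (K + t(K)) / 2
}

#' Eigendecompose a kinship matrix
#'
#' Full symmetric eigendecomposition K = U diag(S) U^T with eigenvalues
#' sorted descending. Small negative eigenvalues from round-off (within
#' `-tol`) are clamped to zero; larger negative eigenvalues are an error
#' because K must be positive semidefinite.
#'
#' @param K symmetric m x m matrix
#' @param tol asymmetry/negativity tolerance, relative to `trace(K)/m`
#' @return An object of class `kinship_eigen`: fields `K`, `U`
#'   (orthogonal), `S` (descending, >= 0), `sample_ids`.
#' @export
eigendecompose <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  asym <- max(abs(K - t(K)))
  if (asym > tol * max(1, max(abs(K))))
    stop("kinship matrix is not symmetric (max asymmetry ", signif(asym, 3), ")")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  neg_tol <- tol * max(1, sum(diag(K)) / nrow(K))
  if (min(e$values) < -neg_tol)
    stop("kinship matrix has a substantially negative eigenvalue: ",
         signif(min(e$values), 4))
  S <- pmax(e$values, 0)
  structure(list(K = K, U = e$vectors, S = S,
                 sample_ids = rownames(K)),
            class = "kinship_eigen")
}

#' @export
print.kinship_eigen <- function(x, ...) {
  cat(sprintf("<kinship_eigen> %d samples, eigenvalues in [%.3g, %.3g]\n",
              length(x$S), min(x$S), max(x$S)))
  invisible(x)
}

#' Build and decompose the kinship matrix of a genotype panel
#'
#' Convenience wrapper: standardize (optionally a marker subset), form the
#' realized relationship matrix, eigendecompose.
#'
#' @param g [genotype_data]
#' @param markers optional SNP ids or indices used to build K (default: all)
#' @param scale unit-variance scaling of columns (see
#'   [standardize_genotypes()])
#' @return A `kinship_eigen` object; the standardization is attached as
#'   `attr(, "standardization")`.
#' @export
kinship <- function(g, markers = NULL, scale = TRUE) {
  gk <- g
  if (!is.null(markers)) {
    j <- if (is.character(markers)) match(markers, g$snp_ids) else markers
    if (anyNA(j)) stop("unknown marker id(s) in `markers`")
    gk <- g[, j]
  }
  std <- standardize_genotypes(gk, scale = scale)
  K <- compute_rrm(std$Z)
  rownames(K) <- colnames(K) <- g$sample_ids
  ke <- eigendecompose(K)
  attr(ke, "standardization") <- std
  ke
}

#' Write / read a kinship matrix as TSV with sample ids
#' @param ke a `kinship_eigen` object (or plain matrix for writing)
#' @param path TSV path
#' @export
write_kinship <- function(ke, path) {
  K <- if (inherits(ke, "kinship_eigen")) ke$K else as.matrix(ke)
  tab <- data.frame(sample_id = rownames(K), K, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  K <- as.matrix(tab[, -1, drop = FALSE])
  rownames(K) <- as.character(tab[[1]])
  eigendecompose(K)
}
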