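#' Predict phenotypes of new samples
#'
#' Best prediction under the fitted mixed model: the fixed SNP effects plus
#' the kinship best linear unbiased predictor of the random effect,
#'
#'   y_hat' = X' b + K_{X'X} (K_{XX} + delta I)^{-1} (y - X b) + mean(y_train)
#'
#' where both kinship blocks are built from *training-sample*
#' standardization (means/scales and the training SNP divisor), so no
#' information leaks from the test samples, and the training phenotype mean
#' removed before null fitting is restored. The linear system is solved
#' directly, never via an explicit inverse.
#'
#' @param g_train training [genotype_data]
#' @param g_test test [genotype_data] on the identical SNP panel (ids and
#'   order)
#' @param y_train training phenotype vector or tibble with `value`
#' @param beta_hat fitted coefficient vector over the training panel's
#'   standardized columns (see `std`), e.g. from [fit_sgl()]
#' @param delta_hat positive variance ratio from the null model
#' @param std training standardization from [standardize_genotypes()]; when
#'   `NULL` it is recomputed from `g_train`
#' @return tibble with `sample_id`, `y_hat`.
#' @export
predict_phenotype <- function(g_train, g_test, y_train, beta_hat, delta_hat,
                              std = NULL) {
  if (is.data.frame(y_train)) y_train <- y_train$value
  y_train <- as.numeric(y_train)
  if (!identical(g_train$snp_ids, g_test$snp_ids))
    stop("test SNP panel must match the training panel (ids and order)")
  if (delta_hat <= 0) stop("delta_hat must be positive")
  if (is.null(std)) std <- standardize_genotypes(g_train)
  Z <- std$Z
  Zt <- apply_standardization(std, g_test)
  p <- ncol(Z)
  beta_hat <- as.numeric(beta_hat)
  if (length(beta_hat) != p)
    stop("beta_hat length ", length(beta_hat),
         " does not match the ", p, " standardized SNPs")
  Kxx <- tcrossprod(Z) / p
  Ktx <- tcrossprod(Zt, Z) / p
  y_mean <- mean(y_train)
  resid <- (y_train - y_mean) - drop(Z %*% beta_hat)
  blup <- drop(Ktx %*% solve(Kxx + delta_hat * diag(nrow(Kxx)), resid))
  tibble::tibble(sample_id = g_test$sample_ids,
                 y_hat = unname(drop(Zt %*% beta_hat) + blup + y_mean))
}
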