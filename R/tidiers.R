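#' Tidy a fitted sparse group lasso
#'
#' One row per nonzero coefficient.
#'
#' @param x an `sgl_fit`
#' @param ... unused
#' @return tibble with `snp_id` (or `term`), `beta`, `lambda`.
#' @export
tidy.sgl_fit <- function(x, ...) {
  nz <- which(x$beta != 0)
  ids <- names(x$beta)
  if (is.null(ids)) ids <- paste0("snp", seq_along(x$beta))
  tibble::tibble(snp_id = ids[nz], beta = unname(x$beta[nz]),
                 lambda = x$lambda)
}

#' @rdname tidy.sgl_fit
#' @export
glance.sgl_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, alpha = x$alpha,
                 n_nonzero = sum(x$beta != 0),
                 objective = x$objective, n_iter = x$n_iter,
                 kkt_residual = x$kkt_residual, converged = x$converged)
}

#' Tidy a lambda path (nonzero coefficients per lambda)
#' @param x a `lambda_path`
#' @param ... unused
#' @export
tidy.lambda_path <- function(x, ...) {
  ids <- rownames(x$beta)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(x$beta)))
  out <- lapply(seq_along(x$lambdas), function(l) {
    nz <- which(x$beta[, l] != 0)
    if (!length(nz)) return(NULL)
    tibble::tibble(lambda = x$lambdas[l], snp_id = ids[nz],
                   beta = x$beta[nz, l])
  })
  dplyr::bind_rows(out)
}

#' @rdname tidy.lambda_path
#' @export
glance.lambda_path <- function(x, ...) {
  tibble::tibble(n_lambda = length(x$lambdas),
                 lambda_max = max(x$lambdas), lambda_min = min(x$lambdas),
                 max_nonzero = max(x$nonzero), alpha = x$alpha,
                 all_converged = all(x$converged))
}

#' Tidy cross-validation results (one row per lambda)
#' @param x a `cv_result`
#' @param ... unused
#' @export
tidy.cv_result <- function(x, ...) x$table

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(best_lambda = x$best_lambda, best_index = x$best_index,
                 best_mean_explained_variance =
                   x$table$mean_explained_variance[x$best_index],
                 k_folds = x$k_folds)
}

#' Tidy stability-selection results (one row per SNP, ranked)
#' @param x a `stability_result`
#' @param ... unused
#' @export
tidy.stability_result <- function(x, ...) dplyr::arrange(x$table, .data$rank)

#' @rdname tidy.stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(n_snps = nrow(x$table), n_selected = length(x$selected),
                 threshold = x$threshold, n_resamples = x$n_resamples,
                 n_lambdas = length(x$lambdas_used), seed = x$seed)
}

#' Tidy a ranking evaluation (the curve points)
#' @param x a `ranking_eval`
#' @param ... unused
#' @export
tidy.ranking_eval <- function(x, ...) x$curve

#' @rdname tidy.ranking_eval
#' @export
glance.ranking_eval <- function(x, ...) {
  tibble::tibble(pr_auc = x$pr_auc, roc_auc = x$roc_auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a whole pipeline run (the ranked stability table)
#' @param x an `sgl_lmm_run`
#' @param ... unused
#' @export
tidy.sgl_lmm_run <- function(x, ...) tidy(x$stability)

#' @rdname tidy.sgl_lmm_run
#' @export
glance.sgl_lmm_run <- function(x, ...) {
  tibble::tibble(method = x$config$method, alpha = x$config$alpha,
                 delta = if (is.null(x$null_model)) NA_real_ else x$null_model$delta,
                 best_lambda = x$cv$best_lambda,
                 n_selected = length(x$stability$selected),
                 seed = x$config$seed)
}
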