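#' Choose the penalty by k-fold cross-validation on explained variance
#'
#' Rotated rows are shuffled (seeded) into `k_folds` folds. For each fold
#' the whole lambda path is refit on the training rows with warm starts, and
#' held-out explained variance `1 - ||y_test - X_test b||^2 /
#' ||y_test - mean(y_test)||^2` is recorded at every lambda. The winning
#' lambda maximizes the fold-mean. Cross-validation operates on the rotated
#' data with the full-data variance ratio, mirroring the single null fit of
#' the pipeline; pass `strict_refit = TRUE` to [run_pipeline()] for
#' per-subset re-rotation.
#'
#' @param problem an [sgl_problem]
#' @param path a `lambda_path` fit on the full data (supplies the lambda
#'   sequence)
#' @param k_folds number of folds (default 5)
#' @param seed integer seed for the fold shuffle
#' @param tol,max_iter solver controls, see [fit_sgl()]
#' @return An object of class `cv_result`: tibble `table` (lambda, mean and
#'   sd of explained variance, n_folds), `best_lambda`, `best_index`.
#' @export
cv_select_lambda <- function(problem, path, k_folds = 5, seed = 1,
                             tol = 1e-6, max_iter = 10000) {
  n <- problem$n
  if (n < 2 * k_folds) stop("need at least 2 rows per fold")
  lambdas <- path$lambdas
  rows <- withr_seed(seed, sample.int(n))
  fold_of <- integer(n); fold_of[rows] <- rep_len(seq_len(k_folds), n)
  ev <- matrix(NA_real_, nrow = length(lambdas), ncol = k_folds)
  for (f in seq_len(k_folds)) {
    test <- fold_of == f
    Xtr <- problem$X[!test, , drop = FALSE]
    ytr <- problem$y[!test]
    Xte <- problem$X[test, , drop = FALSE]
    yte <- problem$y[test]
    denom <- sum((yte - mean(yte))^2)
    if (denom == 0) {
      warning("fold ", f, " has zero-variance held-out response; skipped")
      next
    }
    sub <- problem
    sub$X <- Xtr; sub$y <- ytr; sub$n <- nrow(Xtr)
    res <- sgl_path_cpp(sub$X, sub$y, sub$grp, sub$w, sub$alpha,
                        vapply(lambdas, .lam_internal, numeric(1), problem = sub),
                        rep(0, sub$p), tol, max_iter, Inf)
    pred <- Xte %*% res$beta
    ev[, f] <- 1 - colSums((yte - pred)^2) / denom
  }
  mean_ev <- rowMeans(ev, na.rm = TRUE)
  sd_ev <- apply(ev, 1, stats::sd, na.rm = TRUE)
  best <- which.max(mean_ev)
  structure(list(table = tibble::tibble(lambda = lambdas,
                                        mean_explained_variance = mean_ev,
                                        sd_explained_variance = sd_ev,
                                        n_folds = rowSums(!is.na(ev))),
                 best_lambda = lambdas[best],
                 best_index = best,
                 k_folds = k_folds,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> best lambda = %.4g (index %d of %d), mean EV = %.3f\n",
              x$best_lambda, x$best_index, nrow(x$table),
              x$table$mean_explained_variance[x$best_index]))
  invisible(x)
}

#' Pick the stability-selection penalties from a fitted path
#'
#' Returns the CV-optimal lambda plus `n_extra` larger path values at evenly
#' spaced path indices (the path is geometric, so index spacing is log-lambda
#' spacing) between the start of the path and the optimum. When fewer than
#' `n_extra` informative larger points exist, all larger points are taken
#' with a warning.
#'
#' @param path a `lambda_path`
#' @param best_lambda the CV winner (must lie on the path)
#' @param n_extra number of additional, larger penalties (default 9, for 10
#'   total)
#' @return decreasing numeric vector of penalties containing `best_lambda`.
#' @export
pick_stability_lambdas <- function(path, best_lambda, n_extra = 9) {
  b <- which(abs(path$lambdas - best_lambda) <= 1e-12 * best_lambda)
  if (length(b) != 1) stop("best_lambda does not lie on the path")
  if (b == 1) stop("best_lambda equals lambda_max; the path is uninformative")
  if (b - 1 <= n_extra) {
    warning("only ", b - 1, " larger path point(s) available; using all of them")
    idx <- seq_len(b - 1)
  } else {
    idx <- unique(pmin(pmax(round(seq_len(n_extra) * b / (n_extra + 1)), 1), b - 1))
  }
  sort(unique(c(path$lambdas[idx], best_lambda)), decreasing = TRUE)
}

#' Rank SNPs by stability selection
#'
#' Draws `n_resamples` half-samples of the rotated rows without replacement;
#' on each, the sparse group lasso is fit at all the supplied penalties with
#' warm starts, and a SNP counts as selected in that resample iff its
#' coefficient is nonzero at any of them. The selection frequency over
#' resamples ranks the SNPs; those with frequency at or above `threshold`
#' (inclusive) form the selected set. Ties in frequency are broken by the
#' absolute full-data coefficient at `best_lambda`, then by SNP order.
#'
#' @param problem an [sgl_problem]
#' @param lambdas decreasing penalties (typically from
#'   [pick_stability_lambdas()])
#' @param n_resamples number of half-sample draws (default 100)
#' @param sample_frac fraction of rows per draw, at most 0.5
#' @param threshold selection-frequency cutoff (default 0.5)
#' @param seed integer seed; resample r uses derived seed `seed + r`
#' @param beta_full optional full-data coefficients at `best_lambda` for tie
#'   breaking
#' @param best_lambda the CV winner (metadata + tie break)
#' @param tol,max_iter solver controls
#' @return An object of class `stability_result`: tibble `table` (snp_id,
#'   group_id, frequency, selected, beta_at_best_lambda, rank), `selected`
#'   (ids), `lambdas_used`, `n_resamples`, `seed`.
#' @export
stability_select <- function(problem, lambdas, n_resamples = 100,
                             sample_frac = 0.5, threshold = 0.5, seed = 1,
                             beta_full = NULL, best_lambda = NULL,
                             tol = 1e-6, max_iter = 10000) {
  if (length(lambdas) == 0) stop("need at least one lambda")
  if (sample_frac > 0.5) stop("sample_frac must be <= 0.5 (half-sampling)")
  lambdas <- sort(lambdas, decreasing = TRUE)
  n <- problem$n; p <- problem$p
  n_sub <- floor(n * sample_frac)
  counts <- numeric(p)
  lam_int <- vapply(lambdas, .lam_internal, numeric(1), problem = problem)
  # the 1/(2n) scaling uses the subsample size, matching a fresh problem
  # built on those rows
  for (r in seq_len(n_resamples)) {
    rows <- withr_seed(seed + r, sample.int(n, n_sub))
    Xs <- problem$X[rows, , drop = FALSE]
    ys <- problem$y[rows]
    lam_r <- if (problem$scale_loss) lambdas else lambdas * n_sub
    res <- sgl_path_cpp(Xs, ys, problem$grp, problem$w, problem$alpha,
                        lam_r, rep(0, p), tol, max_iter, Inf)
    counts <- counts + as.numeric(rowSums(res$beta != 0) > 0)
  }
  freq <- counts / n_resamples
  snp_ids <- colnames(problem$X)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  bb <- if (is.null(beta_full)) rep(NA_real_, p) else as.numeric(beta_full)
  ord <- order(-freq, -abs(ifelse(is.na(bb), 0, bb)), seq_len(p))
  tab <- tibble::tibble(
    snp_id = snp_ids,
    group_id = problem$groups$membership,
    frequency = freq,
    selected = freq >= threshold,
    beta_at_best_lambda = bb,
    rank = order(ord))
  structure(list(table = tab,
                 selected = snp_ids[freq >= threshold],
                 lambdas_used = lambdas,
                 best_lambda = best_lambda,
                 n_resamples = n_resamples,
                 sample_frac = sample_frac,
                 threshold = threshold,
                 seed = seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d of %d SNPs selected (freq >= %.2f) over %d resamples\n",
              length(x$selected), nrow(x$table), x$threshold, x$n_resamples))
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
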