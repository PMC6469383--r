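#' Run the full association-mapping pipeline
#'
#' End-to-end: standardize genotypes, build and eigendecompose the kinship
#' matrix, estimate the null-model variance ratio delta, rotate the data,
#' fit the sparse group lasso lambda path, pick the penalty by k-fold
#' cross-validation, and rank SNPs by stability selection. The four
#' benchmark method variants share this one code path:
#' `method = "sgl-lmm"` (default), `"lasso-lmm"` (alpha forced to 1),
#' `"sgl"` and `"lasso"` (identity rotation, no mixed-model correction).
#'
#' @param g [genotype_data] (already QC-filtered, or pass `qc = TRUE`)
#' @param phenotype tibble (`sample_id`, `value`) or numeric vector aligned
#'   with `g`
#' @param groups a [group_structure] over `g`'s SNPs
#' @param alpha L1 share of the penalty (default 0.95)
#' @param method one of `"sgl-lmm"`, `"lasso-lmm"`, `"sgl"`, `"lasso"`
#' @param qc run [qc_filter()] first?
#' @param kinship_markers optional marker subset for the kinship matrix
#' @param nlam,lambda_min_ratio lambda path controls, see [fit_path()]
#' @param k_folds cross-validation folds
#' @param n_resamples,sample_frac,threshold stability-selection controls,
#'   see [stability_select()]
#' @param n_stability_lambdas total penalties used in stability selection
#'   (CV winner plus larger path values)
#' @param seed master integer seed (folds and resamples derive from it)
#' @param unweighted_groups use unit group weights instead of sqrt(size)
#' @param strict_refit re-estimate delta and the rotation inside every
#'   cross-validation fold (slower; default uses the single full-data null
#'   fit throughout)
#' @param tol,max_iter solver controls
#' @param out_dir optional directory: each stage writes its artifact there
#' @return An object of class `sgl_lmm_run` with elements `null_model`,
#'   `kinship`, `path`, `cv`, `stability`, `problem`, `standardization`,
#'   `config`.
#' @export
run_pipeline <- function(g, phenotype, groups, alpha = 0.95,
                         method = c("sgl-lmm", "lasso-lmm", "sgl", "lasso"),
                         qc = FALSE, kinship_markers = NULL,
                         nlam = 100, lambda_min_ratio = 0.01,
                         k_folds = 5, n_resamples = 100, sample_frac = 0.5,
                         threshold = 0.5, n_stability_lambdas = 10,
                         seed = 1, unweighted_groups = FALSE,
                         strict_refit = FALSE,
                         tol = 1e-6, max_iter = 10000, out_dir = NULL) {
  method <- match.arg(method)
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[%s] %s (%.1fs elapsed)", method, stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  if (method %in% c("lasso", "lasso-lmm")) alpha <- 1
  use_lmm <- method %in% c("sgl-lmm", "lasso-lmm")
  if (qc) {
    qcres <- qc_filter(g)
    kept <- qcres$genotypes$snp_ids
    groups <- group_structure(groups$membership[match(kept, g$snp_ids)],
                              snp_ids = kept)
    g <- qcres$genotypes
    log_stage(sprintf("QC: kept %d of %d SNPs", qcres$report$n_kept,
                      qcres$report$n_input))
  }
  if (is.data.frame(phenotype)) {
    phenotype <- phenotype[match(g$sample_ids, phenotype$sample_id), ]
    y <- phenotype$value
  } else y <- as.numeric(phenotype)
  if (anyNA(y)) stop("phenotype missing for some genotyped samples")

  std <- standardize_genotypes(g)
  if (length(std$kept) < length(g$snp_ids)) {
    groups <- group_structure(groups$membership[std$kept],
                              snp_ids = g$snp_ids[std$kept])
  }
  Z <- std$Z
  ke <- NULL; nm <- NULL
  if (use_lmm) {
    ke <- kinship(g, markers = kinship_markers)
    log_stage("kinship eigendecomposition")
    nm <- estimate_delta(ke, y)
    log_stage(sprintf("null model: delta = %.4g%s", nm$delta,
                      if (nm$flat_likelihood) " (flat)" else ""))
    rot <- rotate_data(ke, nm, y, Z)
  } else {
    rot <- identity_rotation(y, Z)
  }
  problem <- sgl_problem(rot, groups, alpha = alpha,
                         unweighted = unweighted_groups)
  path <- fit_path(problem, nlam = nlam, lambda_min_ratio = lambda_min_ratio,
                   tol = tol, max_iter = max_iter)
  log_stage(sprintf("lambda path: %d fits, %d-%d nonzero", nlam,
                    min(path$nonzero), max(path$nonzero)))
  cv <- if (strict_refit && use_lmm)
    cv_select_lambda_strict(g, y, groups, ke, path$lambdas, alpha,
                            k_folds = k_folds, seed = seed,
                            unweighted = unweighted_groups,
                            tol = tol, max_iter = max_iter)
  else
    cv_select_lambda(problem, path, k_folds = k_folds, seed = seed,
                     tol = tol, max_iter = max_iter)
  log_stage(sprintf("cross-validation: best lambda = %.4g (index %d)",
                    cv$best_lambda, cv$best_index))
  lams <- pick_stability_lambdas(path, cv$best_lambda,
                                 n_extra = n_stability_lambdas - 1)
  stab <- stability_select(problem, lams, n_resamples = n_resamples,
                           sample_frac = sample_frac, threshold = threshold,
                           seed = seed,
                           beta_full = path$beta[, cv$best_index],
                           best_lambda = cv$best_lambda,
                           tol = tol, max_iter = max_iter)
  log_stage(sprintf("stability selection: %d SNPs at freq >= %.2f",
                    length(stab$selected), threshold))
  run <- structure(list(null_model = nm, kinship = ke, path = path, cv = cv,
                        stability = stab, problem = problem,
                        standardization = std, genotypes = g, phenotype = y,
                        groups = groups,
                        config = list(method = method, alpha = alpha,
                                      nlam = nlam,
                                      lambda_min_ratio = lambda_min_ratio,
                                      k_folds = k_folds,
                                      n_resamples = n_resamples,
                                      sample_frac = sample_frac,
                                      threshold = threshold, seed = seed,
                                      unweighted_groups = unweighted_groups,
                                      strict_refit = strict_refit)),
                   class = "sgl_lmm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# per-fold re-rotation variant: delta and the eigenbasis are re-estimated on
# the training rows of every fold
cv_select_lambda_strict <- function(g, y, groups, ke_full, lambdas, alpha,
                                    k_folds = 5, seed = 1, unweighted = FALSE,
                                    tol = 1e-6, max_iter = 10000) {
  n <- length(y)
  rows <- withr_seed(seed, sample.int(n))
  fold_of <- integer(n); fold_of[rows] <- rep_len(seq_len(k_folds), n)
  ev <- matrix(NA_real_, nrow = length(lambdas), ncol = k_folds)
  for (f in seq_len(k_folds)) {
    test <- fold_of == f
    gtr <- g[which(!test), ]; gte <- g[which(test), ]
    std <- standardize_genotypes(gtr)
    gs_f <- if (length(std$kept) < length(gtr$snp_ids))
      group_structure(groups$membership[std$kept]) else groups
    ke <- kinship(gtr)
    nm <- estimate_delta(ke, y[!test])
    rot <- rotate_data(ke, nm, y[!test], std$Z)
    prob <- sgl_problem(rot, gs_f, alpha = alpha, unweighted = unweighted)
    res <- sgl_path_cpp(prob$X, prob$y, prob$grp, prob$w, prob$alpha,
                        lambdas, rep(0, prob$p), tol, max_iter, Inf)
    # held-out rows scored in the original basis with the fold's effects
    Zte <- apply_standardization(std, gte)
    yte <- y[test]
    denom <- sum((yte - mean(yte))^2)
    if (denom == 0) next
    for (l in seq_along(lambdas)) {
      pred <- predict_phenotype(gtr, gte, y[!test], res$beta[, l], nm$delta,
                                std = std)$y_hat
      ev[l, f] <- 1 - sum((yte - pred)^2) / denom
    }
  }
  mean_ev <- rowMeans(ev, na.rm = TRUE)
  best <- which.max(mean_ev)
  structure(list(table = tibble::tibble(lambda = lambdas,
                                        mean_explained_variance = mean_ev,
                                        sd_explained_variance = apply(ev, 1, stats::sd, na.rm = TRUE),
                                        n_folds = rowSums(!is.na(ev))),
                 best_lambda = lambdas[best], best_index = best,
                 k_folds = k_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.sgl_lmm_run <- function(x, ...) {
  cat(sprintf("<sgl_lmm_run> method %s, alpha = %.2f\n", x$config$method,
              x$config$alpha))
  if (!is.null(x$null_model)) print(x$null_model)
  print(x$cv); print(x$stability)
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$null_model))
    write_null_model(run$null_model, file.path(dir, "null_model.txt"))
  write_path(run$path, file.path(dir, "path.tsv"))
  utils::write.table(as.data.frame(run$cv$table), file.path(dir, "cv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$stability$table),
                     file.path(dir, "stability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfgtab <- data.frame(key = names(run$config),
                       value = vapply(run$config, as.character, ""))
  utils::write.table(cfgtab, file.path(dir, "run_config.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Benchmark the four method variants on a simulation grid
#'
#' For every simulated dataset and every method (lasso, sgl, lasso-lmm,
#' sgl-lmm), runs the pipeline and scores causal-SNP recovery by the PR-AUC
#' of stability frequencies against the causal mask.
#'
#' @param manifest output of [simulate_grid()] (eager, with a `dataset`
#'   column)
#' @param methods method names to run
#' @param ... passed to [run_pipeline()]
#' @return tibble with one row per (method, sigma_sig, sigma_pop, rep):
#'   `pr_auc` plus the manifest columns; summarize with [evaluate_grid()].
#' @export
run_benchmark <- function(manifest,
                          methods = c("lasso", "sgl", "lasso-lmm", "sgl-lmm"),
                          ...) {
  stopifnot("dataset" %in% names(manifest))
  out <- list()
  for (mth in methods) {
    rows <- manifest
    rows$method <- mth
    rows$pr_auc <- purrr::map_dbl(manifest$dataset, function(ds) {
      run <- run_pipeline(ds$genotypes, ds$phenotype, ds$groups,
                          method = mth, seed = ds$config$seed, ...)
      labels <- ds$causal_mask[match(run$stability$table$snp_id,
                                     ds$genotypes$snp_ids)]
      pr_auc(run$stability$table$frequency, labels)
    })
    rows$dataset <- NULL
    out[[mth]] <- rows
  }
  dplyr::bind_rows(out)
}
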