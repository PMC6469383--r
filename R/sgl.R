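#' Define a sparse group lasso problem on rotated data
#'
#' Bundles the whitened design and response with the grouping, the L1/L2
#' mixing weight alpha, and per-group weights. The objective minimized by
#' [fit_sgl()] is
#'
#'   (1/(2n)) ||y_tilde - X_tilde b||^2
#'   + lambda (1-alpha) sum_G w_G ||b_G||_2 + lambda alpha ||b||_1
#'
#' with w_G = sqrt(p_G) by default (`unweighted = TRUE` sets w_G = 1, and
#' `scale_loss = FALSE` drops the 1/(2n) so the printed formula is runnable
#' verbatim; both only rescale the meaning of lambda).
#'
#' @param rot a `rotated_data` object (or any list with `y_tilde`,
#'   `X_tilde`)
#' @param groups a [group_structure] over the columns of `X_tilde`
#' @param alpha L1 share of the penalty, in `[0, 1]`; 1 = lasso, 0 = group
#'   lasso
#' @param unweighted use w_G = 1 instead of sqrt(group size)
#' @param scale_loss divide the squared error by 2n (default) rather than 1
#' @return An object of class `sgl_problem`.
#' @export
sgl_problem <- function(rot, groups, alpha = 0.95, unweighted = FALSE,
                        scale_loss = TRUE) {
  X <- as.matrix(rot$X_tilde)
  y <- as.numeric(rot$y_tilde)
  stopifnot(nrow(X) == length(y), alpha >= 0, alpha <= 1)
  if (length(groups$membership) != ncol(X))
    stop("group structure covers ", length(groups$membership),
         " SNPs but the design has ", ncol(X), " columns")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("design and response must be finite")
  w <- if (unweighted) rep(1, length(groups$groups)) else sqrt(as.numeric(groups$sizes))
  if (any(w <= 0)) stop("group weights must be positive")
  structure(list(X = X, y = y, groups = groups, grp = group_index(groups),
                 alpha = alpha, w = w, scale_loss = scale_loss,
                 n = nrow(X), p = ncol(X)),
            class = "sgl_problem")
}

# internal: effective lambda passed to the 1/(2n)-scaled C++ core.
# With scale_loss = FALSE the user-facing objective is the verbatim
# ||y - Xb||^2 + lambda * penalty = 2n * [RSS/(2n) + (lambda/(2n)) * penalty].
.lam_internal <- function(problem, lambda) {
  if (problem$scale_loss) lambda else lambda / (2 * problem$n)
}

.obj_external <- function(problem, value) {
  if (problem$scale_loss) value else value * 2 * problem$n
}

#' Sparse group lasso objective value
#' @param problem an [sgl_problem]
#' @param beta coefficient vector, length `problem$p`
#' @param lambda penalty strength
#' @return scalar objective.
#' @export
sgl_objective <- function(problem, beta, lambda) {
  v <- sgl_objective_cpp(problem$X, problem$y, problem$grp, problem$w,
                         problem$alpha, .lam_internal(problem, lambda),
                         as.numeric(beta))
  .obj_external(problem, v)
}

#' Maximum violation of the optimality (KKT) conditions
#'
#' Zero groups must satisfy `||soft(grad_G, alpha lambda)||_2 <=
#' (1-alpha) w_G lambda`; nonzero coordinates must zero the subgradient.
#' Returns the largest violation (0 at an exact solution).
#'
#' @inheritParams sgl_objective
#' @return scalar residual, >= 0.
#' @export
kkt_residual <- function(problem, beta, lambda) {
  sgl_kkt_cpp(problem$X, problem$y, problem$grp, problem$w,
              problem$alpha, .lam_internal(problem, lambda),
              as.numeric(beta))
}

#' Smallest penalty that keeps every coefficient at zero
#'
#' From stationarity of the objective at beta = 0: for each group the
#' condition `||soft(X_G^T y / n, alpha lambda)||_2 <= (1-alpha) w_G lambda`
#' has a unique crossing in lambda, found by bisection (1e-10 relative);
#' lambda_max is the maximum over groups. At `alpha = 1` this reduces to the
#' lasso closed form `max_j |x_j^T y| / n`.
#'
#' @param problem an [sgl_problem]
#' @return positive scalar (0 when `y_tilde` is identically zero).
#' @export
lambda_max <- function(problem) {
  y <- problem$y
  if (all(y == 0)) return(0)
  n_eff <- problem$n
  alpha <- problem$alpha
  lam_g <- vapply(seq_along(problem$groups$groups), function(g) {
    c_g <- drop(crossprod(problem$X[, problem$grp == g, drop = FALSE], y)) / n_eff
    w_g <- problem$w[g]
    if (alpha == 1) return(max(abs(c_g)))
    if (alpha == 0) return(sqrt(sum(c_g^2)) / w_g)
    crit <- function(lam) {
      s <- pmax(abs(c_g) - alpha * lam, 0)
      sqrt(sum(s^2)) - (1 - alpha) * w_g * lam
    }
    hi <- max(abs(c_g)) / alpha   # soft threshold kills c_g entirely here
    lo <- 0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (crit(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-10 * hi) break
    }
    hi  # upper end: zero condition guaranteed to hold
  }, numeric(1))
  lam <- max(lam_g)
  if (problem$scale_loss) lam else lam * 2 * problem$n
}

#' Fit the sparse group lasso at one penalty value
#'
#' Blockwise (group-cyclic) descent: each group is set to zero when its
#' screening condition holds, otherwise its subproblem is minimized by
#' proximal gradient with the exact sparse-group prox. Terminates when the
#' largest coefficient change in a full sweep falls below
#' `tol * max(1, ||beta||_inf)` and the KKT residual is below `kkt_tol`.
#'
#' @param problem an [sgl_problem]
#' @param lambda penalty strength (>= 0)
#' @param beta_init warm-start coefficients (default all zero)
#' @param tol convergence tolerance on coefficient change
#' @param max_iter maximum number of full sweeps
#' @param kkt_tol maximum acceptable KKT residual at convergence
#' @return An object of class `sgl_fit`: `beta` (named), `lambda`,
#'   `objective`, `n_iter`, `kkt_residual`, `converged`.
#' @export
fit_sgl <- function(problem, lambda, beta_init = NULL, tol = 1e-6,
                    max_iter = 10000, kkt_tol = 1e-4) {
  if (lambda < 0) stop("lambda must be >= 0")
  beta0 <- if (is.null(beta_init)) rep(0, problem$p) else as.numeric(beta_init)
  res <- sgl_path_cpp(problem$X, problem$y, problem$grp, problem$w,
                      problem$alpha, .lam_internal(problem, lambda),
                      beta0, tol, max_iter, kkt_tol)
  if (!res$converged[1])
    warning(sprintf("fit_sgl did not converge at lambda = %.4g (kkt = %.3g)",
                    lambda, res$kkt_residual[1]))
  structure(list(beta = stats::setNames(drop(res$beta), colnames(problem$X)),
                 lambda = lambda,
                 objective = .obj_external(problem, res$objective[1]),
                 n_iter = res$n_iter[1],
                 kkt_residual = res$kkt_residual[1],
                 converged = as.logical(res$converged[1]),
                 alpha = problem$alpha),
            class = "sgl_fit")
}

#' @export
print.sgl_fit <- function(x, ...) {
  cat(sprintf("<sgl_fit> lambda = %.4g, %d nonzero of %d, kkt = %.2g\n",
              x$lambda, sum(x$beta != 0), length(x$beta), x$kkt_residual))
  invisible(x)
}

#' Fit a geometric lambda path with warm starts
#'
#' `nlam` penalties geometrically spaced from [lambda_max()] down to
#' `lambda_min_ratio * lambda_max`; each fit is warm-started from the
#' previous one, so the first fit is exactly zero and sparsity decays along
#' the path.
#'
#' @inheritParams fit_sgl
#' @param nlam number of path points (default 100)
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#' @param lambdas optional explicit decreasing lambda sequence overriding
#'   the geometric default
#' @return An object of class `lambda_path`: `lambdas`, `beta` (p x nlam
#'   matrix), per-lambda `objective`, `n_iter`, `kkt_residual`,
#'   `converged`, `nonzero`.
#' @export
fit_path <- function(problem, nlam = 100, lambda_min_ratio = 0.01,
                     lambdas = NULL, tol = 1e-6, max_iter = 10000,
                     kkt_tol = 1e-4) {
  if (is.null(lambdas)) {
    if (nlam < 2) stop("nlam must be >= 2")
    lmax <- lambda_max(problem)
    if (lmax <= 0) stop("lambda_max is zero (null response); no path to fit")
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlam))
  } else {
    if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  }
  res <- sgl_path_cpp(problem$X, problem$y, problem$grp, problem$w,
                      problem$alpha,
                      vapply(lambdas, .lam_internal, numeric(1), problem = problem),
                      rep(0, problem$p), tol, max_iter, kkt_tol)
  if (!all(res$converged == 1)) {
    bad <- which(res$converged == 0)
    warning("path fits not converged at lambda index(es): ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  beta <- res$beta
  rownames(beta) <- colnames(problem$X)
  structure(list(lambdas = lambdas,
                 beta = beta,
                 objective = .obj_external(problem, res$objective),
                 n_iter = res$n_iter,
                 kkt_residual = res$kkt_residual,
                 converged = as.logical(res$converged),
                 nonzero = colSums(beta != 0),
                 alpha = problem$alpha),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("<lambda_path> %d lambdas in [%.4g, %.4g], nonzero %d-%d\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              min(x$nonzero), max(x$nonzero)))
  invisible(x)
}

#' Write a fitted path as tidy TSV (lambda, snp_id, beta; nonzero rows only)
#' @param path_fit a `lambda_path`
#' @param file output TSV path
#' @export
write_path <- function(path_fit, file) {
  tab <- tidy(path_fit)
  utils::write.table(as.data.frame(tab), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
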