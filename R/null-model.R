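#' Negative profile log-likelihood of the variance ratio delta
#'
#' Under the null (no fixed effects) the phenotype is multivariate normal
#' with covariance sigma_g^2 (K + delta I). Profiling out sigma_g^2 leaves a
#' one-dimensional objective in delta:
#'
#'   f(delta) = sum_i log(S_i + delta)
#'            + m * log( (1/m) * sum_i (U^T y)_i^2 / (S_i + delta) )
#'
#' which is -2x the profile log-likelihood up to an additive constant that
#' does not depend on delta (the constant is dropped throughout, so
#' log-likelihood values are comparable only within one dataset).
#'
#' @param delta positive variance ratio sigma_e^2 / sigma_g^2
#' @param S kinship eigenvalues (descending, >= 0)
#' @param Uty rotated phenotype U^T y
#' @return scalar objective value (smaller is better).
#' @export
profile_negloglik <- function(delta, S, Uty) {
  if (delta <= 0) stop("delta must be positive")
  if (all(Uty == 0)) stop("phenotype is identically zero; likelihood degenerate")
  d <- S + delta
  if (any(d <= 0)) stop("S + delta must be positive")
  m <- length(Uty)
  sum(log(d)) + m * log(sum(Uty^2 / d) / m)
}

#' Profiled genetic variance at a given delta
#'
#' sigma_g^2(delta) = (1/m) sum_i (U^T y)_i^2 / (S_i + delta).
#'
#' @inheritParams profile_negloglik
#' @return positive scalar.
#' @export
estimate_sigma_g2 <- function(delta, S, Uty) {
  if (delta <= 0) stop("delta must be positive")
  mean(Uty^2 / (S + delta))
}

#' Estimate the null-model variance ratio delta
#'
#' Maximum-likelihood estimate of delta = sigma_e^2/sigma_g^2 with all fixed
#' effects at zero: [profile_negloglik()] is evaluated on a log-spaced grid
#' of ln delta in [-10, 10] and refined by bounded scalar minimization
#' within the bracketing grid cell. The phenotype is mean-centered first;
#' the removed mean is stored for restoration at prediction. When the
#' profile is flat across the whole grid (range < `flat_tol`, e.g. K = I so
#' only sigma_g^2(1 + delta) is identified), delta is set to 1 by convention
#' and flagged.
#'
#' @param ke a `kinship_eigen` object
#' @param y numeric phenotype vector, or a tibble with a `value` column
#' @param grid_size number of grid points over ln delta in [-10, 10]
#' @param flat_tol objective range below which the profile is declared flat
#' @return An object of class `null_model`: `delta`, `sigma_g2`, `loglik`
#'   (-f/2, constant dropped), `flat_likelihood`, `y_mean`, `m`.
#' @export
estimate_delta <- function(ke, y, grid_size = 100, flat_tol = 1e-6) {
  if (is.data.frame(y)) y <- y$value
  y <- as.numeric(y)
  m <- length(y)
  stopifnot(m == length(ke$S))
  if (m < 10) warning("fewer than 10 samples; delta estimate will be unstable")
  y_mean <- mean(y)
  yc <- y - y_mean
  if (all(yc == 0)) stop("phenotype has zero variance")
  Uty <- drop(crossprod(ke$U, yc))
  lgrid <- seq(-10, 10, length.out = grid_size)
  fvals <- vapply(exp(lgrid), profile_negloglik, numeric(1), S = ke$S, Uty = Uty)
  if (any(!is.finite(fvals)))
    stop("non-finite profile objective at delta = ",
         signif(exp(lgrid[which(!is.finite(fvals))[1]]), 4))
  flat <- (max(fvals) - min(fvals)) < flat_tol
  if (flat) {
    delta <- 1
    fopt <- profile_negloglik(delta, ke$S, Uty)
  } else {
    i <- which.min(fvals)
    lo <- lgrid[max(1, i - 1)]; hi <- lgrid[min(grid_size, i + 1)]
    opt <- stats::optimize(function(l) profile_negloglik(exp(l), ke$S, Uty),
                           lower = lo, upper = hi, tol = 1e-10)
    # refinement must not be worse than the grid optimum
    if (opt$objective <= fvals[i]) {
      delta <- exp(opt$minimum); fopt <- opt$objective
    } else {
      delta <- exp(lgrid[i]); fopt <- fvals[i]
    }
  }
  structure(list(delta = delta,
                 sigma_g2 = estimate_sigma_g2(delta, ke$S, Uty),
                 loglik = -fopt / 2,
                 flat_likelihood = flat,
                 y_mean = y_mean,
                 m = m),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> delta = %.4g, sigma_g2 = %.4g%s\n",
              x$delta, x$sigma_g2,
              if (x$flat_likelihood) " (flat profile; delta = 1 by convention)" else ""))
  invisible(x)
}

#' Rotate phenotype and genotypes into the whitened basis
#'
#' Multiplies y and X by S_delta U^T with (S_delta)_ii = (S_i + delta)^(-1/2),
#' so that ||y_tilde - X_tilde beta||^2 = (y - X beta)^T (K + delta I)^{-1}
#' (y - X beta) for every beta: generalized least squares in the original
#' basis becomes ordinary least squares in the rotated one. The phenotype is
#' centered with the null model's stored mean before rotation.
#'
#' @param ke `kinship_eigen`
#' @param nm `null_model` fitted on the same samples in the same order
#' @param y phenotype vector or tibble with `value`
#' @param X numeric matrix of dosages/covariates (m rows)
#' @return A list of class `rotated_data`: `y_tilde`, `X_tilde`,
#'   `delta_used`, `y_mean`.
#' @export
rotate_data <- function(ke, nm, y, X) {
  if (is.data.frame(y)) y <- y$value
  y <- as.numeric(y)
  X <- as.matrix(X)
  m <- length(ke$S)
  if (length(y) != m || nrow(X) != m)
    stop("dimension mismatch between kinship (", m, "), phenotype (",
         length(y), ") and genotypes (", nrow(X), ")")
  w <- 1 / sqrt(ke$S + nm$delta)
  yc <- y - nm$y_mean
  y_tilde <- w * drop(crossprod(ke$U, yc))
  X_tilde <- w * crossprod(ke$U, X)
  colnames(X_tilde) <- colnames(X)
  structure(list(y_tilde = y_tilde, X_tilde = X_tilde,
                 delta_used = nm$delta, y_mean = nm$y_mean),
            class = "rotated_data")
}

#' Identity rotation (no mixed-model correction)
#'
#' Used by the lasso/SGL baselines without population correction: U = I and
#' unit scaling, so the "rotated" data are the centered originals.
#'
#' @param y phenotype vector or tibble with `value`
#' @param X numeric matrix
#' @return A `rotated_data` object with `delta_used = NA`.
#' @export
identity_rotation <- function(y, X) {
  if (is.data.frame(y)) y <- y$value
  y <- as.numeric(y)
  X <- as.matrix(X)
  y_mean <- mean(y)
  structure(list(y_tilde = y - y_mean, X_tilde = X,
                 delta_used = NA_real_, y_mean = y_mean),
            class = "rotated_data")
}

#' Serialize / restore a null model as a key-value text file
#' @param nm `null_model`
#' @param path text file path
#' @export
write_null_model <- function(nm, path) {
  lines <- c(sprintf("delta\t%.17g", nm$delta),
             sprintf("sigma_g2\t%.17g", nm$sigma_g2),
             sprintf("loglik\t%.17g", nm$loglik),
             sprintf("flat_likelihood\t%d", as.integer(nm$flat_likelihood)),
             sprintf("y_mean\t%.17g", nm$y_mean),
             sprintf("m\t%d", nm$m))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  kv <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  val <- stats::setNames(kv[[2]], kv[[1]])
  structure(list(delta = as.numeric(val["delta"]),
                 sigma_g2 = as.numeric(val["sigma_g2"]),
                 loglik = as.numeric(val["loglik"]),
                 flat_likelihood = as.logical(as.integer(val["flat_likelihood"])),
                 y_mean = as.numeric(val["y_mean"]),
                 m = as.integer(val["m"])),
            class = "null_model")
}
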