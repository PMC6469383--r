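test_that("objective evaluates term-by-term", {
  prob <- make_problem(n = 20, p = 6, n_groups = 2, alpha = 0.7, seed = 41)
  # beta = 0: penalty vanishes
  expect_equal(sgl_objective(prob, rep(0, 6), lambda = 3),
               sum(prob$y^2) / (2 * prob$n))
  set.seed(42)
  b <- rnorm(6); lam <- 0.4
  manual <- sum((prob$y - prob$X %*% b)^2) / (2 * prob$n) +
    lam * (1 - 0.7) * (sqrt(3) * sqrt(sum(b[prob$grp == 1]^2)) +
                       sqrt(3) * sqrt(sum(b[prob$grp == 2]^2))) +
    lam * 0.7 * sum(abs(b))
  expect_equal(sgl_objective(prob, b, lam), manual, tolerance = 1e-12)
  # alpha = 1: pure lasso penalty
  prob1 <- make_problem(n = 20, p = 6, alpha = 1, seed = 41)
  expect_equal(sgl_objective(prob1, b, lam),
               sum((prob1$y - prob1$X %*% b)^2) / (2 * prob1$n) +
                 lam * sum(abs(b)),
               tolerance = 1e-12)
})

test_that("lambda_max has the lasso closed form and brackets the zero solution", {
  prob1 <- make_problem(n = 30, p = 5, alpha = 1, seed = 43)
  expect_equal(lambda_max(prob1),
               max(abs(crossprod(prob1$X, prob1$y))) / prob1$n,
               tolerance = 1e-9)
  # null response
  prob0 <- prob1; prob0$y <- rep(0, 30)
  expect_equal(lambda_max(prob0), 0)
  # mixed alpha: fit just above is zero, 5% below is nonzero
  prob <- make_problem(n = 30, p = 4, n_groups = 2, alpha = 0.6, seed = 44)
  lmax <- lambda_max(prob)
  expect_equal(sum(fit_sgl(prob, 1.001 * lmax)$beta != 0), 0)
  expect_gt(sum(fit_sgl(prob, 0.95 * lmax)$beta != 0), 0)
  # group lasso limit
  prob_g <- make_problem(n = 30, p = 4, n_groups = 2, alpha = 0, seed = 44)
  lmax_g <- lambda_max(prob_g)
  norms <- sapply(1:2, function(g)
    sqrt(sum((crossprod(prob_g$X[, prob_g$grp == g], prob_g$y) / 30)^2)) /
      sqrt(sum(prob_g$grp == g)))
  expect_equal(lmax_g, max(norms), tolerance = 1e-9)
})

test_that("orthonormal-design lasso solutions are exact soft thresholds", {
  set.seed(45)
  n <- 32; p <- 6
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # X'X = n I
  y <- rnorm(n)
  gs <- group_structure(rep(c("a", "b"), each = 3))
  prob <- sgl_problem(identity_rotation(y, X), gs, alpha = 1)
  lam <- 0.3 * lambda_max(prob)
  fit <- fit_sgl(prob, lam)
  z <- drop(crossprod(X, prob$y)) / n
  closed <- sign(z) * pmax(abs(z) - lam, 0)
  expect_equal(unname(fit$beta), closed, tolerance = 1e-8)
  expect_lt(kkt_residual(prob, closed, lam), 1e-10)
  # perturbing an active coordinate breaks optimality
  pert <- closed; pert[which.max(abs(closed))] <- pert[which.max(abs(closed))] + 0.1
  expect_gt(kkt_residual(prob, pert, lam), 0)
})

test_that("solver matches the independent full-gradient FISTA oracle", {
  for (seed in 1:8) {
    alpha <- c(0.95, 0.5, 0.2)[(seed %% 3) + 1]
    prob <- make_problem(n = 30, p = 6, n_groups = 2, alpha = alpha,
                         seed = seed)
    lam <- 0.1 * lambda_max(prob)
    fit <- fit_sgl(prob, lam, tol = 1e-9)
    b_or <- oracle_sgl_fista(prob$X, prob$y, prob$grp, prob$w, alpha, lam)
    o_fit <- sgl_objective(prob, fit$beta, lam)
    o_or <- oracle_sgl_objective(prob$X, prob$y, prob$grp, prob$w, alpha,
                                 lam, b_or)
    expect_equal(o_fit, o_or, tolerance = 1e-5)
    expect_lt(fit$kkt_residual, 1e-4)
    expect_equal(unname(fit$beta), b_or, tolerance = 1e-4)
  }
})

test_that("alpha = 1 coefficients match glmnet coordinate descent", {
  skip_if_not_installed("glmnet")
  for (seed in c(51, 52, 53)) {
    prob <- make_problem(n = 40, p = 8, n_groups = 3, alpha = 1, seed = seed)
    lam <- 0.15 * lambda_max(prob)
    fit <- fit_sgl(prob, lam, tol = 1e-10)
    gfit <- glmnet::glmnet(prob$X, prob$y, lambda = lam, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(fit$beta), as.numeric(gfit$beta), tolerance = 1e-6)
  }
})

test_that("alpha = 0 solutions match a pure group-lasso oracle", {
  prob <- make_problem(n = 30, p = 6, n_groups = 2, alpha = 0, seed = 54)
  lam <- 0.2 * lambda_max(prob)
  fit <- fit_sgl(prob, lam, tol = 1e-9)
  b_or <- oracle_sgl_fista(prob$X, prob$y, prob$grp, prob$w, 0, lam)
  expect_equal(unname(fit$beta), b_or, tolerance = 1e-5)
})

test_that("solutions are invariant to group and column permutations", {
  prob <- make_problem(n = 30, p = 8, n_groups = 2, alpha = 0.8, seed = 55)
  lam <- 0.1 * lambda_max(prob)
  fit <- fit_sgl(prob, lam, tol = 1e-10)
  perm <- c(5:8, 1:4)  # swap the two groups wholesale
  gs_p <- group_structure(prob$groups$membership[perm])
  prob_p <- sgl_problem(list(y_tilde = prob$y, X_tilde = prob$X[, perm]),
                        gs_p, alpha = 0.8)
  fit_p <- fit_sgl(prob_p, lam, tol = 1e-10)
  expect_equal(unname(fit_p$beta), unname(fit$beta[perm]), tolerance = 1e-7)
})

test_that("warm-started paths agree with cold starts and nest correctly", {
  prob <- make_problem(n = 40, p = 10, n_groups = 3, alpha = 0.9, seed = 56)
  path <- fit_path(prob, nlam = 12, lambda_min_ratio = 0.05)
  expect_equal(path$nonzero[1], 0)         # first fit all-zero
  expect_gte(path$nonzero[12], path$nonzero[1])
  expect_true(all(diff(path$lambdas) < 0))
  for (l in c(4, 8, 12)) {
    cold <- fit_sgl(prob, path$lambdas[l], tol = 1e-8)
    expect_equal(path$objective[l], cold$objective, tolerance = 1e-5)
  }
  # nested-lambda optimality: beta(l2) is at least as good at l2 as beta(l1)
  o12 <- sgl_objective(prob, path$beta[, 12], path$lambdas[12])
  o4_at12 <- sgl_objective(prob, path$beta[, 4], path$lambdas[12])
  expect_lte(o12, o4_at12 + 1e-10)
})

test_that("converged fits keep small KKT residuals across random instances", {
  worst <- 0
  for (seed in 1:20) {
    prob <- make_problem(n = 25, p = 8, n_groups = 3,
                         alpha = runif(1), seed = 100 + seed)
    lam <- runif(1, 0.05, 0.6) * lambda_max(prob)
    fit <- fit_sgl(prob, lam)
    worst <- max(worst, fit$kkt_residual)
  }
  expect_lt(worst, 1e-4)
})

test_that("unweighted and unscaled conventions change only lambda's meaning", {
  prob_w <- make_problem(n = 30, p = 6, n_groups = 2, alpha = 0.5, seed = 57)
  rot <- list(y_tilde = prob_w$y, X_tilde = prob_w$X)
  gs <- prob_w$groups
  prob_u <- sgl_problem(rot, gs, alpha = 0.5, unweighted = TRUE)
  expect_equal(prob_u$w, c(1, 1))
  prob_v <- sgl_problem(rot, gs, alpha = 0.5, scale_loss = FALSE)
  lam <- 0.1 * lambda_max(prob_w)
  b <- fit_sgl(prob_w, lam, tol = 1e-10)$beta
  # verbatim objective at lambda_v = 2n*lambda equals 2n * scaled objective
  n2 <- 2 * prob_v$n
  expect_equal(sgl_objective(prob_v, b, n2 * lam),
               n2 * sgl_objective(prob_w, b, lam), tolerance = 1e-8)
  expect_equal(lambda_max(prob_v), n2 * lambda_max(prob_w), tolerance = 1e-8)
  # and the minimizers coincide
  b_v <- fit_sgl(prob_v, n2 * lam, tol = 1e-10)$beta
  expect_equal(unname(b_v), unname(b), tolerance = 1e-6)
})
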