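# Independent oracles used across tests. These deliberately share no code
# with the package's solver: full-gradient FISTA with the exact sparse-group
# prox (vs the package's blockwise descent), dense-matrix likelihood
# evaluations, and brute-force metric enumeration.

# exact prox of t * [la1 ||b||_1 + sum_g la2_g ||b_g||_2]
oracle_sgl_prox <- function(z, t, la1, la2g, grp) {
  out <- numeric(length(z))
  for (g in unique(grp)) {
    id <- which(grp == g)
    u <- sign(z[id]) * pmax(abs(z[id]) - t * la1, 0)
    nu <- sqrt(sum(u^2))
    out[id] <- if (nu <= t * la2g[g]) 0 else u * (1 - t * la2g[g] / nu)
  }
  out
}

# high-precision full-vector FISTA for
#   (1/2n)||y - Xb||^2 + lambda alpha ||b||_1 + lambda(1-alpha) sum w_g ||b_g||_2
oracle_sgl_fista <- function(X, y, grp, w, alpha, lambda,
                             max_iter = 200000, tol = 1e-13) {
  n <- nrow(X); p <- ncol(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE, only.values = TRUE)$values)
  la1 <- lambda * alpha
  la2g <- lambda * (1 - alpha) * w
  b <- z <- numeric(p); tk <- 1
  for (i in seq_len(max_iter)) {
    gr <- drop(crossprod(X, X %*% z - y)) / n
    bn <- oracle_sgl_prox(z - gr / L, 1 / L, la1, la2g, grp)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + (tk - 1) / tn * (bn - b)
    done <- max(abs(bn - b)) < tol * max(1, max(abs(bn)))
    b <- bn; tk <- tn
    if (done && i > 10) break
  }
  b
}

oracle_sgl_objective <- function(X, y, grp, w, alpha, lambda, b) {
  pen2 <- sum(sapply(unique(grp), function(g)
    w[g] * sqrt(sum(b[grp == g]^2))))
  sum((y - X %*% b)^2) / (2 * nrow(X)) +
    lambda * (1 - alpha) * pen2 + lambda * alpha * sum(abs(b))
}

# tiny random regression problem with grouping
make_problem <- function(n = 30, p = 6, n_groups = 2, alpha = 0.95,
                         seed = 1, snr = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * rbinom(p, 1, 0.6)
  y <- drop(X %*% beta) + rnorm(n) * sd(X %*% beta) / snr
  gs <- group_structure(rep_len(paste0("g", seq_len(n_groups)), p))
  rot <- identity_rotation(y, X)
  sgl_problem(rot, gs, alpha = alpha)
}

# small genotype panel with known dosages
make_panel <- function(dos, ...) {
  genotype_data(as.matrix(dos), ...)
}

# random dosage panel
random_panel <- function(m = 20, p = 10, maf = 0.3, miss = 0, seed = 1) {
  set.seed(seed)
  dos <- matrix(rbinom(m * p, 2, maf), m, p)
  if (miss > 0) dos[matrix(runif(m * p) < miss, m, p)] <- NA
  genotype_data(dos)
}

# shared small simulated dataset for selection/pipeline tests
small_sim <- function(seed = 7, sigma_sig = 0.5, sigma_pop = 0.5) {
  cfg <- sim_config(n_samples = 200, n_groups = 25, snps_per_group = 8,
                    m_active = 2, causal_per_active = 3,
                    sigma_sig = sigma_sig, sigma_pop = sigma_pop, seed = seed)
  simulate_dataset(cfg)
}
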