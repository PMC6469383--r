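#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the semi-empirical design this
#' generator emulates: 1130 samples, 200 gene groups of 10 SNPs (p = 2000),
#' 3 active groups with 5 causal SNPs each (k = 15), signal weight
#' `sigma_sig` and confounder weight `sigma_pop` mixing a genetic signal, a
#' kinship-driven population effect, and iid noise. Population structure is
#' generated by a two-population Balding-Nichols model (Fst 0.1) and
#' within-gene linkage disequilibrium by an AR(1) latent Gaussian with
#' correlation `ld_rho`.
#'
#' @param n_samples number of samples (default 1130)
#' @param n_groups number of gene groups (default 200)
#' @param snps_per_group SNPs per group (default 10)
#' @param m_active number of groups carrying causal SNPs (default 3)
#' @param causal_per_active causal SNPs per active group (default 5)
#' @param sigma_sig signal mixing weight in `[0, 1]`
#' @param sigma_pop confounder mixing weight in `[0, 1]`
#' @param n_populations number of discrete subpopulations (default 2)
#' @param fst Wright's fixation index controlling between-population
#'   differentiation, in `[0, 1)`
#' @param ld_rho AR(1) correlation of the latent Gaussian within a group
#' @param seed master integer seed
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 1130, n_groups = 200, snps_per_group = 10,
                       m_active = 3, causal_per_active = 5,
                       sigma_sig = 0.5, sigma_pop = 0.5,
                       n_populations = 2, fst = 0.1, ld_rho = 0.5,
                       seed = 1) {
  cfg <- list(n_samples = n_samples, n_groups = n_groups,
              snps_per_group = snps_per_group, m_active = m_active,
              causal_per_active = causal_per_active,
              sigma_sig = sigma_sig, sigma_pop = sigma_pop,
              n_populations = n_populations, fst = fst, ld_rho = ld_rho,
              seed = as.integer(seed))
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must lie in [0, 1)")
  if (cfg$sigma_sig < 0 || cfg$sigma_sig > 1 ||
      cfg$sigma_pop < 0 || cfg$sigma_pop > 1)
    stop("sigma_sig and sigma_pop must lie in [0, 1]")
  if (cfg$m_active > cfg$n_groups) stop("m_active cannot exceed n_groups")
  if (cfg$causal_per_active > cfg$snps_per_group)
    stop("causal_per_active cannot exceed snps_per_group")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate structured genotypes with within-gene LD
#'
#' Balding-Nichols population structure: each SNP draws an ancestral
#' frequency from Uniform(0.1, 0.9) and per-population frequencies from a
#' Beta distribution with that mean and variance `fst * p(1-p)`; samples are
#' split evenly over populations. Within each contiguous group of
#' `snps_per_group` SNPs, each of a sample's two allele copies is generated
#' by thresholding a latent AR(1) Gaussian (correlation `ld_rho`) at the
#' population frequency quantile, giving Binomial(2, p) marginals with
#' realistic within-gene LD.
#'
#' @param cfg a [sim_config]
#' @return list with `genotypes` ([genotype_data]), `groups`
#'   ([group_structure]), `population` (per-sample integer).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed(cfg$seed, {
    n <- cfg$n_samples
    G <- cfg$n_groups; s <- cfg$snps_per_group
    p <- G * s
    npop <- cfg$n_populations
    pop <- rep_len(seq_len(npop), n)
    p_anc <- stats::runif(p, 0.1, 0.9)
    if (cfg$fst > 0) {
      a <- p_anc * (1 - cfg$fst) / cfg$fst
      b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
      p_pop <- matrix(stats::rbeta(npop * p, rep(a, each = npop),
                                   rep(b, each = npop)),
                      nrow = npop)
    } else {
      p_pop <- matrix(rep(p_anc, each = npop), nrow = npop)
    }
    p_pop <- pmin(pmax(p_pop, 1e-4), 1 - 1e-4)
    # AR(1) Cholesky factor shared by all groups
    R <- cfg$ld_rho^abs(outer(seq_len(s), seq_len(s), "-"))
    Rchol <- chol(R)
    dos <- matrix(0, nrow = n, ncol = p)
    for (g in seq_len(G)) {
      cols <- (g - 1) * s + seq_len(s)
      thr <- stats::qnorm(t(p_pop[, cols, drop = FALSE]))  # s x npop
      for (copy in 1:2) {
        E <- matrix(stats::rnorm(n * s), n, s) %*% Rchol
        dos[, cols] <- dos[, cols] + (E < t(thr)[pop, , drop = FALSE])
      }
    }
    snp_ids <- sprintf("snp%04d", seq_len(p))
    gd <- genotype_data(dos, sample_ids = sprintf("ind%04d", seq_len(n)),
                        snp_ids = snp_ids, chrom = "1",
                        pos = seq_len(p) * 100L)
    gs <- group_structure(rep(sprintf("gene%03d", seq_len(G)), each = s),
                          snp_ids = snp_ids)
    attr(gd, "allele_freq") <- p_pop  # per-population truth, kept for audit
    list(genotypes = gd, groups = gs, population = pop)
  })
}

#' Draw a kinship-distributed population confounder
#'
#' y_pop = U diag(sqrt(S)) z with z standard normal, i.e. a draw from
#' N(0, K), then scaled to unit sample variance so the phenotype mixer's
#' weights act on a common scale.
#'
#' @param ke a `kinship_eigen` from the simulated genotypes
#' @param seed integer seed
#' @param standardize scale to unit sample variance (default TRUE)
#' @return numeric vector of length m.
#' @export
simulate_population_effect <- function(ke, seed, standardize = TRUE) {
  withr_seed(seed, {
    z <- stats::rnorm(length(ke$S))
    y_pop <- drop(ke$U %*% (sqrt(ke$S) * z))
    if (standardize && stats::sd(y_pop) > 0) y_pop <- y_pop / stats::sd(y_pop)
    y_pop
  })
}

standardize_component <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Assemble a simulated phenotype from signal, confounder and noise
#'
#' Chooses `m_active` groups uniformly without replacement and
#' `causal_per_active` SNPs within each; causal effects are standard normal
#' and the genetic signal is `y_sig = X_k beta` over the causal dosages.
#' Signal, confounder and iid noise are each standardized to mean 0, unit
#' variance (unless `raw_components`) and mixed as
#'
#'   y = sigma_sig * y_sig + (1 - sigma_sig) * (sigma_pop * y_pop +
#'       (1 - sigma_pop) * phi)
#'
#' @param cfg a [sim_config]
#' @param genotypes [genotype_data] from [simulate_genotypes()]
#' @param groups matching [group_structure]
#' @param y_pop confounder from [simulate_population_effect()]
#' @param seed integer seed for causal placement, effects and noise
#' @param raw_components skip component standardization (mix the raw draws)
#' @return An object of class `simulated_dataset`: `genotypes`, `groups`,
#'   `phenotype` (tibble sample_id/value), `causal_mask`, `causal_snps`,
#'   `active_groups`, `true_beta`, `components` (tibble y_sig/y_pop/phi),
#'   `config`.
#' @export
simulate_phenotype <- function(cfg, genotypes, groups, y_pop, seed,
                               raw_components = FALSE) {
  p <- length(genotypes$snp_ids)
  withr_seed(seed, {
    active <- sort(sample(groups$groups, cfg$m_active))
    causal_idx <- integer(0)
    for (g in active) {
      members <- which(groups$membership == g)
      if (length(members) < cfg$causal_per_active)
        stop("active group ", g, " has fewer than ", cfg$causal_per_active,
             " SNPs")
      causal_idx <- c(causal_idx, sort(sample(members, cfg$causal_per_active)))
    }
    beta <- stats::rnorm(length(causal_idx))
    y_sig <- unname(drop(genotypes$dosages[, causal_idx, drop = FALSE] %*% beta))
    phi <- stats::rnorm(cfg$n_samples)
    if (!raw_components) {
      y_sig <- standardize_component(y_sig)
      y_pop <- standardize_component(y_pop)
      phi <- standardize_component(phi)
    }
    y <- cfg$sigma_sig * y_sig +
      (1 - cfg$sigma_sig) * (cfg$sigma_pop * y_pop + (1 - cfg$sigma_pop) * phi)
    mask <- rep(FALSE, p); mask[causal_idx] <- TRUE
    true_beta <- numeric(p); true_beta[causal_idx] <- beta
    structure(list(genotypes = genotypes,
                   groups = groups,
                   phenotype = tibble::tibble(sample_id = genotypes$sample_ids,
                                              value = y),
                   causal_mask = mask,
                   causal_snps = genotypes$snp_ids[causal_idx],
                   active_groups = active,
                   true_beta = true_beta,
                   components = tibble::tibble(y_sig = y_sig, y_pop = y_pop,
                                               phi = phi),
                   config = cfg),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d samples, %d SNPs, %d causal in %d groups (sigma_sig = %.2f, sigma_pop = %.2f)\n",
              length(x$phenotype$value), length(x$causal_mask),
              sum(x$causal_mask), length(x$active_groups),
              x$config$sigma_sig, x$config$sigma_pop))
  invisible(x)
}

#' Simulate one full dataset (genotypes, kinship confounder, phenotype)
#'
#' Convenience wrapper running [simulate_genotypes()], [kinship()],
#' [simulate_population_effect()] and [simulate_phenotype()] with seeds
#' derived from `cfg$seed`. The kinship eigendecomposition is attached as
#' `attr(, "kinship")` so pipelines need not recompute it.
#'
#' @param cfg a [sim_config]
#' @param raw_components see [simulate_phenotype()]
#' @return a `simulated_dataset`.
#' @export
simulate_dataset <- function(cfg, raw_components = FALSE) {
  geno <- simulate_genotypes(cfg)
  ke <- kinship(geno$genotypes)
  y_pop <- simulate_population_effect(ke, seed = cfg$seed + 1000003L)
  ds <- simulate_phenotype(cfg, geno$genotypes, geno$groups, y_pop,
                           seed = cfg$seed + 2000003L,
                           raw_components = raw_components)
  attr(ds, "kinship") <- ke
  attr(ds, "population") <- geno$population
  ds
}

# stable 31-bit seed from grid coordinates
derive_seed <- function(master, sigma_sig, sigma_pop, rep) {
  h <- (as.double(master) * 2654435.0 +
        round(1000 * sigma_sig) * 97003.0 +
        round(1000 * sigma_pop) * 89.0 +
        rep * 7.0)
  as.integer(h %% 2147483629)
}

#' Simulate a grid of datasets over mixing weights
#'
#' One dataset per (sigma_sig, sigma_pop, rep) cell with a deterministic
#' per-cell seed derived from the master seed, so manifests reproduce
#' exactly. `combos` restricts the full factorial to a subset of
#' (sigma_sig, sigma_pop) pairs.
#'
#' @param cfg_base a [sim_config] supplying everything but the mixing
#'   weights
#' @param sigmas_sig,sigmas_pop mixing-weight levels
#' @param reps datasets per cell (default 10)
#' @param combos optional two-column data frame of (sigma_sig, sigma_pop)
#'   pairs to keep
#' @param lazy if `TRUE`, return only the manifest with per-cell configs
#'   (datasets generated on demand via [simulate_dataset()])
#' @return tibble manifest with columns sigma_sig, sigma_pop, rep, seed and
#'   (unless lazy) a `dataset` list-column.
#' @export
simulate_grid <- function(cfg_base, sigmas_sig = c(0.1, 0.2, 0.3, 0.4, 0.5),
                          sigmas_pop = c(0.5, 0.7, 0.9), reps = 10,
                          combos = NULL, lazy = FALSE) {
  if (!length(sigmas_sig) || !length(sigmas_pop)) stop("empty sigma lists")
  grid <- expand.grid(sigma_sig = sigmas_sig, sigma_pop = sigmas_pop,
                      rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  if (!is.null(combos)) {
    keep <- interaction(grid$sigma_sig, grid$sigma_pop) %in%
      interaction(combos[[1]], combos[[2]])
    grid <- grid[keep, , drop = FALSE]
  }
  grid <- grid[order(grid$sigma_sig, grid$sigma_pop, grid$rep), , drop = FALSE]
  man <- tibble::as_tibble(grid)
  man$seed <- mapply(derive_seed, master = cfg_base$seed,
                     sigma_sig = man$sigma_sig, sigma_pop = man$sigma_pop,
                     rep = man$rep)
  if (!lazy) {
    man$dataset <- purrr::pmap(man, function(sigma_sig, sigma_pop, rep, seed) {
      cfg <- cfg_base
      cfg$sigma_sig <- sigma_sig; cfg$sigma_pop <- sigma_pop
      cfg$seed <- seed
      simulate_dataset(cfg)
    })
  }
  man
}

#' Write a simulated dataset's files (genotypes, phenotype, groups, truth)
#' @param ds a `simulated_dataset`
#' @param dir output directory (created if needed)
#' @param format genotype format, `"tsv"` or `"plink"`
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(ds, dir, format = "tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(ds$genotypes, file.path(dir, if (format == "tsv") "genotypes.tsv" else "genotypes"),
                  format = format)
  write_phenotype(ds$phenotype, file.path(dir, "phenotype.tsv"))
  write_groups(ds$groups, file.path(dir, "groups.tsv"))
  utils::write.table(
    data.frame(snp_id = ds$genotypes$snp_ids, causal = as.integer(ds$causal_mask),
               true_beta = ds$true_beta),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ds$components), file.path(dir, "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- ds$config
  writeLines(paste(names(cfg), unlist(cfg), sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}
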