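test_that("no-structure, no-LD genotypes have matched population frequencies", {
  cfg <- sim_config(n_samples = 1130, n_groups = 500, snps_per_group = 10,
                    fst = 0, ld_rho = 0, seed = 91)
  sim <- simulate_genotypes(cfg)
  pop <- sim$population
  f1 <- colMeans(sim$genotypes$dosages[pop == 1, ]) / 2
  f2 <- colMeans(sim$genotypes$dosages[pop == 2, ]) / 2
  expect_lt(mean(abs(f1 - f2)), 0.02)
})

test_that("genotype means match the binomial moment per SNP", {
  cfg <- sim_config(n_samples = 1130, n_groups = 50, snps_per_group = 10,
                    seed = 92)
  sim <- simulate_genotypes(cfg)
  pop <- sim$population
  freq <- attr(sim$genotypes, "allele_freq")
  w <- as.numeric(table(pop)) / length(pop)
  expected <- 2 * drop(w %*% freq)
  observed <- colMeans(sim$genotypes$dosages)
  # MC standard error of a mean of 1130 dosages is about sqrt(0.5/1130)
  expect_lt(mean(abs(observed - expected)), 4 * sqrt(0.5 / 1130))
  expect_lt(max(abs(observed - expected)), 8 * sqrt(0.5 / 1130))
})

test_that("genotype simulation is deterministic and group-consistent", {
  cfg <- sim_config(n_samples = 60, n_groups = 8, snps_per_group = 5,
                    seed = 93)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_equal(length(s1$groups$groups), 8)
  expect_true(all(s1$groups$sizes == 5))
  expect_error(sim_config(fst = 1), "fst")
})

test_that("within-group LD is present and between-group LD is absent", {
  cfg <- sim_config(n_samples = 800, n_groups = 40, snps_per_group = 10,
                    fst = 0, ld_rho = 0.5, seed = 94)
  sim <- simulate_genotypes(cfg)
  cc <- cor(sim$genotypes$dosages[, 1:20])
  within <- cc[cbind(1:9, 2:10)]          # adjacent pairs, group 1
  across <- cc[cbind(1:10, 11:20)]        # pairs straddling two groups
  expect_gt(mean(within), 0.2)
  expect_lt(mean(abs(across)), 0.1)
})

test_that("population effect draws follow N(0, K)", {
  g <- random_panel(m = 15, p = 60, seed = 95)
  ke <- kinship(g)
  draws <- sapply(1:2000, function(i)
    simulate_population_effect(ke, seed = 10000 + i, standardize = FALSE))
  emp <- tcrossprod(draws) / 2000
  mc_se <- sqrt((outer(diag(ke$K), diag(ke$K)) + ke$K^2) / 2000)
  expect_true(all(abs(emp - ke$K) <= 3 * mc_se + 0.05))
  # identity kinship: standardized draws are unit-variance iid normals
  ke_i <- eigendecompose(diag(50))
  yp <- simulate_population_effect(ke_i, seed = 96)
  expect_equal(stats::sd(yp), 1, tolerance = 1e-12)
  expect_identical(yp, simulate_population_effect(ke_i, seed = 96))
})

test_that("phenotypes place the right number of causal SNPs in active groups", {
  ds <- simulate_dataset(sim_config(n_samples = 120, n_groups = 20,
                                    snps_per_group = 10, seed = 97))
  expect_equal(sum(ds$causal_mask), 15)
  expect_length(ds$active_groups, 3)
  causal_groups <- unique(ds$groups$membership[ds$causal_mask])
  expect_setequal(causal_groups, ds$active_groups)
  expect_true(all(table(ds$groups$membership[ds$causal_mask]) == 5))
  expect_equal(which(ds$true_beta != 0), which(ds$causal_mask))
})

test_that("mixing-weight boundaries reproduce single components", {
  cfg1 <- sim_config(n_samples = 80, n_groups = 10, snps_per_group = 6,
                     m_active = 2, causal_per_active = 3,
                     sigma_sig = 1, seed = 98)
  ds1 <- simulate_dataset(cfg1)
  expect_equal(ds1$phenotype$value, ds1$components$y_sig)
  cfg0 <- cfg1; cfg0$sigma_sig <- 0; cfg0$sigma_pop <- 0
  ds0 <- simulate_dataset(cfg0)
  expect_equal(ds0$phenotype$value, ds0$components$phi)
  expect_equal(mean(ds0$components$phi), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ds0$components$phi), 1, tolerance = 1e-12)
})

test_that("phenotype variance follows the mixing-weight bookkeeping", {
  tot <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_samples = 500, n_groups = 30, snps_per_group = 10,
                      sigma_sig = 0.4, sigma_pop = 0.7, seed = 200 + s)
    ds <- simulate_dataset(cfg)
    tot <- tot + stats::var(ds$phenotype$value)
  }
  expected <- 0.4^2 + 0.6^2 * (0.7^2 + 0.3^2)
  # components are standardized but not mutually orthogonal; allow MC slack
  expect_equal(tot / 5, expected, tolerance = 0.15)
})

test_that("grid manifests are deterministic and support the reduced design", {
  cfg <- sim_config(n_samples = 50, n_groups = 6, snps_per_group = 5, seed = 99)
  man <- simulate_grid(cfg, reps = 10, lazy = TRUE)
  expect_equal(nrow(man), 150)
  combos <- expand.grid(sigma_sig = c(0.1, 0.2, 0.3, 0.4),
                        sigma_pop = c(0.5, 0.7, 0.9))
  man12 <- simulate_grid(cfg, reps = 10, combos = combos, lazy = TRUE)
  expect_equal(nrow(man12), 120)
  man2 <- simulate_grid(cfg, reps = 10, lazy = TRUE)
  expect_identical(man, man2)
  expect_equal(anyDuplicated(man$seed), 0)
  # eager generation carries matching phenotypes
  sm <- simulate_grid(cfg, sigmas_sig = 0.5, sigmas_pop = 0.5, reps = 2)
  expect_length(sm$dataset, 2)
  expect_identical(sm$dataset[[1]]$config$seed, sm$seed[1])
  sm2 <- simulate_grid(cfg, sigmas_sig = 0.5, sigmas_pop = 0.5, reps = 2)
  expect_equal(sm$dataset[[1]]$phenotype, sm2$dataset[[1]]$phenotype)
})

test_that("simulated datasets round-trip through their file bundle", {
  ds <- simulate_dataset(sim_config(n_samples = 30, n_groups = 4,
                                    snps_per_group = 5, m_active = 2,
                                    causal_per_active = 2, seed = 100))
  dir <- withr::local_tempdir()
  write_simulated_dataset(ds, dir)
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(g2$dosages, ds$genotypes$dosages)
  ph2 <- read_phenotype(file.path(dir, "phenotype.tsv"), g2)
  expect_equal(ph2$value, unname(ds$phenotype$value))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE)
  expect_equal(as.logical(truth$causal), ds$causal_mask)
})
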