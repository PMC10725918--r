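test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fis = 1.2), "fis")
  expect_error(sim_config(n_loci = 0), "positive")
  expect_error(sim_config(clone_error_alleles = 21, n_loci = 10),
               "clone_error_alleles")
})

test_that("frequencies sit on the allele ladder and respect the fst limit", {
  cfg <- sim_config(n_pops = 3, n_loci = 2, alleles_per_locus = 5,
                    base_length = 100, motif_step = 2, fst = 0,
                    n_cultivars = 0, seed = 1)
  set.seed(1)
  fr <- simulate_frequencies(cfg)
  expect_setequal(unique(fr$allele[fr$locus == "L01"]),
                  c(100, 102, 104, 106, 108))
  # fst = 0: every population equals the ancestral frequencies
  anc <- fr$freq[fr$group == "ancestral"]
  for (p in c("P1", "P2", "P3")) {
    expect_equal(fr$freq[fr$group == p], anc)
  }
})

test_that("Balding-Nichols draws match the model's variance", {
  # fst = 0.2, 2 alleles: Var(p_pop) = fst * p * (1 - p)
  cfg <- sim_config(n_pops = 1, n_loci = 1, alleles_per_locus = 2,
                    fst = 0.2, n_cultivars = 0, seed = 1)
  set.seed(99)
  p_anc <- 0.6
  draws <- replicate(10000, {
    x <- rgamma(2, shape = c(p_anc, 1 - p_anc) * (1 - 0.2) / 0.2)
    x[1] / sum(x)
  })
  expect_lt(abs(mean(draws) - p_anc), 0.01)
  expect_lt(abs(var(draws) / (0.2 * p_anc * (1 - p_anc)) - 1), 0.05)
  # and the generator's own draws reproduce that second moment
  set.seed(7)
  reps <- replicate(10000, {
    fr <- simulate_frequencies(cfg)
    fr$freq[fr$group == "P1"][1]
  })
  anc_mean <- 0.5  # Dirichlet(1,1) ancestral mean
  expect_lt(abs(mean(reps) - anc_mean), 0.02)
})

test_that("genotype draws honour the inbreeding coefficient", {
  base <- list(n_pops = 1, n_per_pop = 1000, n_loci = 1,
               alleles_per_locus = 2, n_cultivars = 0, clone_pairs = 0,
               scoring_error_rate = 0, missing_rate = 0, fst = 0)
  # fis = 1: all homozygous
  cfg1 <- do.call(sim_config, c(base, list(fis = 1, seed = 2)))
  set.seed(2)
  ds1 <- simulate_genotypes(simulate_frequencies(cfg1), cfg1)
  expect_true(all(ds1$a1 == ds1$a2))
  # fis = 0, p = (0.5, 0.5): Ho ~ Binomial(1000, 0.5)
  cfg0 <- do.call(sim_config, c(base, list(fis = 0, seed = 3)))
  fr <- simulate_frequencies(cfg0)
  fr$freq[fr$group == "P1"] <- c(0.5, 0.5)
  set.seed(3)
  ds0 <- simulate_genotypes(fr, cfg0)
  ho <- mean(ds0$a1[, 1] != ds0$a2[, 1])
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(ho - 0.5), 3 * se)
})

test_that("missingness is applied at the configured rate", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 100, n_loci = 10,
                    n_cultivars = 0, clone_pairs = 0,
                    scoring_error_rate = 0, missing_rate = 0.1, seed = 4)
  ds <- simulate_ssr_dataset(cfg)
  n_cells <- length(ds$a1)
  se <- sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(mean(is.na(ds$a1)) - 0.1), 3 * se)
})

test_that("injected clones stay within the configured distance", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 20, clone_pairs = 6,
                    clone_error_alleles = 2, scoring_error_rate = 0,
                    missing_rate = 0, seed = 5)
  ds <- simulate_ssr_dataset(cfg)
  truth <- attr(ds, "clone_truth")
  expect_equal(nrow(truth), 6)
  dm <- pairwise_distance(ds)
  for (r in seq_len(nrow(truth))) {
    expect_lte(dm$d[truth$source[r], truth$clone[r]], 2)
  }
  # with zero perturbations the copy is identical
  cfg0 <- sim_config(n_pops = 1, n_per_pop = 10, clone_pairs = 2,
                     clone_error_alleles = 0, scoring_error_rate = 0,
                     missing_rate = 0, n_cultivars = 0, seed = 6)
  ds0 <- simulate_ssr_dataset(cfg0)
  t0 <- attr(ds0, "clone_truth")
  dm0 <- pairwise_distance(ds0)
  expect_true(all(dm0$d[cbind(t0$source, t0$clone)] == 0))
})

test_that("scoring error perturbs alleles on-ladder at the right rate", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 50, n_loci = 10,
                    clone_pairs = 0, n_cultivars = 0, missing_rate = 0,
                    scoring_error_rate = 0.0085, seed = 8)
  set.seed(8)
  fr <- simulate_frequencies(cfg)
  clean <- simulate_genotypes(fr, cfg)
  noisy <- apply_scoring_error(clean, cfg)
  # rate = 0 leaves data unchanged
  cfg0 <- sim_config(scoring_error_rate = 0)
  expect_equal(apply_scoring_error(clean, cfg0)$a1, clean$a1)
  # perturbed alleles remain on each locus ladder
  lad <- attr(fr, "ladder")
  for (loc in noisy$loci) {
    expect_true(all(noisy$a1[, loc] %in% lad[[loc]]))
    expect_true(all(noisy$a2[, loc] %in% lad[[loc]]))
  }
  # perturbation count is binomial around the configured rate
  n_alleles <- 2 * length(clean$a1)
  hits <- sum(attr(noisy, "perturbation_counts"))
  expect_lt(abs(hits / n_alleles - 0.0085),
            3 * sqrt(0.0085 * (1 - 0.0085) / n_alleles))
})

test_that("the full generator is reproducible from its seed", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 10, n_loci = 3, seed = 123)
  ds1 <- simulate_ssr_dataset(cfg)
  ds2 <- simulate_ssr_dataset(cfg)
  expect_identical(ds1$a1, ds2$a1)
  expect_identical(ds1$a2, ds2$a2)
  expect_identical(attr(ds1, "clone_truth"), attr(ds2, "clone_truth"))
})
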