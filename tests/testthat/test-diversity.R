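test_that("locus summaries match closed forms", {
  # 10 individuals, 5 heterozygous, p = (0.5, 0.5)
  geno <- c(lapply(1:5, function(i) list(L1 = c(100L, 102L))),
            lapply(1:3, function(i) list(L1 = c(100L, 100L))),
            lapply(1:2, function(i) list(L1 = c(102L, 102L))))
  names(geno) <- sprintf("i%02d", 1:10)
  # 5 het + 3 AA + 2 BB: p_100 = (10+6)/20 ... adjust to exact halves
  geno[["i09"]] <- list(L1 = c(100L, 102L))
  geno[["i10"]] <- list(L1 = c(102L, 102L))
  ds <- make_ds(geno)
  tab <- locus_summary(ds, "pooled")
  p <- allele_frequencies(ds)$freq
  expect_equal(tab$na, 2)
  expect_equal(tab$ne, 1 / sum(p^2))
  expect_equal(tab$ho, 0.6)
  expect_equal(tab$uhe, (20 / 19) * (1 - sum(p^2)))
  # monomorphic locus
  dsm <- make_ds(list(a = list(L1 = c(100L, 100L)),
                      b = list(L1 = c(100L, 100L))))
  tm <- locus_summary(dsm, "pooled")
  expect_equal(c(tm$ne, tm$ho, tm$uhe), c(1, 0, 0))
})

test_that("allelic richness matches exhaustive subsample enumeration", {
  # spot value: counts {2,2}, g = 2 -> 2 * (1 - 1/6) = 5/3
  ds <- make_ds(list(a = list(L1 = c(100L, 100L)),
                     b = list(L1 = c(102L, 102L))))
  ar <- allelic_richness(ds, "pooled", g = 2)
  expect_equal(ar$ar, 5 / 3)
  expect_equal(ar$ar, oracle_ar(c(2, 2), 2))
  # oracle sweep over random count vectors, N <= 8 copies, g <= 4
  set.seed(71)
  for (r in 1:20) {
    n_alleles <- sample(2:4, 1)
    counts <- as.numeric(rmultinom(1, sample(4:8, 1), rep(1, n_alleles)))
    counts <- counts[counts > 0]
    for (g in 2:min(4, sum(counts))) {
      expect_equal(ssrpopgen:::.ar_closed_form(counts, g),
                   oracle_ar(counts, g), tolerance = 1e-12)
    }
  }
})

test_that("allelic richness equals Na at full sample size and is
           monotone in g", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 12, clone_pairs = 0,
                    n_cultivars = 0, missing_rate = 0, seed = 72)
  ds <- simulate_ssr_dataset(cfg)
  tab <- locus_summary(ds, "population")
  full <- allelic_richness(ds, "population", g = 24)
  merged <- merge(tab, full, by = c("group", "locus"))
  expect_equal(merged$ar, as.numeric(merged$na))
  g_seq <- seq(2, 24, by = 2)
  ar_by_g <- sapply(g_seq, function(g) {
    a <- allelic_richness(ds, "population", g = g)
    mean(a$ar)
  })
  expect_true(all(diff(ar_by_g) > 0))
})

test_that("closed-form rarefaction agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(73)
  counts <- as.numeric(rmultinom(1, 60, c(0.4, 0.3, 0.2, 0.07, 0.03)))
  counts <- counts[counts > 0]
  for (g in c(2, 10, 25)) {
    expect_equal(ssrpopgen:::.ar_closed_form(counts, g),
                 suppressWarnings(
                   unname(c(vegan::rarefy(matrix(counts, 1), g)))),
                 tolerance = 1e-10)
  }
})

test_that("private alleles are alleles seen in exactly one group", {
  ds <- make_ds(list(
    a1 = list(L1 = c(100L, 102L)), a2 = list(L1 = c(100L, 104L)),
    b1 = list(L1 = c(100L, 102L)), b2 = list(L1 = c(100L, 102L))),
    pop = c("PA", "PA", "PB", "PB"))
  pa <- private_alleles(ds, "population")
  expect_equal(pa$counts, c(PA = 1L, PB = 0L))
  expect_equal(pa$alleles$allele, 104L)
  # all alleles shared -> zero everywhere
  ds2 <- make_ds(list(a = list(L1 = c(100L, 102L)),
                      b = list(L1 = c(100L, 102L))), pop = c("PA", "PB"))
  expect_equal(sum(private_alleles(ds2, "population")$counts), 0L)
  expect_error(private_alleles(ds, "pooled"), "two groups")
})

test_that("FIS estimation recovers simulated inbreeding and is invariant
           to allele relabeling", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 40, fis = 0.15,
                    clone_pairs = 0, scoring_error_rate = 0,
                    missing_rate = 0, n_cultivars = 0, seed = 74)
  ds <- simulate_ssr_dataset(cfg)
  est <- fis_estimate(ds, "population", n_boot = 300, seed = 1)
  expect_true(all(abs(est$fis - 0.15) < 0.08))
  expect_true(all(est$ci_lo <= est$fis & est$fis <= est$ci_hi))
  # relabeling alleles (shift all lengths) leaves FIS unchanged
  ds2 <- ds
  ds2$a1 <- ds$a1 + 60L
  ds2$a2 <- ds$a2 + 60L
  est2 <- fis_estimate(ds2, "population", n_boot = 300, seed = 1)
  expect_equal(est$fis, est2$fis)
  # Ho = Hs at every locus -> FIS = 0 with CI spanning 0 is the
  # theoretical target; a balanced heterozygote/homozygote toy gives 0
  expect_error(fis_estimate(ds, n_boot = 10), "n_boot")
})

test_that("HWE permutation test is calibrated and detects inbreeding", {
  # monomorphic locus -> p = 1 with flag
  dsm <- make_ds(lapply(setNames(1:6, paste0("i", 1:6)),
                        function(i) list(L1 = c(100L, 100L))))
  r <- hwe_test(dsm, "L1", "P1", n_perm = 99)
  expect_true(r$monomorphic)
  expect_equal(r$p_value, 1)
  # power: fis = 0.3 at n = 50 rejects in most simulations
  cfg <- sim_config(n_pops = 1, n_per_pop = 50, n_loci = 12, fis = 0.3,
                    clone_pairs = 0, n_cultivars = 0,
                    scoring_error_rate = 0, missing_rate = 0, seed = 75)
  ds <- simulate_ssr_dataset(cfg)
  pv <- vapply(ds$loci, function(loc) {
    hwe_test(ds, loc, "P1", n_perm = 199, seed = 7)$p_value
  }, numeric(1))
  expect_gte(mean(pv < 0.05), 0.8)
})

test_that("the allele accumulation curve is concave, non-decreasing and
           ends at the observed allele count", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 15, n_loci = 5,
                    clone_pairs = 0, n_cultivars = 20,
                    cultivar_fst = 0.3, missing_rate = 0, seed = 76)
  ds <- simulate_ssr_dataset(cfg)
  curve <- allele_rarefaction_curve(ds, "gene_pool")
  for (gp in unique(curve$group)) {
    v <- curve$expected_alleles[curve$group == gp]
    expect_true(all(diff(v) > -1e-9))
    expect_true(all(diff(diff(v)) < 1e-9))  # concave
    tab <- locus_summary(subset(ds, gene_pools = gp), "pooled")
    expect_equal(v[length(v)], sum(tab$na))
  }
  # bottlenecked cultivar pool accumulates fewer alleles at equal n
  wild <- curve[curve$group == "wild", ]
  cult <- curve[curve$group == "cultivar", ]
  n_common <- min(max(wild$n_ind), max(cult$n_ind))
  expect_gt(wild$expected_alleles[wild$n_ind == n_common],
            cult$expected_alleles[cult$n_ind == n_common])
})
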