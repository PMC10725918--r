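test_that("GENEPOP files decode 3-digit allele pairs and missing codes", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c(
    "toy panel", "LocA",
    "Pop", "a1 , 100102", "a2 , 102102",
    "Pop", "b1 , 000000", "b2 , 104100"
  ), path)
  ds <- read_genepop(path)
  expect_equal(n_ind(ds), 4)
  expect_equal(ds$loci, "LocA")
  expect_equal(unname(ds$a1["a1", ]), 100L)
  expect_equal(unname(ds$a2["a1", ]), 102L)
  expect_true(is.na(ds$a1["b1", ]))
  # unphased: stored in canonical ascending order
  expect_equal(unname(c(ds$a1["b2", ], ds$a2["b2", ])), c(100L, 104L))
  # populations follow file order, named by last member
  expect_equal(unique(ds$pop), c("a2", "b2"))
})

test_that("malformed GENEPOP input is rejected with location info", {
  p1 <- withr::local_tempfile()
  writeLines(c("t", "L1", "Pop", "x , 100102 104104"), p1)
  expect_error(read_genepop(p1), "format error")
  p2 <- withr::local_tempfile()
  writeLines(c("t", "L1", "Pop", "x , 10012"), p2)
  expect_error(read_genepop(p2), "4.*or 6|uniformly")
  p3 <- withr::local_tempfile()
  writeLines(c("t", "L1", "Pop", "x , 100102", "x , 100102"), p3)
  expect_error(read_genepop(p3), "duplicate")
  p4 <- withr::local_tempfile()
  writeLines(c("t", "L1", "Pop", "x , 000102"), p4)
  expect_error(read_genepop(p4), "half-missing")
})

test_that("round trips through both formats are the identity", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 8, n_loci = 5,
                    n_cultivars = 4, missing_rate = 0.05, seed = 11)
  ds <- simulate_ssr_dataset(cfg)
  gp <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, gp)
  back <- read_genepop(gp)
  expect_equal(back$loci, ds$loci)
  expect_setequal(back$ind, ds$ind)
  # GENEPOP writes Pop blocks, which may reorder individuals; genotypes
  # must be identical per individual
  expect_equal(back$a1[ds$ind, ], ds$a1)
  expect_equal(back$a2[ds$ind, ], ds$a2)
  wide <- withr::local_tempfile(fileext = ".csv")
  write_wide_table(ds, wide)
  back2 <- read_wide_table(wide)
  expect_equal(back2$a1, ds$a1)
  expect_equal(back2$a2, ds$a2)
  expect_equal(back2$pop, ds$pop)
  expect_equal(back2$gene_pool, ds$gene_pool)
})

test_that("GENEPOP writer handles alleles beyond 3 digits via offsets", {
  ds <- make_ds(list(x = list(L1 = c(1250L, 1266L)),
                     y = list(L1 = c(1250L, 1250L))))
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, path)
  back <- read_genepop(path)
  expect_equal(back$a1, ds$a1)
  expect_equal(back$a2, ds$a2)
})

test_that("wide tables flag unpaired columns and bad tokens", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,population,L1_1", "x,P,100"), p)
  expect_error(read_wide_table(p), "unpaired")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,population,L1_1,L1_2", "x,P,10a,102"), p2)
  expect_error(read_wide_table(p2), "non-integer.*L1_1")
})

test_that("subset restricts margins, preserves order and refuses unknowns", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 5, n_loci = 11,
                    n_cultivars = 0, clone_pairs = 0, seed = 3)
  ds <- simulate_ssr_dataset(cfg)
  dropped <- subset(ds, loci = ds$loci[-4])
  expect_equal(n_loci(dropped), 10)
  expect_equal(dropped$loci, ds$loci[-4])
  sub_all <- subset(ds, individuals = ds$ind)
  expect_equal(sub_all[c("ind", "pop", "gene_pool", "loci", "a1", "a2")],
               ds[c("ind", "pop", "gene_pool", "loci", "a1", "a2")])
  expect_error(subset(ds, loci = character(0)), "no loci")
  expect_error(subset(ds, populations = "Atlantis"), "unknown.*valid")
})

test_that("allele frequencies count gene copies and normalise per group", {
  ds <- make_ds(list(i1 = list(L1 = c(100L, 100L)),
                     i2 = list(L1 = c(100L, 102L)),
                     i3 = list(L1 = NA)))
  ft <- allele_frequencies(ds)
  expect_equal(ft$freq, c(0.75, 0.25))
  expect_equal(attr(ft, "n_copies")$n_copies, 4L)
  # fully missing locus absent, not NaN
  ds2 <- make_ds(list(i1 = list(L1 = c(100L, 100L), L2 = NA),
                      i2 = list(L1 = c(102L, 102L), L2 = NA)))
  ft2 <- allele_frequencies(ds2)
  expect_false("L2" %in% ft2$locus)
})

test_that("subset-then-frequencies equals filtering the computation", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 10, n_loci = 4,
                    n_cultivars = 0, clone_pairs = 0,
                    missing_rate = 0.05, seed = 5)
  ds <- simulate_ssr_dataset(cfg)
  sub <- subset(ds, populations = c("P1", "P3"))
  f_sub <- allele_frequencies(sub, "population")
  f_all <- allele_frequencies(ds, "population")
  f_fil <- f_all[f_all$group %in% c("P1", "P3"), ]
  rownames(f_fil) <- NULL
  attr(f_sub, "n_copies") <- NULL
  attr(f_fil, "n_copies") <- NULL
  class(f_fil) <- class(f_sub)
  f_fil$group <- as.character(f_fil$group)
  expect_equal(f_sub, f_fil)
})

test_that("sample frequencies converge to generating frequencies", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 1000, n_loci = 3,
                    alleles_per_locus = 4,
                    n_cultivars = 0, clone_pairs = 0, fst = 0, fis = 0,
                    scoring_error_rate = 0, missing_rate = 0, seed = 17)
  set.seed(cfg$seed)
  freqs <- simulate_frequencies(cfg)
  ds <- simulate_genotypes(freqs, cfg)
  ft <- allele_frequencies(ds)
  for (loc in ds$loci) {
    gen <- freqs[freqs$locus == loc & freqs$group == "P1", ]
    obs <- setNames(rep(0, nrow(gen)), gen$allele)
    est <- ft[ft$locus == loc, ]
    obs[as.character(est$allele)] <- est$freq
    expect_lt(sum(abs(obs - gen$freq)), 0.05)  # L1 error at 2000 copies
  }
})
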