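test_that("pairwise distance counts allele differences with pairwise
           deletion of missing loci", {
  ds <- make_ds(list(
    i1 = list(L1 = c(100L, 102L), L2 = c(200L, 200L)),
    i2 = list(L1 = c(100L, 104L), L2 = c(200L, 200L)),
    i3 = list(L1 = c(100L, 102L), L2 = NA),
    i4 = list(L1 = c(106L, 108L), L2 = c(202L, 204L))))
  dm <- pairwise_distance(ds)
  expect_equal(dm$d["i1", "i2"], 1L)            # one allele differs
  expect_equal(dm$d["i1", "i3"], 0L)            # missing locus excluded
  expect_equal(dm$comparable["i1", "i3"], 1L)
  expect_equal(dm$d["i1", "i4"], 4L)            # fully disjoint
  expect_equal(diag(dm$d), setNames(rep(0L, 4), ds$ind))
  expect_true(isSymmetric(unname(dm$d)))
})

test_that("a pair with no comparable locus is undefined, not zero", {
  ds <- make_ds(list(i1 = list(L1 = c(100L, 102L), L2 = NA),
                     i2 = list(L1 = NA, L2 = c(200L, 200L))))
  dm <- pairwise_distance(ds)
  expect_true(is.na(dm$d["i1", "i2"]))
  h <- distance_histogram(dm)
  expect_equal(sum(h$count), 0L)
})

test_that("distances obey the triangle inequality on complete data", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 15, missing_rate = 0,
                    clone_pairs = 3, seed = 41)
  ds <- simulate_ssr_dataset(cfg)
  d <- pairwise_distance(ds)$d
  n <- nrow(d)
  idx <- t(combn(n, 3))
  viol <- apply(idx, 1, function(tr) {
    a <- d[tr[1], tr[2]]; b <- d[tr[2], tr[3]]; cc <- d[tr[1], tr[3]]
    cc > a + b || a > cc + b || b > a + cc
  })
  expect_false(any(viol))
})

test_that("the histogram conserves pair counts and shows injected clones", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 25, clone_pairs = 8,
                    clone_error_alleles = 2, seed = 42)
  ds <- simulate_ssr_dataset(cfg)
  dm <- pairwise_distance(ds)
  h <- distance_histogram(dm)
  n <- n_ind(ds)
  expect_equal(sum(h$count), n * (n - 1) / 2)
  low <- sum(h$count[h$distance <= 2])
  expect_gte(low, 8)                    # the clone clump
  gap <- h$count[h$distance %in% 4:7]
  expect_true(any(gap == 0))            # separated from the main mass
})

test_that("threshold suggestion reads the initial peak off the histogram", {
  # clump at 1-3, gap, main mass at 10+ -> threshold 3
  h <- data.frame(distance = c(0:4, 10:14),
                  count = c(0, 5, 8, 4, 0, 50, 80, 90, 60, 20))
  expect_equal(suggest_threshold(h), 3L)
  # monotone rise into the main mode: no clump, threshold 0
  h2 <- data.frame(distance = 0:5, count = c(0, 0, 1, 5, 20, 40))
  expect_warning(thr <- suggest_threshold(h2), "returning 0")
  expect_equal(thr, 0L)
  # synthetic clones at <= 2 recovered with the suggested threshold
  cfg <- sim_config(n_pops = 4, n_per_pop = 25, clone_pairs = 8,
                    clone_error_alleles = 2, seed = 43)
  ds <- simulate_ssr_dataset(cfg)
  dm <- pairwise_distance(ds)
  thr <- suggest_threshold(distance_histogram(dm))
  expect_gte(thr, 2L)
  mlgs <- contract_mlgs(ds, thr, dm)
  truth <- attr(ds, "clone_truth")
  same <- mlgs$mlg[match(truth$source, mlgs$ind)] ==
    mlgs$mlg[match(truth$clone, mlgs$ind)]
  expect_true(all(same))
})

test_that("contraction is single linkage with sensible representatives", {
  # chain A-B:2, B-C:3 merges into one MLG at threshold 3
  ds <- make_ds(list(
    A = list(L1 = c(100L, 100L), L2 = c(200L, 202L), L3 = c(300L, 300L)),
    B = list(L1 = c(100L, 102L), L2 = c(200L, 204L), L3 = c(300L, 300L)),
    C = list(L1 = c(102L, 104L), L2 = c(200L, 206L), L3 = c(300L, 302L)),
    D = list(L1 = c(150L, 152L), L2 = c(250L, 252L), L3 = c(350L, 352L))))
  dm <- pairwise_distance(ds)
  expect_equal(dm$d["A", "B"], 2L)
  expect_equal(dm$d["B", "C"], 3L)
  m <- contract_mlgs(ds, 3, dm)
  expect_equal(m$mlg[match("A", m$ind)], m$mlg[match("C", m$ind)])
  expect_equal(length(unique(m$mlg)), 2)
  # threshold 0 separates everything distinct
  m0 <- contract_mlgs(ds, 0, dm)
  expect_equal(length(unique(m0$mlg)), 4)
  # representative: fewest missing cells, ties broken lexicographically
  ds2 <- make_ds(list(
    b = list(L1 = c(100L, 100L), L2 = c(200L, 200L)),
    a = list(L1 = c(100L, 100L), L2 = c(200L, 200L)),
    c = list(L1 = c(100L, 100L), L2 = NA)))
  m2 <- contract_mlgs(ds2, 0)
  expect_equal(m2$ind[m2$representative], "a")
})

test_that("threshold-0 grouping equals exact-genotype hashing on
           complete data", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 20, clone_pairs = 6,
                    clone_error_alleles = 0, scoring_error_rate = 0,
                    missing_rate = 0, seed = 44)
  ds <- simulate_ssr_dataset(cfg)
  m0 <- contract_mlgs(ds, 0)
  key <- apply(cbind(ds$a1, ds$a2), 1, paste, collapse = "/")
  expect_equal(length(unique(m0$mlg)), length(unique(key)))
  # same partition, not just same size
  expect_true(all(tapply(key, m0$mlg, function(k) length(unique(k))) == 1))
})

test_that("MLG count is monotone non-increasing in the threshold", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 20, clone_pairs = 5, seed = 45)
  ds <- simulate_ssr_dataset(cfg)
  dm <- pairwise_distance(ds)
  counts <- vapply(0:6, function(t) {
    length(unique(contract_mlgs(ds, t, dm)$mlg))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("synonymy report distinguishes exact synonyms from contracted
           groups", {
  ds <- make_ds(list(
    s1 = list(L1 = c(100L, 100L), L2 = c(200L, 202L)),
    s2 = list(L1 = c(100L, 100L), L2 = c(200L, 202L)),  # synonym of s1
    c1 = list(L1 = c(110L, 112L), L2 = c(210L, 210L)),
    c2 = list(L1 = c(110L, 114L), L2 = c(210L, 210L)),  # distance 1
    u1 = list(L1 = c(150L, 152L), L2 = c(250L, 252L))),
    gene_pool = c("cultivar", "cultivar", "wild", "wild", "wild"))
  m <- contract_mlgs(ds, 1)
  rep <- synonymy_report(m, ds)
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$type, c("synonym", "contracted"))
  expect_equal(rep$max_distance[rep$type == "synonym"], 0L)
  expect_match(rep$gene_pools[rep$type == "synonym"], "cultivar;cultivar")
  # no multi-member MLGs -> empty report
  m0 <- contract_mlgs(subset(ds, individuals = c("s1", "c1", "u1")), 0)
  expect_equal(nrow(synonymy_report(
    m0, subset(ds, individuals = c("s1", "c1", "u1")))), 0)
})
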