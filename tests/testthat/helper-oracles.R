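# Independent brute-force oracles, deliberately implemented by
# enumeration rather than through the package's closed forms.

# P(two unrelated HWE individuals share a genotype): sum over genotypes
# of P(g)^2.
oracle_pid <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      tot <- tot + pg^2
    }
  }
  tot
}

# P(two full sibs share a genotype): enumerate ordered parental allele
# quadruples (i,j) x (k,l); each sib draws one allele per parent
# uniformly; match probability is sum over genotypes of the conditional
# sib-genotype probability squared.
oracle_pidsibs <- function(p) {
  k <- length(p)
  idx <- as.matrix(expand.grid(i = 1:k, j = 1:k, m = 1:k, l = 1:k))
  w <- p[idx[, 1]] * p[idx[, 2]] * p[idx[, 3]] * p[idx[, 4]]
  # the four equally likely sib genotypes, as sorted pairs
  g1a <- pmin(idx[, 1], idx[, 3]); g1b <- pmax(idx[, 1], idx[, 3])
  g2a <- pmin(idx[, 1], idx[, 4]); g2b <- pmax(idx[, 1], idx[, 4])
  g3a <- pmin(idx[, 2], idx[, 3]); g3b <- pmax(idx[, 2], idx[, 3])
  g4a <- pmin(idx[, 2], idx[, 4]); g4b <- pmax(idx[, 2], idx[, 4])
  A <- cbind(g1a, g2a, g3a, g4a)
  B <- cbind(g1b, g2b, g3b, g4b)
  match_p <- numeric(nrow(idx))
  for (c1 in 1:4) {
    for (c2 in 1:4) {
      match_p <- match_p + (A[, c1] == A[, c2] & B[, c1] == B[, c2]) / 16
    }
  }
  sum(w * match_p)
}

# Expected distinct alleles in a subsample of g gene copies, by
# exhaustive enumeration of all subsets.
oracle_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- combn(length(copies), g)
  mean(apply(subs, 2, function(s) length(unique(copies[s]))))
}

# All frequency vectors with k parts on a `step` grid (sorted
# descending; PID-type statistics are symmetric in allele labels).
grid_freq_vectors <- function(max_k = 6, step = 0.05) {
  units <- round(1 / step)
  partitions <- function(n, k, max_part) {
    if (k == 1) {
      if (n <= max_part) return(list(n)) else return(list())
    }
    out <- list()
    for (first in seq_len(min(n - k + 1, max_part))) {
      for (rest in partitions(n - first, k - 1, first)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  vecs <- list()
  for (k in seq_len(max_k)) {
    for (part in partitions(units, k, units)) {
      vecs[[length(vecs) + 1L]] <- sort(part, decreasing = TRUE) / units
    }
  }
  vecs
}

# Direct-definition Nei-Chesser differentiation, written as plain loops
# over a long genotype table; independent of the package's vectorised
# implementation.
oracle_diff <- function(ds, grouping, statistic) {
  gfac <- if (length(grouping) == 1) {
    switch(grouping, population = ds$pop, gene_pool = ds$gene_pool)
  } else as.character(grouping)
  levs <- unique(gfac)
  hs_l <- c(); ht_l <- c(); k_used <- NA
  for (loc in ds$loci) {
    ns <- c(); ho <- c(); pmats <- list()
    alleles <- sort(unique(stats::na.omit(c(ds$a1[, loc], ds$a2[, loc]))))
    for (g in levs) {
      rows <- which(gfac == g & !is.na(ds$a1[, loc]))
      if (!length(rows)) next
      cnt <- setNames(numeric(length(alleles)), alleles)
      het <- 0
      for (r in rows) {
        cnt[as.character(ds$a1[r, loc])] <-
          cnt[as.character(ds$a1[r, loc])] + 1
        cnt[as.character(ds$a2[r, loc])] <-
          cnt[as.character(ds$a2[r, loc])] + 1
        if (ds$a1[r, loc] != ds$a2[r, loc]) het <- het + 1
      }
      ns <- c(ns, length(rows))
      ho <- c(ho, het / length(rows))
      pmats[[g]] <- cnt / (2 * length(rows))
    }
    k <- length(pmats)
    if (k < 2) next
    k_used <- k
    ntilde <- k / sum(1 / ns)
    hs_raw <- mean(sapply(pmats, function(p) 1 - sum(p^2)))
    pbar <- Reduce(`+`, pmats) / k
    ht_raw <- 1 - sum(pbar^2)
    ho_bar <- mean(ho)
    hs <- ntilde / (ntilde - 1) * (hs_raw - ho_bar / (2 * ntilde))
    ht <- ht_raw + hs / (ntilde * k) - ho_bar / (2 * ntilde * k)
    hs_l <- c(hs_l, hs); ht_l <- c(ht_l, ht)
  }
  switch(statistic,
    gst = (sum(ht_l) - sum(hs_l)) / sum(ht_l),
    gppst = {
      mhs <- mean(hs_l); mht <- mean(ht_l)
      k_used * (mht - mhs) / ((k_used * mht - mhs) * (1 - mhs))
    },
    d = mean((k_used / (k_used - 1)) * (ht_l - hs_l) / (1 - hs_l)))
}

# Closed-form expected GST for the Balding-Nichols island model with k
# demes and drift parameter fst (estimator-independent large-sample
# value): Hs ~ (1-F)(1-sum p^2), Ht ~ (1-F/k)(1-sum p^2).
bn_expected_gst <- function(fst, k) {
  fst * (1 - 1 / k) / (1 - fst / k)
}
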