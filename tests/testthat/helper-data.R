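# Small hand-built datasets used across test files.

# Build a genotype_dataset from a list of per-individual genotype lists:
# geno[[ind]][[locus]] = c(a1, a2) or NA.
make_ds <- function(geno, pop = NULL, gene_pool = NULL, loci = NULL) {
  ind <- names(geno)
  if (is.null(loci)) loci <- names(geno[[1]])
  n <- length(ind)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    for (k in seq_along(loci)) {
      g <- geno[[i]][[loci[k]]]
      if (!is.null(g) && !all(is.na(g))) {
        a1[i, k] <- g[1]; a2[i, k] <- g[2]
      }
    }
  }
  if (is.null(pop)) pop <- rep("P1", n)
  if (is.null(gene_pool)) gene_pool <- rep("wild", n)
  genotype_dataset(ind, pop, gene_pool, loci, a1, a2)
}

# Dataset with two populations carrying fully disjoint fixed alleles.
disjoint_fixed_ds <- function(n_per_pop = 50) {
  ind <- c(sprintf("A%02d", seq_len(n_per_pop)),
           sprintf("B%02d", seq_len(n_per_pop)))
  a <- matrix(c(rep(100L, n_per_pop), rep(120L, n_per_pop)), ncol = 1)
  genotype_dataset(ind, rep(c("PA", "PB"), each = n_per_pop),
                   rep("wild", 2 * n_per_pop), "L1", a, a)
}

# Duplicate one sample set into k identically distributed "groups".
identical_groups_ds <- function(base_a1, base_a2, k = 3) {
  n <- nrow(base_a1)
  ind <- unlist(lapply(seq_len(k), function(g) sprintf("G%d_%02d", g, 1:n)))
  genotype_dataset(ind, rep(paste0("G", seq_len(k)), each = n),
                   rep("wild", k * n), colnames(base_a1),
                   do.call(rbind, replicate(k, base_a1, simplify = FALSE)),
                   do.call(rbind, replicate(k, base_a2, simplify = FALSE)))
}
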