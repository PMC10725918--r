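#' Per-group, per-locus diversity summary
#'
#' For every (group, locus) with data: `n_typed` diploid individuals,
#' `na` observed alleles, `ne = 1 / sum(p_i^2)` effective alleles,
#' `ho` observed heterozygosity, and `uhe` unbiased gene diversity
#' `(2N / (2N - 1)) (1 - sum(p_i^2))`.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()].
#' @return An object of class `diversity_table` (data frame with columns
#'   `group`, `locus`, `n_typed`, `na`, `ne`, `ho`, `uhe`).
#' @export
locus_summary <- function(ds, grouping = "population") {
  g <- .resolve_grouping(ds, grouping)
  rows <- list()
  for (lev in levels(g)) {
    for (loc in ds$loci) {
      x1 <- ds$a1[g == lev, loc]
      x2 <- ds$a2[g == lev, loc]
      ok <- !is.na(x1)
      n <- sum(ok)
      if (n == 0) next
      p <- as.numeric(table(c(x1[ok], x2[ok]))) / (2 * n)
      he <- 1 - sum(p^2)
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, locus = loc, n_typed = n, na = length(p),
        ne = 1 / sum(p^2), ho = mean(x1[ok] != x2[ok]),
        uhe = if (n > 1) (2 * n / (2 * n - 1)) * he else he,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_table", "data.frame")
  out
}

# closed-form hypergeometric rarefaction for one allele-count vector
.ar_closed_form <- function(counts, g) {
  N <- sum(counts)
  if (g > N) stop("rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g`
#' gene copies (hypergeometric rarefaction):
#' \deqn{AR(g) = \sum_a [1 - C(N - N_a, g) / C(N, g)]}
#' with `N` typed gene copies and `N_a` copies of allele `a`. The
#' default `g` is the smallest number of typed gene copies across the
#' compared groups at each locus, so groups are compared at a common
#' standardised size.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()].
#' @param g rarefaction size in gene copies (`>= 2`); `NULL` for the
#'   per-locus minimum across groups.
#' @return data frame `group`, `locus`, `g`, `ar`.
#' @export
allelic_richness <- function(ds, grouping = "population", g = NULL) {
  if (!is.null(g) && g < 2) stop("validation error: g must be >= 2")
  ft <- allele_frequencies(ds, grouping)
  nc <- attr(ft, "n_copies")
  rows <- list()
  for (loc in unique(ft$locus)) {
    ncl <- nc[nc$locus == loc, ]
    gl <- if (is.null(g)) min(ncl$n_copies) else g
    for (grp in ncl$group) {
      counts <- ft$count[ft$locus == loc & ft$group == grp]
      if (gl > sum(counts)) next  # group too small for requested g
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, locus = loc, g = gl,
        ar = .ar_closed_form(counts, gl), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Private alleles per group
#'
#' An allele is private to a group when it is observed there and in no
#' other group of the comparison.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()]; must yield >= 2 groups.
#' @return list with `counts` (named integer vector per group) and
#'   `alleles` (data frame `group`, `locus`, `allele`).
#' @export
private_alleles <- function(ds, grouping = "population") {
  ft <- allele_frequencies(ds, grouping)
  if (length(unique(ft$group)) < 2) {
    stop("private alleles require at least two groups")
  }
  key <- paste(ft$locus, ft$allele)
  n_groups_with <- table(key)
  priv <- ft[n_groups_with[key] == 1L, c("group", "locus", "allele")]
  rownames(priv) <- NULL
  counts <- table(factor(priv$group, levels = unique(ft$group)))
  list(counts = setNames(as.integer(counts), names(counts)),
       alleles = priv)
}

#' Within-population inbreeding coefficient with bootstrap CI
#'
#' Per locus, `f = 1 - Ho / Hs` with `Hs` the unbiased gene diversity;
#' the population estimate aggregates by ratio of sums across loci,
#' `FIS = 1 - sum(Ho) / sum(Hs)`, which is robust to low-diversity loci.
#' Confidence intervals are percentile bootstrap over loci.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()].
#' @param n_boot bootstrap replicates (>= 100 for a CI).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return data frame `group`, `fis`, `ci_lo`, `ci_hi`, `n_loci`.
#'   Groups monomorphic at every locus get `NA` estimates.
#' @export
fis_estimate <- function(ds, grouping = "population", n_boot = 1000,
                         seed = 1L, conf = 0.95) {
  if (n_boot < 100) stop("n_boot must be >= 100 for a bootstrap CI")
  tab <- locus_summary(ds, grouping)
  set.seed(seed)
  a <- (1 - conf) / 2
  rows <- lapply(unique(tab$group), function(grp) {
    t0 <- tab[tab$group == grp & tab$uhe > 0, ]
    if (!nrow(t0)) {
      return(data.frame(group = grp, fis = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_loci = 0L))
    }
    est <- 1 - sum(t0$ho) / sum(t0$uhe)
    boot <- vapply(seq_len(n_boot), function(b) {
      j <- sample(nrow(t0), replace = TRUE)
      1 - sum(t0$ho[j]) / sum(t0$uhe[j])
    }, numeric(1))
    data.frame(group = grp, fis = est,
               ci_lo = unname(quantile(boot, a)),
               ci_hi = unname(quantile(boot, 1 - a)),
               n_loci = nrow(t0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg permutation test
#'
#' Tests heterozygosity against Hardy-Weinberg expectation within one
#' population at one locus. The statistic is `|Ho - He|`; the null
#' distribution is generated by shuffling the typed gene copies among
#' individuals (allele frequencies, and hence `He`, are invariant), and
#' `p = (1 + #extreme) / (1 + n_perm)`. A heterozygote deficit driven by
#' inbreeding inflates the statistic.
#'
#' @param ds a [genotype_dataset()].
#' @param locus locus name.
#' @param population population label.
#' Because the permutation statistic is discrete, the reported `p_value`
#' is valid but conservative; `p_smooth` is the randomized permutation
#' p-value (ties broken uniformly), which is exactly Uniform(0,1) under
#' the null and is the quantity to use for calibration diagnostics.
#'
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list `p_value`, `p_smooth`, `ho`, `he`, `monomorphic`.
#' @export
hwe_test <- function(ds, locus, population, n_perm = 999, seed = 1L) {
  sel <- ds$pop == population
  x1 <- ds$a1[sel, locus]; x2 <- ds$a2[sel, locus]
  ok <- !is.na(x1)
  n <- sum(ok)
  if (n < 5) stop("need at least 5 typed individuals")
  copies <- c(x1[ok], x2[ok])
  p <- as.numeric(table(copies)) / (2 * n)
  he <- 1 - sum(p^2)
  ho <- mean(x1[ok] != x2[ok])
  if (length(unique(copies)) == 1) {
    return(list(p_value = 1, p_smooth = 1, ho = ho, he = he,
                monomorphic = TRUE))
  }
  set.seed(seed)
  obs <- abs(ho - he)
  greater <- 0L
  ties <- 0L
  for (b in seq_len(n_perm)) {
    s <- sample(copies)
    ho_b <- mean(s[seq_len(n)] != s[n + seq_len(n)])
    stat <- abs(ho_b - he)
    if (stat > obs + 1e-12) greater <- greater + 1L
    else if (stat > obs - 1e-12) ties <- ties + 1L
  }
  list(p_value = (1 + greater + ties) / (1 + n_perm),
       p_smooth = (greater + runif(1) * (1 + ties)) / (1 + n_perm),
       ho = ho, he = he, monomorphic = FALSE)
}

#' Allele accumulation (rarefaction) curve
#'
#' Expected total number of distinct alleles, summed over loci, in a
#' random subsample of `n` individuals (`2n` gene copies), for
#' `n = 1..N` per group. Computed by hypergeometric expectation on gene
#' copies; at loci with missing data the subsample size is capped at the
#' observed number of typed copies. The curve is non-decreasing and
#' concave; a bottlenecked group's curve lies below a diverse group's at
#' equal `n`.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()].
#' @return data frame `group`, `n_ind`, `expected_alleles`.
#' @export
allele_rarefaction_curve <- function(ds, grouping = "gene_pool") {
  gfac <- .resolve_grouping(ds, grouping)
  ft <- allele_frequencies(ds, grouping)
  rows <- list()
  for (lev in levels(gfac)) {
    N <- sum(gfac == lev)
    for (n in seq_len(N)) {
      ea <- 0
      for (loc in unique(ft$locus)) {
        counts <- ft$count[ft$locus == loc & ft$group == lev]
        if (!length(counts)) next
        gl <- min(2L * n, sum(counts))
        ea <- ea + .ar_closed_form(counts, gl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, n_ind = n, expected_alleles = ea,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
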