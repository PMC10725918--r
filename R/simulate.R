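#' Configuration for the SSR data simulator
#'
#' Defaults emulate a panel of hyper-variable dinucleotide SSRs scored on
#' a set of weakly differentiated wild populations plus a cultivated
#' gene pool: 8 wild populations of 30 diploid individuals, 10 loci with
#' 15-30 alleles each on a 2-bp ladder, within-population inbreeding
#' FIS = 0.15, weak differentiation (Balding-Nichols FST = 0.02), five
#' injected clone pairs differing by at most 2 alleles, a per-allele
#' mis-scoring rate of 0.85% and 1% missing cells. The cultivated group
#' is drawn from the same ancestral frequencies but with a larger drift
#' parameter (`cultivar_fst`), producing the allele-poorer, bottlenecked
#' profile typical of clonally propagated crops.
#'
#' @param n_pops number of wild populations.
#' @param n_per_pop diploid individuals per wild population.
#' @param n_cultivars individuals in the cultivated group (0 disables it).
#' @param n_loci number of loci.
#' @param alleles_per_locus integer, or length-2 range sampled per locus.
#' @param motif_step ladder step in bp.
#' @param base_length shortest allele length in bp.
#' @param fst Balding-Nichols differentiation parameter, in \[0, 1).
#' @param cultivar_fst drift parameter for the cultivated group.
#' @param fis within-population inbreeding coefficient, in \[0, 1\].
#' @param clone_pairs number of clonal copies appended by
#'   [inject_clones()].
#' @param clone_error_alleles maximum alleles perturbed per clonal copy.
#' @param scoring_error_rate per-allele mis-scoring probability.
#' @param missing_rate per-cell missing probability.
#' @param seed RNG seed used by [simulate_ssr_dataset()].
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 8, n_per_pop = 30, n_cultivars = 60,
                       n_loci = 10, alleles_per_locus = c(15, 30),
                       motif_step = 2, base_length = 100,
                       fst = 0.02, cultivar_fst = 0.12, fis = 0.15,
                       clone_pairs = 5, clone_error_alleles = 2,
                       scoring_error_rate = 0.0085, missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
              n_cultivars = as.integer(n_cultivars),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              motif_step = as.integer(motif_step),
              base_length = as.integer(base_length),
              fst = fst, cultivar_fst = cultivar_fst, fis = fis,
              clone_pairs = as.integer(clone_pairs),
              clone_error_alleles = as.integer(clone_error_alleles),
              scoring_error_rate = scoring_error_rate,
              missing_rate = missing_rate, seed = as.integer(seed))
  counts <- c("n_pops", "n_per_pop", "n_loci", "motif_step", "base_length")
  for (f in counts) {
    if (cfg[[f]] < 1) stop("config error: '", f, "' must be positive")
  }
  if (cfg$n_cultivars < 0 || cfg$clone_pairs < 0 ||
      cfg$clone_error_alleles < 0) {
    stop("config error: counts must be non-negative")
  }
  if (!length(cfg$alleles_per_locus) %in% c(1, 2) ||
      any(cfg$alleles_per_locus < 1)) {
    stop("config error: 'alleles_per_locus' must be a count or range")
  }
  for (f in c("fis", "scoring_error_rate", "missing_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config error: '", f, "' must be in [0, 1]")
    }
  }
  for (f in c("fst", "cultivar_fst")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop("config error: '", f, "' must be in [0, 1)")
    }
  }
  if (cfg$clone_error_alleles > 2L * cfg$n_loci) {
    stop("config error: 'clone_error_alleles' exceeds 2 * n_loci")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1  # degenerate guard
  x / sum(x)
}

#' Simulate population allele frequencies (Balding-Nichols model)
#'
#' Per locus, ancestral frequencies are drawn from a symmetric
#' Dirichlet(1) over a ladder of allele lengths
#' `base_length + (0:(k-1)) * motif_step`; each population's frequencies
#' are then drawn from Dirichlet(p * (1 - fst) / fst). With `fst = 0`
#' all populations share the ancestral frequencies exactly. The
#' cultivated group (`group "CULT"`) uses `cultivar_fst` as its drift
#' parameter.
#'
#' @param cfg a [sim_config()].
#' @return an `allele_freq_table` over groups `P1..Pn` (+ `CULT`), with
#'   the per-locus ladder in attribute `ladder`. Zero-frequency alleles
#'   are retained so every group shares the same allele ladder.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pops <- paste0("P", seq_len(cfg$n_pops))
  groups <- c(pops, if (cfg$n_cultivars > 0) "CULT")
  rows <- list()
  ladder <- list()
  for (l in seq_len(cfg$n_loci)) {
    k <- if (length(cfg$alleles_per_locus) == 1) cfg$alleles_per_locus else
      sample(cfg$alleles_per_locus[1]:cfg$alleles_per_locus[2], 1)
    alleles <- cfg$base_length + (seq_len(k) - 1L) * cfg$motif_step
    loc <- sprintf("L%02d", l)
    ladder[[loc]] <- alleles
    p_anc <- .rdirichlet1(rep(1, k))
    for (g in groups) {
      f <- if (g == "CULT") cfg$cultivar_fst else cfg$fst
      p <- if (f == 0) p_anc else .rdirichlet1(p_anc * (1 - f) / f)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, group = g, allele = alleles, count = NA_integer_,
        freq = p, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus = loc, group = "ancestral", allele = alleles,
      count = NA_integer_, freq = p_anc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ladder") <- ladder
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

#' Simulate diploid genotypes from population frequencies
#'
#' Genotypes are drawn with inbreeding: with probability `fis` the two
#' gene copies are identical by descent (a single allele draw), otherwise
#' two independent draws, giving P(homozygote i) = p_i^2 + fis p_i (1-p_i)
#' and P(heterozygote ij) = 2 p_i p_j (1 - fis). Missing cells are then
#' masked i.i.d. at `missing_rate`.
#'
#' @param freqs an `allele_freq_table` from [simulate_frequencies()].
#' @param cfg a [sim_config()].
#' @return a [genotype_dataset()] with populations `P1..Pn` (gene pool
#'   `"wild"`) and optionally `CULT` (gene pool `"cultivar"`), carrying
#'   the simulation ladder in attribute `ladder`.
#' @export
simulate_genotypes <- function(freqs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pops <- paste0("P", seq_len(cfg$n_pops))
  groups <- c(pops, if (cfg$n_cultivars > 0) "CULT")
  sizes <- c(rep(cfg$n_per_pop, cfg$n_pops),
             if (cfg$n_cultivars > 0) cfg$n_cultivars)
  loci <- unique(freqs$locus)
  n <- sum(sizes)
  pop <- rep(groups, sizes)
  ind <- unlist(lapply(seq_along(groups), function(i) {
    sprintf("%s_%03d", groups[i], seq_len(sizes[i]))
  }))
  gp <- ifelse(pop == "CULT", "cultivar", "wild")
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (k in seq_along(loci)) {
    for (g in groups) {
      sel <- freqs$locus == loci[k] & freqs$group == g
      alleles <- freqs$allele[sel]
      p <- freqs$freq[sel]
      rows <- which(pop == g)
      m <- length(rows)
      ibd <- runif(m) < cfg$fis
      x1 <- sample(alleles, m, replace = TRUE, prob = p)
      x2 <- sample(alleles, m, replace = TRUE, prob = p)
      x2[ibd] <- x1[ibd]
      a1[rows, k] <- x1
      a2[rows, k] <- x2
    }
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(n * length(loci)) < cfg$missing_rate, n)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  ds <- genotype_dataset(ind, pop, gp, loci, a1, a2)
  attr(ds, "ladder") <- attr(freqs, "ladder")
  ds
}

# ladder neighbour one motif step away, reflected at the ladder ends
.ladder_neighbour <- function(allele, ladder, step) {
  lo <- min(ladder); hi <- max(ladder)
  up <- allele + step
  dn <- allele - step
  if (dn < lo) up
  else if (up > hi) dn
  else if (runif(1) < 0.5) up else dn
}

.ds_ladder <- function(ds, cfg) {
  lad <- attr(ds, "ladder")
  if (is.null(lad)) {
    lad <- lapply(ds$loci, function(loc) {
      obs <- c(ds$a1[, loc], ds$a2[, loc])
      obs <- obs[!is.na(obs)]
      seq(min(obs), max(obs), by = cfg$motif_step)
    })
    names(lad) <- ds$loci
  }
  lad
}

#' Append clonal copies of randomly chosen individuals
#'
#' Each copy replicates its source genotype and then has `0..clone_error_alleles`
#' alleles (uniformly drawn) replaced by a one-step ladder neighbour,
#' emulating clones that differ only through genotyping error or somatic
#' mutation at hyper-variable loci. Copies keep the source's population
#' and gene pool and are named `<source>_cl<i>`.
#'
#' @param ds a [genotype_dataset()].
#' @param cfg a [sim_config()].
#' @return the augmented data set; attribute `clone_truth` is a data
#'   frame (`source`, `clone`, `n_perturbed`) for truth-tracking.
#' @export
inject_clones <- function(ds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$clone_pairs == 0) {
    attr(ds, "clone_truth") <- data.frame(source = character(),
                                          clone = character(),
                                          n_perturbed = integer())
    return(ds)
  }
  if (cfg$clone_pairs > n_ind(ds)) {
    stop("config error: more clone pairs than individuals")
  }
  lad <- .ds_ladder(ds, cfg)
  src <- sample(ds$ind, cfg$clone_pairs)
  add1 <- matrix(NA_integer_, cfg$clone_pairs, n_loci(ds))
  add2 <- matrix(NA_integer_, cfg$clone_pairs, n_loci(ds))
  truth <- data.frame(source = src,
                      clone = paste0(src, "_cl", seq_along(src)),
                      n_perturbed = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(src)) {
    j <- match(src[i], ds$ind)
    x1 <- ds$a1[j, ]; x2 <- ds$a2[j, ]
    n_err <- sample(0:cfg$clone_error_alleles, 1)
    typed <- which(!is.na(x1))
    slots <- c(typed, typed + n_loci(ds))  # allele slots: a1 then a2
    n_err <- min(n_err, length(slots))
    for (s in if (n_err > 0) sample(slots, n_err) else integer()) {
      loc <- ((s - 1L) %% n_loci(ds)) + 1L
      if (s <= n_loci(ds)) {
        x1[loc] <- .ladder_neighbour(x1[loc], lad[[loc]], cfg$motif_step)
      } else {
        x2[loc] <- .ladder_neighbour(x2[loc], lad[[loc]], cfg$motif_step)
      }
    }
    add1[i, ] <- x1; add2[i, ] <- x2
    truth$n_perturbed[i] <- n_err
  }
  j <- match(src, ds$ind)
  out <- genotype_dataset(
    c(ds$ind, truth$clone), c(ds$pop, ds$pop[j]),
    c(ds$gene_pool, ds$gene_pool[j]), ds$loci,
    rbind(ds$a1, add1), rbind(ds$a2, add2))
  attr(out, "ladder") <- attr(ds, "ladder")
  attr(out, "clone_truth") <- truth
  out
}

#' Apply per-allele mis-scoring error
#'
#' Every non-missing allele is independently replaced by a one-step
#' ladder neighbour with probability `scoring_error_rate`, mimicking the
#' dominant SSR genotyping failure mode (mis-called fragment length one
#' motif away), not allele dropout.
#'
#' @param ds a [genotype_dataset()].
#' @param cfg a [sim_config()].
#' @return the perturbed data set; attribute `perturbation_counts` gives
#'   the number of altered alleles per locus.
#' @export
apply_scoring_error <- function(ds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- setNames(integer(n_loci(ds)), ds$loci)
  if (cfg$scoring_error_rate == 0) {
    attr(ds, "perturbation_counts") <- counts
    return(ds)
  }
  lad <- .ds_ladder(ds, cfg)
  a1 <- ds$a1; a2 <- ds$a2
  for (k in seq_len(n_loci(ds))) {
    for (mat in 1:2) {
      a <- if (mat == 1) a1 else a2
      hit <- which(!is.na(a[, k]) & runif(nrow(a)) < cfg$scoring_error_rate)
      for (j in hit) {
        a[j, k] <- .ladder_neighbour(a[j, k], lad[[ds$loci[k]]],
                                     cfg$motif_step)
      }
      if (mat == 1) a1 <- a else a2 <- a
      counts[k] <- counts[k] + length(hit)
    }
  }
  out <- genotype_dataset(ds$ind, ds$pop, ds$gene_pool, ds$loci, a1, a2)
  attr(out, "ladder") <- attr(ds, "ladder")
  attr(out, "clone_truth") <- attr(ds, "clone_truth")
  attr(out, "perturbation_counts") <- counts
  out
}

#' Simulate a complete SSR data set
#'
#' Runs the full generator chain — frequencies, genotypes, clone
#' injection, scoring error — under a single seed, so a config fully
#' determines the data set bit for bit.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_dataset()] with attributes `ladder`,
#'   `clone_truth`, `perturbation_counts` and `sim_config`.
#' @export
simulate_ssr_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  freqs <- simulate_frequencies(cfg)
  ds <- simulate_genotypes(freqs, cfg)
  ds <- inject_clones(ds, cfg)
  ds <- apply_scoring_error(ds, cfg)
  attr(ds, "sim_config") <- cfg
  attr(ds, "sim_frequencies") <- freqs
  ds
}
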