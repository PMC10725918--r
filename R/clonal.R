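#' Pairwise allele-difference distances
#'
#' For every pair of individuals, the distance is the number of allele
#' differences summed over loci typed in both (per locus:
#' `2 - |multiset intersection|` of the two unordered pairs), so one
#' unit of distance equals one allele of difference. Loci missing in
#' either individual are excluded pairwise and counted separately; a
#' pair with no comparable locus gets an undefined (`NA`) distance.
#'
#' @param ds a [genotype_dataset()] with at least two individuals.
#' @return An object of class `ssr_dist`: a list with integer matrices
#'   `d` (distances, `NA` when undefined) and `comparable` (number of
#'   loci typed in both individuals).
#' @export
pairwise_distance <- function(ds) {
  n <- n_ind(ds)
  if (n < 2) stop("need at least two individuals")
  L <- n_loci(ds)
  # per-locus mismatch via vectorised comparison of sorted pairs
  d <- matrix(0L, n, n, dimnames = list(ds$ind, ds$ind))
  comp <- matrix(0L, n, n, dimnames = list(ds$ind, ds$ind))
  for (k in seq_len(L)) {
    x1 <- ds$a1[, k]; x2 <- ds$a2[, k]
    typed <- !is.na(x1)
    tj <- which(typed)
    if (length(tj) < 2) next
    # mismatch(i,j) for sorted pairs (x1<=x2):
    # 0 if identical; else 1 if pairs share >=1 allele (as multisets); else 2
    s1 <- x1[tj]; s2 <- x2[tj]
    eq <- outer(s1, s1, "==") & outer(s2, s2, "==")
    share <- outer(s1, s1, "==") | outer(s2, s2, "==") |
      outer(s1, s2, "==") | outer(s2, s1, "==")
    # shared-allele test above overcounts one case: pairs {a,a} vs {b,a}
    # are caught correctly, but {a,b} vs {b,a} cannot occur (sorted).
    # Homozygote {a,a} vs heterozygote {a,b}: share TRUE, eq FALSE -> 1. ok
    mm <- matrix(2L, length(tj), length(tj))
    mm[share] <- 1L
    mm[eq] <- 0L
    d[tj, tj] <- d[tj, tj] + mm
    comp[tj, tj] <- comp[tj, tj] + 1L
  }
  d[comp == 0L] <- NA_integer_
  diag(d) <- 0L
  structure(list(d = d, comparable = comp), class = "ssr_dist")
}

#' @export
print.ssr_dist <- function(x, ...) {
  cat("ssr_dist:", nrow(x$d), "individuals; distance range",
      paste(range(x$d[upper.tri(x$d)], na.rm = TRUE), collapse = "-"), "\n")
  invisible(x)
}

#' Histogram of pairwise distances
#'
#' Counts of unordered pairs per integer distance, 0..max. Undefined
#' pairs (no comparable locus) are excluded, so the histogram total is
#' the number of defined pairs.
#'
#' @param dm an `ssr_dist` from [pairwise_distance()].
#' @return data frame with columns `distance`, `count`.
#' @export
distance_histogram <- function(dm) {
  stopifnot(inherits(dm, "ssr_dist"))
  v <- dm$d[upper.tri(dm$d)]
  v <- v[!is.na(v)]
  if (!length(v)) return(data.frame(distance = integer(), count = integer()))
  tab <- tabulate(v + 1L, nbins = max(v) + 1L)
  data.frame(distance = 0:max(v), count = tab)
}

#' Suggest a clone-contraction threshold from the distance histogram
#'
#' Automates the visual rule of reading a small initial peak off the
#' histogram of pairwise distances: clones and near-clones form a clump
#' of low distances separated by a valley from the main mass of
#' unrelated-pair distances. The threshold returned is the largest
#' distance inside that clump. The valley is located as the longest run
#' of zero counts between the first non-zero distance and the
#' histogram's main mode (low-distance clumps are sparse, so internal
#' single-distance dips must not split them); for a continuous
#' histogram with no empty valley, the first local peak followed by a
#' local minimum `m` is used and the threshold is `m - 1`. If the
#' histogram rises monotonically into its main mode (no separated
#' low-distance clump), 0 is returned with a warning.
#'
#' @param histogram data frame from [distance_histogram()].
#' @return a single integer threshold.
#' @export
suggest_threshold <- function(histogram) {
  if (!nrow(histogram)) stop("empty histogram")
  counts <- merge(data.frame(distance = 0:max(histogram$distance)),
                  histogram, all.x = TRUE)
  counts$count[is.na(counts$count)] <- 0L
  y <- counts$count
  n <- length(y)
  if (n < 3) return(0L)
  mode_i <- which.max(y)
  first_nz <- which(y > 0)[1]
  if (first_nz >= mode_i) {
    warning("histogram rises straight into its main mode; returning 0")
    return(0L)
  }
  # longest zero-count valley strictly between the clump and the mode
  run_len <- 0L; run_start <- NA_integer_
  best_len <- 0L; best_start <- NA_integer_
  for (i in seq(first_nz + 1L, mode_i - 1L)) {
    if (y[i] == 0L) {
      if (run_len == 0L) run_start <- i
      run_len <- run_len + 1L
      if (run_len > best_len) { best_len <- run_len; best_start <- run_start }
    } else run_len <- 0L
  }
  if (best_len > 0L) {
    return(counts$distance[best_start - 1L])
  }
  # continuous histogram: literal first-peak / first-minimum scan
  peak <- NA_integer_
  for (i in seq_len(n - 1)) {
    if (y[i] > 0 && y[i + 1] < y[i]) { peak <- i; break }
  }
  if (is.na(peak) || y[peak] == max(y)) {
    warning("no low-distance peak in histogram; returning 0")
    return(0L)
  }
  m <- n
  for (i in seq(peak + 1, n - 1)) {
    if (y[i + 1] >= y[i]) { m <- i; break }
  }
  max(counts$distance[m] - 1L, 0L)
}

#' Contract near-identical multilocus genotypes
#'
#' Links individuals whose pairwise distance is at most `threshold` and
#' takes connected components (single linkage) as multilocus genotype
#' (MLG) classes; at `threshold = 0` these are strict MLGs, at larger
#' thresholds "contracted" MLGs that absorb genotyping error and somatic
#' mutation. Undefined distances never link. The representative of each
#' MLG is its member with the fewest missing cells (ties broken by
#' lexicographic ID).
#'
#' @param ds a [genotype_dataset()].
#' @param threshold non-negative integer distance threshold.
#' @param dm optional precomputed [pairwise_distance()] result.
#' @return An object of class `mlg_assignment`: a data frame with
#'   columns `ind`, `mlg` (integer id), `representative` (logical), and
#'   attributes `threshold` and `contracted` (logical per MLG: collapsed
#'   at distance > 0).
#' @export
contract_mlgs <- function(ds, threshold = 0, dm = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.null(dm)) dm <- pairwise_distance(ds)
  d <- dm$d
  n <- nrow(d)
  adj <- !is.na(d) & d <= threshold
  # connected components via repeated BFS
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  miss <- rowSums(is.na(ds$a1))
  rep_flag <- logical(n)
  contracted <- logical(cur)
  for (c0 in seq_len(cur)) {
    mem <- which(comp == c0)
    ord <- mem[order(miss[mem], ds$ind[mem])]
    rep_flag[ord[1]] <- TRUE
    if (length(mem) > 1) {
      contracted[c0] <- max(d[mem, mem], na.rm = TRUE) > 0
    }
  }
  out <- data.frame(ind = ds$ind, mlg = comp, representative = rep_flag,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "contracted") <- contracted
  attr(out, "dist") <- dm
  class(out) <- c("mlg_assignment", "data.frame")
  out
}

#' Report synonym groups and contracted MLGs
#'
#' One row per multi-member MLG, listing member IDs, their gene pools
#' and the maximum intra-MLG distance. Groups with maximum distance 0
#' are exact synonyms; the rest are contracted MLGs.
#'
#' @param mlgs an `mlg_assignment` from [contract_mlgs()].
#' @param ds the matching [genotype_dataset()].
#' @return data frame `mlg`, `size`, `members`, `gene_pools`,
#'   `max_distance`, `type` (`"synonym"` or `"contracted"`).
#' @export
synonymy_report <- function(mlgs, ds) {
  stopifnot(inherits(mlgs, "mlg_assignment"))
  dm <- attr(mlgs, "dist")
  rows <- list()
  for (m in unique(mlgs$mlg)) {
    mem <- which(mlgs$mlg == m)
    if (length(mem) < 2) next
    dmax <- max(dm$d[mem, mem], na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      mlg = m, size = length(mem),
      members = paste(mlgs$ind[mem], collapse = ";"),
      gene_pools = paste(ds$gene_pool[match(mlgs$ind[mem], ds$ind)],
                         collapse = ";"),
      max_distance = dmax,
      type = if (dmax == 0) "synonym" else "contracted",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(mlg = integer(), size = integer(),
                      members = character(), gene_pools = character(),
                      max_distance = integer(), type = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep one representative per MLG
#'
#' Convenience wrapper used before population-level analyses so that
#' clonal duplicates do not bias frequencies.
#'
#' @param ds a [genotype_dataset()].
#' @param mlgs an `mlg_assignment`; computed at `threshold` if missing.
#' @param threshold passed to [contract_mlgs()] when `mlgs` is `NULL`.
#' @return a [genotype_dataset()] restricted to MLG representatives.
#' @export
deduplicate_mlgs <- function(ds, mlgs = NULL, threshold = 0) {
  if (is.null(mlgs)) mlgs <- contract_mlgs(ds, threshold)
  subset(ds, individuals = mlgs$ind[mlgs$representative])
}
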