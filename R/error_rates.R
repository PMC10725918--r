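#' Genotyping error rates from replicate runs
#'
#' Compares two independent genotyping runs of the same individuals.
#' A *reaction* is one (individual, locus) cell genotyped in both runs;
#' it counts as erroneous when the two unordered allele pairs differ.
#' Allele errors per reaction are `2 - |multiset intersection|` of the
#' two pairs, so a single mis-scored allele ({100,102} vs {100,104})
#' contributes one allele error, and completely disjoint pairs two.
#' Cells missing in either run are excluded from the denominator.
#'
#' @param ds_a,ds_b [genotype_dataset()] objects sharing individual IDs
#'   and loci (their intersection is compared).
#' @return An object of class `error_rate_table`: a data frame with one
#'   row per locus plus `Mean` and `Total` rows and columns
#'   `locus`, `n_reactions`, `n_errors_reaction`, `n_errors_allele`,
#'   `rate_per_reaction`, `rate_per_allele`. The `Mean` row holds the
#'   overall rates computed from the totals
#'   (`sum errors / sum reactions`), the convention used when a single
#'   overall per-reaction and per-allele rate is quoted for a panel.
#' @export
compare_replicates <- function(ds_a, ds_b) {
  shared_ind <- intersect(ds_a$ind, ds_b$ind)
  shared_loci <- intersect(ds_a$loci, ds_b$loci)
  if (!length(shared_ind)) {
    stop("validation error: replicates share no individuals")
  }
  if (!length(shared_loci)) {
    stop("validation error: replicates share no loci")
  }
  ia <- match(shared_ind, ds_a$ind)
  ib <- match(shared_ind, ds_b$ind)
  res <- data.frame(locus = shared_loci, n_reactions = 0L,
                    n_errors_reaction = 0L, n_errors_allele = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_along(shared_loci)) {
    loc <- shared_loci[k]
    p1 <- cbind(ds_a$a1[ia, loc], ds_a$a2[ia, loc])
    p2 <- cbind(ds_b$a1[ib, loc], ds_b$a2[ib, loc])
    ok <- !is.na(p1[, 1]) & !is.na(p2[, 1])
    res$n_reactions[k] <- sum(ok)
    if (!any(ok)) next
    nerr <- vapply(which(ok), function(j) {
      .allele_mismatch(p1[j, ], p2[j, ])
    }, integer(1))
    res$n_errors_reaction[k] <- sum(nerr > 0L)
    res$n_errors_allele[k] <- sum(nerr)
  }
  if (sum(res$n_reactions) == 0L) {
    warning("no comparable reactions between replicates")
  }
  res$rate_per_reaction <- ifelse(res$n_reactions > 0,
                                  res$n_errors_reaction / res$n_reactions,
                                  NA_real_)
  res$rate_per_allele <- ifelse(res$n_reactions > 0,
                                res$n_errors_allele / (2 * res$n_reactions),
                                NA_real_)
  tot_rx <- sum(res$n_reactions)
  overall_rx <- if (tot_rx > 0) sum(res$n_errors_reaction) / tot_rx else
    NA_real_
  overall_al <- if (tot_rx > 0) sum(res$n_errors_allele) / (2 * tot_rx) else
    NA_real_
  out <- rbind(
    res,
    data.frame(locus = "Mean", n_reactions = NA_integer_,
               n_errors_reaction = NA_integer_, n_errors_allele = NA_integer_,
               rate_per_reaction = overall_rx, rate_per_allele = overall_al,
               stringsAsFactors = FALSE),
    data.frame(locus = "Total", n_reactions = tot_rx,
               n_errors_reaction = sum(res$n_errors_reaction),
               n_errors_allele = sum(res$n_errors_allele),
               rate_per_reaction = NA_real_, rate_per_allele = NA_real_,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("error_rate_table", "data.frame")
  out
}

# allele errors between two unordered genotype pairs:
# 2 - size of multiset intersection
.allele_mismatch <- function(g1, g2) {
  g1 <- sort(g1); g2 <- sort(g2)
  inter <- 0L
  used <- c(FALSE, FALSE)
  for (a in g1) {
    hit <- which(!used & g2 == a)
    if (length(hit)) {
      inter <- inter + 1L
      used[hit[1]] <- TRUE
    }
  }
  2L - inter
}

#' Reconstruct a replicate pair with a prescribed comparison structure
#'
#' Builds two deterministic replicate data sets whose comparison by
#' [compare_replicates()] yields exactly the given per-locus numbers of
#' comparable reactions and (single-allele) errors — useful for
#' validating the error-rate computation against a published QC table,
#' where the per-locus counts are the primary data. Reactions beyond
#' `n_reactions` at a locus are made incomparable by blanking the cell
#' in the second replicate.
#'
#' @param counts data frame with columns `locus`, `n_reactions`,
#'   `n_errors` (single-allele errors).
#' @param n_individuals panel size per replicate (defaults to the
#'   largest `n_reactions`).
#' @return list with `a` and `b`, two [genotype_dataset()] objects.
#' @export
simulate_replicate_pair <- function(counts, n_individuals = NULL) {
  need <- c("locus", "n_reactions", "n_errors")
  if (!all(need %in% names(counts))) {
    stop("counts needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(n_individuals)) n_individuals <- max(counts$n_reactions)
  if (any(counts$n_errors > counts$n_reactions)) {
    stop("more errors than reactions at some locus")
  }
  if (any(counts$n_reactions > n_individuals)) {
    stop("n_reactions exceeds the panel size")
  }
  n <- n_individuals
  ind <- sprintf("rep_ind_%03d", seq_len(n))
  L <- nrow(counts)
  base1 <- matrix(100L, n, L)
  base2 <- matrix(102L, n, L)
  b1 <- base1
  b2 <- base2
  for (k in seq_len(L)) {
    ne <- counts$n_errors[k]
    if (ne > 0) b2[seq_len(ne), k] <- 104L  # one mis-scored allele
    drop <- counts$n_reactions[k] < n
    if (drop) {
      miss <- seq(counts$n_reactions[k] + 1L, n)
      b1[miss, k] <- NA_integer_
      b2[miss, k] <- NA_integer_
    }
  }
  gp <- rep("wild", n)
  pop <- rep("QC", n)
  list(a = genotype_dataset(ind, pop, gp, counts$locus, base1, base2),
       b = genotype_dataset(ind, pop, gp, counts$locus, b1, b2))
}

#' Overall error rates of an error-rate table
#'
#' @param x an `error_rate_table` from [compare_replicates()].
#' @return named numeric vector `rate_per_reaction`, `rate_per_allele`
#'   (totals-based).
#' @export
overall_error_rates <- function(x) {
  stopifnot(inherits(x, "error_rate_table"))
  m <- x[x$locus == "Mean", ]
  c(rate_per_reaction = m$rate_per_reaction,
    rate_per_allele = m$rate_per_allele)
}
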