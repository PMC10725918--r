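#' Construct a diploid SSR genotype data set
#'
#' The central container of the package: individuals by loci diploid
#' genotypes with alleles coded as fragment lengths in base pairs.
#' Genotypes are unphased; each cell is stored in canonical (ascending)
#' allele order. A cell is either a complete pair or missing — half-called
#' genotypes are not representable.
#'
#' @param ind character vector of unique individual identifiers.
#' @param pop character vector of population labels, one per individual.
#' @param gene_pool character vector, one per individual, each one of
#'   `"wild"`, `"cultivar"`, `"outgroup"`.
#' @param loci character vector of locus names (order is preserved by all
#'   readers and writers).
#' @param a1,a2 integer matrices (`length(ind)` x `length(loci)`) holding
#'   the two allele lengths of each genotype; `NA` in both marks a missing
#'   cell. Pairs are reordered so that `a1 <= a2`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `ind`, `pop`, `gene_pool`, `loci`, `a1`, `a2`.
#' @export
#' @examples
#' ds <- genotype_dataset(
#'   ind = c("i1", "i2"), pop = c("P1", "P1"), gene_pool = c("wild", "wild"),
#'   loci = "L1", a1 = matrix(c(100L, 102L)), a2 = matrix(c(104L, 102L))
#' )
#' ds
genotype_dataset <- function(ind, pop, gene_pool, loci, a1, a2) {
  ind <- as.character(ind)
  loci <- as.character(loci)
  if (anyDuplicated(ind)) {
    stop("duplicate individual IDs: ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "))
  }
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (length(pop) != length(ind) || length(gene_pool) != length(ind)) {
    stop("'pop' and 'gene_pool' must have one entry per individual")
  }
  pop <- as.character(pop)
  gene_pool <- as.character(gene_pool)
  bad <- setdiff(unique(gene_pool), .GENE_POOLS)
  if (length(bad)) {
    stop("unknown gene pool label(s): ", paste(bad, collapse = ", "),
         " (expected wild/cultivar/outgroup)")
  }
  a1 <- .as_allele_matrix(a1, ind, loci, "a1")
  a2 <- .as_allele_matrix(a2, ind, loci, "a2")
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing genotypes are not representable: a cell must be ",
         "a complete allele pair or fully missing")
  }
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0L) || any(a2[ok] <= 0L)) {
    stop("allele lengths must be positive integers")
  }
  swap <- ok & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  structure(
    list(ind = ind, pop = pop, gene_pool = gene_pool, loci = loci,
         a1 = a1, a2 = a2),
    class = "genotype_dataset"
  )
}

.as_allele_matrix <- function(m, ind, loci, what) {
  m <- as.matrix(m)
  if (nrow(m) != length(ind) || ncol(m) != length(loci)) {
    stop("'", what, "' must be a ", length(ind), " x ", length(loci),
         " matrix")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ind, loci)
  m
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$ind), "individuals,",
      length(x$loci), "loci\n")
  cat("  populations:", paste(unique(x$pop), collapse = ", "), "\n")
  gp <- table(x$gene_pool)
  cat("  gene pools: ", paste(names(gp), gp, sep = "=", collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals and loci
#'
#' @param ds a [genotype_dataset()].
#' @return `n_ind()` and `n_loci()` return single integers.
#' @export
n_ind <- function(ds) length(ds$ind)

#' @rdname n_ind
#' @export
n_loci <- function(ds) length(ds$loci)

#' Subset a genotype data set
#'
#' Restrict a data set to named individuals, populations, gene pools
#' and/or loci. Order of retained individuals and loci is preserved;
#' population and gene-pool labels are carried over. Typical uses are
#' dropping a failing locus from the panel or excluding a population too
#' small for population-level inference.
#'
#' @param x a [genotype_dataset()].
#' @param individuals,populations,loci,gene_pools character vectors of
#'   names to keep; `NULL` (default) keeps everything for that margin.
#'   Individual/population/gene-pool filters are combined by
#'   intersection.
#' @param ... unused.
#' @return a `genotype_dataset`.
#' @export
subset.genotype_dataset <- function(x, individuals = NULL, populations = NULL,
                                    loci = NULL, gene_pools = NULL, ...) {
  .check_known <- function(req, have, what) {
    bad <- setdiff(req, have)
    if (length(bad)) {
      stop("unknown ", what, ": ", paste(bad, collapse = ", "),
           "; valid: ", paste(unique(have), collapse = ", "))
    }
  }
  keep <- rep(TRUE, length(x$ind))
  if (!is.null(individuals)) {
    .check_known(individuals, x$ind, "individual(s)")
    keep <- keep & x$ind %in% individuals
  }
  if (!is.null(populations)) {
    .check_known(populations, x$pop, "population(s)")
    keep <- keep & x$pop %in% populations
  }
  if (!is.null(gene_pools)) {
    .check_known(gene_pools, .GENE_POOLS, "gene pool(s)")
    keep <- keep & x$gene_pool %in% gene_pools
  }
  lkeep <- x$loci
  if (!is.null(loci)) {
    .check_known(loci, x$loci, "locus/loci")
    lkeep <- x$loci[x$loci %in% loci]
  }
  if (!any(keep)) stop("subset would retain no individuals")
  if (!length(lkeep)) stop("subset would retain no loci")
  genotype_dataset(
    ind = x$ind[keep], pop = x$pop[keep], gene_pool = x$gene_pool[keep],
    loci = lkeep,
    a1 = x$a1[keep, lkeep, drop = FALSE],
    a2 = x$a2[keep, lkeep, drop = FALSE]
  )
}

# Resolve a grouping specification to a factor over individuals.
# grouping: "pooled", "population", "gene_pool", or a vector (possibly
# named by individual ID) of labels.
.resolve_grouping <- function(ds, grouping) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% c("pooled", "population", "gene_pool")) {
    g <- switch(grouping,
      pooled = rep("all", length(ds$ind)),
      population = ds$pop,
      gene_pool = ds$gene_pool
    )
  } else if (length(grouping) == length(ds$ind)) {
    g <- as.character(grouping)
    if (!is.null(names(grouping))) {
      if (!setequal(names(grouping), ds$ind)) {
        stop("named grouping vector must cover exactly the individuals")
      }
      g <- as.character(grouping[ds$ind])
    }
  } else {
    stop("'grouping' must be \"pooled\", \"population\", \"gene_pool\" ",
         "or a label per individual")
  }
  factor(g, levels = unique(g))
}

#' Allele frequencies per locus and group
#'
#' Frequencies are computed from non-missing gene copies only (two per
#' typed diploid individual). A (locus, group) combination with zero
#' typed copies is simply absent from the table rather than reported as
#' `NaN`.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping `"pooled"` (default), `"population"`, `"gene_pool"`,
#'   or a custom label per individual.
#' @return An object of class `allele_freq_table`: a data frame with
#'   columns `locus`, `group`, `allele`, `count`, `freq`, carrying an
#'   `n_copies` attribute (data frame `locus`, `group`, `n_copies`).
#'   Frequencies sum to one within each (locus, group).
#' @export
#' @examples
#' ds <- genotype_dataset(c("a", "b"), c("P", "P"), c("wild", "wild"), "L1",
#'                        matrix(c(100L, 100L)), matrix(c(100L, 102L)))
#' allele_frequencies(ds)
allele_frequencies <- function(ds, grouping = "pooled") {
  g <- .resolve_grouping(ds, grouping)
  rows <- list()
  copies <- list()
  for (loc in ds$loci) {
    x1 <- ds$a1[, loc]
    x2 <- ds$a2[, loc]
    for (lev in levels(g)) {
      sel <- g == lev & !is.na(x1)
      nc <- 2L * sum(sel)
      if (nc == 0L) next
      tab <- table(c(x1[sel], x2[sel]))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, group = lev,
        allele = as.integer(names(tab)),
        count = as.integer(tab),
        freq = as.numeric(tab) / nc,
        stringsAsFactors = FALSE
      )
      copies[[length(copies) + 1L]] <- data.frame(
        locus = loc, group = lev, n_copies = nc, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no non-missing genotypes in data set")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_copies") <- do.call(rbind, copies)
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

# Frequency vector for one (locus, group) from an allele_freq_table.
.freq_vector <- function(ft, locus, group = NULL) {
  sel <- ft$locus == locus
  if (!is.null(group)) sel <- sel & ft$group == group
  setNames(ft$freq[sel], ft$allele[sel])
}
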