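#' Evanno delta-K model selection
#'
#' Post-processes replicate log-probability values from external
#' Bayesian clustering runs (e.g. STRUCTURE) to choose the number of
#' clusters K. Reports per K the replicate mean and SD of lnP, the
#' first difference `L'(K)`, the absolute second difference `|L''(K)|`
#' of the means, and
#' \deqn{\Delta K = |L(K+1) - 2 L(K) + L(K-1)| / SD(L(K)).}
#' Mean lnP per K (the "plot the average log probability" criterion) is
#' reported alongside. Delta-K is undefined at the boundary K values and
#' wherever the replicate SD is zero.
#'
#' @param lnp_table data frame with columns `K`, `rep`, `lnp` (at least
#'   3 consecutive K values, >= 2 replicates each).
#' @return data frame `K`, `n_rep`, `mean_lnp`, `sd_lnp`, `lprime`,
#'   `lsecond`, `delta_k`.
#' @export
#' @examples
#' tab <- expand.grid(K = 1:3, rep = 1:3)
#' tab$lnp <- c(-100, -100, -100, -80, -82, -78, -78, -78, -78)
#' evanno_delta_k(tab)
evanno_delta_k <- function(lnp_table) {
  need <- c("K", "rep", "lnp")
  if (!all(need %in% names(lnp_table))) {
    stop("lnp_table needs columns K, rep, lnp")
  }
  ks <- sort(unique(lnp_table$K))
  if (length(ks) < 3) stop("need lnP for at least 3 K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  n_rep <- vapply(ks, function(k) sum(lnp_table$K == k), integer(1))
  if (any(n_rep < 2)) {
    stop("need >= 2 replicates per K (SD undefined otherwise)")
  }
  mu <- vapply(ks, function(k) mean(lnp_table$lnp[lnp_table$K == k]),
               numeric(1))
  s <- vapply(ks, function(k) sd(lnp_table$lnp[lnp_table$K == k]),
              numeric(1))
  m <- length(ks)
  lprime <- c(NA, diff(mu))
  lsecond <- rep(NA_real_, m)
  delta_k <- rep(NA_real_, m)
  for (i in seq(2, m - 1)) {
    lsecond[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1])
    delta_k[i] <- if (s[i] > 0) lsecond[i] / s[i] else NA_real_
  }
  data.frame(K = ks, n_rep = n_rep, mean_lnp = mu, sd_lnp = s,
             lprime = lprime, lsecond = lsecond, delta_k = delta_k)
}

#' TreeMix microsatellite input export
#'
#' Summarises each (group, locus) as the mean and sample (n-1) standard
#' deviation of all non-missing allele lengths (two per typed
#' individual), the per-group summary TreeMix expects for
#' microsatellite data. The file layout is a header line of group
#' names followed by one row per locus of comma-joined `mean,sd` cells,
#' space-separated across groups; a leading `#` comment records the SD
#' convention. Cells with fewer than two gene copies have an undefined
#' SD and are written as `NA,NA`.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()] (typically a gene-pool
#'   level grouping decided from clustering output).
#' @param path output file path, or `NULL` to skip writing.
#' @return data frame `group`, `locus`, `mean_bp`, `sd_bp`, `n_copies`,
#'   invisibly carrying `path` as an attribute when written.
#' @export
treemix_microsat_export <- function(ds, grouping = "gene_pool",
                                    path = NULL) {
  gfac <- .resolve_grouping(ds, grouping)
  rows <- list()
  for (lev in levels(gfac)) {
    for (loc in ds$loci) {
      x <- c(ds$a1[gfac == lev, loc], ds$a2[gfac == lev, loc])
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, locus = loc,
        mean_bp = if (length(x)) mean(x) else NA_real_,
        sd_bp = if (length(x) >= 2) sd(x) else NA_real_,
        n_copies = length(x), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# microsatellite summary: mean,sd of allele length (bp); sd uses n-1", con)
    writeLines(paste(levels(gfac), collapse = " "), con)
    for (loc in ds$loci) {
      cells <- vapply(levels(gfac), function(lev) {
        r <- tab[tab$group == lev & tab$locus == loc, ]
        if (is.na(r$sd_bp)) "NA,NA" else
          sprintf("%.6g,%.6g", r$mean_bp, r$sd_bp)
      }, character(1))
      writeLines(paste(cells, collapse = " "), con)
    }
    attr(tab, "path") <- path
  }
  tab
}

#' Re-read a TreeMix microsatellite export
#'
#' Parser for the layout written by [treemix_microsat_export()], for
#' verification and round-trip checks. Locus names are not stored in
#' the file; they are returned as `locus_1..locus_L` unless supplied.
#'
#' @param path file path.
#' @param loci optional locus names in row order.
#' @return data frame `group`, `locus`, `mean_bp`, `sd_bp`.
#' @export
read_treemix_microsat <- function(path, loci = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  groups <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  if (is.null(loci)) loci <- sprintf("locus_%d", seq_along(body))
  rows <- list()
  for (i in seq_along(body)) {
    cells <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(cells) != length(groups)) {
      stop("row ", i, " has ", length(cells), " cells for ",
           length(groups), " groups")
    }
    for (j in seq_along(groups)) {
      v <- suppressWarnings(as.numeric(strsplit(cells[j], ",")[[1]]))
      rows[[length(rows) + 1L]] <- data.frame(
        group = groups[j], locus = loci[i], mean_bp = v[1], sd_bp = v[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive group labels from a cluster-membership matrix
#'
#' Applies the usual majority rule to the membership proportions of an
#' external clustering run: an individual is assigned to `cluster` when
#' its membership there is at least `threshold`, otherwise to the
#' `fallback` label (e.g. an "admixed" catch-all group).
#'
#' @param membership data frame with column `ind` plus one numeric
#'   column per cluster (rows summing to 1).
#' @param cluster column name of the focal cluster.
#' @param threshold membership cut-off (default 0.5).
#' @param fallback label for individuals below the cut-off.
#' @return named character vector of group labels by individual.
#' @export
membership_groups <- function(membership, cluster, threshold = 0.5,
                              fallback = "other") {
  if (!"ind" %in% names(membership)) stop("membership needs an 'ind' column")
  if (!cluster %in% names(membership)) {
    stop("no membership column '", cluster, "'")
  }
  lab <- ifelse(membership[[cluster]] >= threshold, cluster, fallback)
  setNames(lab, membership$ind)
}
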