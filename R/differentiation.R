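# Per-locus Nei-Chesser corrected within- and total gene diversities.
# Returns NULL when fewer than 2 groups have data at the locus.
.hs_ht_locus <- function(ds, gfac, locus, correction = "nei_chesser") {
  x1 <- ds$a1[, locus]; x2 <- ds$a2[, locus]
  levs <- levels(gfac)
  ps <- list(); ns <- numeric(); hos <- numeric()
  alleles <- sort(unique(c(x1, x2)))
  alleles <- alleles[!is.na(alleles)]
  for (lev in levs) {
    sel <- gfac == lev & !is.na(x1)
    n <- sum(sel)
    if (n == 0) next
    cnt <- table(factor(c(x1[sel], x2[sel]), levels = alleles))
    ps[[lev]] <- as.numeric(cnt) / (2 * n)
    ns <- c(ns, n)
    hos <- c(hos, mean(x1[sel] != x2[sel]))
  }
  k <- length(ps)
  if (k < 2) return(NULL)
  P <- do.call(cbind, ps)                      # alleles x groups
  hs_raw <- 1 - mean(colSums(P^2))
  pbar <- rowMeans(P)
  ht_raw <- 1 - sum(pbar^2)
  if (correction == "none") {
    return(list(hs = hs_raw, ht = ht_raw, k = k))
  }
  ntilde <- k / sum(1 / ns)                    # harmonic mean sample size
  ho_bar <- mean(hos)
  hs <- ntilde / (ntilde - 1) * (hs_raw - ho_bar / (2 * ntilde))
  ht <- ht_raw + hs / (ntilde * k) - ho_bar / (2 * ntilde * k)
  list(hs = hs, ht = ht, k = k)
}

.diff_value <- function(ds, gfac, statistic, correction,
                        d_multilocus = "mean") {
  per <- lapply(ds$loci, function(loc)
    .hs_ht_locus(ds, gfac, loc, correction))
  keep <- !vapply(per, is.null, logical(1))
  per <- per[keep]
  if (!length(per)) stop("no locus with data in >= 2 groups")
  hs <- vapply(per, `[[`, numeric(1), "hs")
  ht <- vapply(per, `[[`, numeric(1), "ht")
  k <- per[[1]]$k
  per_locus <- switch(statistic,
    gst = ifelse(ht > 0, (ht - hs) / ht, NA_real_),
    gppst = ifelse(hs < 1 & ht > 0,
                   k * (ht - hs) / ((k * ht - hs) * (1 - hs)), NA_real_),
    d = ifelse(hs < 1, (k / (k - 1)) * (ht - hs) / (1 - hs), NA_real_))
  value <- switch(statistic,
    gst = {
      if (sum(ht) <= 0) stop("total gene diversity is zero; GST undefined")
      (sum(ht) - sum(hs)) / sum(ht)           # summed components
    },
    gppst = {
      mhs <- mean(hs); mht <- mean(ht)
      if (mhs >= 1) stop("Hs = 1; G''ST undefined")
      k * (mht - mhs) / ((k * mht - mhs) * (1 - mhs))
    },
    d = {
      v <- per_locus[!is.na(per_locus)]
      if (!length(v)) stop("Jost's D undefined at every locus")
      if (d_multilocus == "harmonic") {
        if (any(v <= 0)) mean(v) else 1 / mean(1 / v)
      } else mean(v)
    })
  list(value = value, per_locus = setNames(per_locus, ds$loci[keep]), k = k)
}

.diff_stat_name <- c(gst = "GST", gppst = "G''ST", d = "Jost's D")

#' Among-group differentiation statistics
#'
#' Nei's GST, the standardised G''ST (Meirmans-Hedrick) and Jost's D,
#' computed per locus from within-group (`Hs`) and total (`Ht`) gene
#' diversities with Nei-Chesser small-sample corrections:
#' \deqn{Hs = \tilde n/(\tilde n - 1) [1 - \overline{\sum_a p_{sa}^2}
#'   - \bar H_o / (2\tilde n)]}
#' \deqn{Ht = 1 - \sum_a \bar p_a^2 + Hs/(\tilde n k)
#'   - \bar H_o/(2 \tilde n k)}
#' where \eqn{\tilde n} is the harmonic mean sample size and `k` the
#' number of groups. Then per locus GST = (Ht - Hs)/Ht,
#' G''ST = k(Ht - Hs)/\[(kHt - Hs)(1 - Hs)\] and
#' D = (k/(k-1)) (Ht - Hs)/(1 - Hs). The multilocus GST and G''ST
#' aggregate the summed (respectively averaged) Hs/Ht components; the
#' multilocus D averages per-locus D (harmonic-mean option available).
#' G''ST and D rescale GST's dependence on within-group diversity, which
#' keeps GST numerically small for hyper-variable markers even when
#' groups share few alleles.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping as in [allele_frequencies()]; needs >= 2 groups.
#' @param statistic `"gst"`, `"gppst"` or `"d"`.
#' @param correction `"nei_chesser"` (default) or `"none"` (raw plug-in
#'   diversities; useful for closed-form checks).
#' @param n_perm if > 0, a permutation p-value is attached (see
#'   [permutation_test()]).
#' @param seed RNG seed for the permutation test.
#' @param d_multilocus `"mean"` or `"harmonic"` aggregation for D.
#' @return An object of class `diff_result`: list with `statistic`,
#'   `value`, `per_locus`, `k`, `groups`, and optionally `p_value`,
#'   `n_perm`.
#' @export
#' @examples
#' cfg <- sim_config(n_pops = 3, n_per_pop = 15, n_loci = 4,
#'                   n_cultivars = 0, clone_pairs = 0, seed = 7)
#' ds <- simulate_ssr_dataset(cfg)
#' differentiation(ds, "population", "gst")$value
differentiation <- function(ds, grouping = "population",
                            statistic = c("gst", "gppst", "d"),
                            correction = c("nei_chesser", "none"),
                            n_perm = 0, seed = 1L,
                            d_multilocus = c("mean", "harmonic")) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  d_multilocus <- match.arg(d_multilocus)
  gfac <- .resolve_grouping(ds, grouping)
  if (nlevels(gfac) < 2) stop("need >= 2 groups")
  res <- .diff_value(ds, gfac, statistic, correction, d_multilocus)
  out <- list(statistic = .diff_stat_name[[statistic]], value = res$value,
              per_locus = res$per_locus, k = res$k,
              groups = levels(gfac))
  if (n_perm > 0) {
    pt <- permutation_test(ds, grouping, statistic, n_perm = n_perm,
                           seed = seed, correction = correction,
                           d_multilocus = d_multilocus)
    out$p_value <- pt$p_value
    out$n_perm <- n_perm
  }
  class(out) <- "diff_result"
  out
}

#' @export
print.diff_result <- function(x, ...) {
  cat(x$statistic, "=", signif(x$value, 4))
  if (!is.null(x$p_value)) cat(", p =", signif(x$p_value, 3))
  cat(" (", x$k, " groups)\n", sep = "")
  invisible(x)
}

#' Pairwise differentiation matrix
#'
#' The statistic computed for every unordered pair of groups.
#'
#' @inheritParams differentiation
#' @return symmetric numeric matrix with `NA` diagonal; if `n_perm > 0`,
#'   attribute `p_values` holds the matching matrix of p-values.
#' @export
pairwise_differentiation <- function(ds, grouping = "population",
                                     statistic = c("gst", "gppst", "d"),
                                     correction = c("nei_chesser", "none"),
                                     n_perm = 0, seed = 1L) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  gfac <- .resolve_grouping(ds, grouping)
  levs <- levels(gfac)
  if (length(levs) < 3) stop("pairwise matrix needs >= 3 groups")
  m <- matrix(NA_real_, length(levs), length(levs),
              dimnames = list(levs, levs))
  pm <- m
  for (i in seq_along(levs)[-length(levs)]) {
    for (j in seq((i + 1), length(levs))) {
      keep <- gfac %in% levs[c(i, j)]
      sub <- subset(ds, individuals = ds$ind[keep])
      gsub <- setNames(as.character(gfac)[keep], ds$ind[keep])
      r <- tryCatch(
        differentiation(sub, gsub, statistic, correction,
                        n_perm = n_perm, seed = seed),
        error = function(e) NULL)
      if (!is.null(r)) {
        m[i, j] <- m[j, i] <- r$value
        if (n_perm > 0) pm[i, j] <- pm[j, i] <- r$p_value
      }
    }
  }
  if (n_perm > 0) attr(m, "p_values") <- pm
  m
}

#' Permutation test for differentiation
#'
#' Permutes whole multilocus individuals among groups (group sizes
#' preserved, within-individual genotype structure intact) and
#' recomputes the statistic; `p = (1 + #perm >= observed)/(1 + n_perm)`.
#'
#' @inheritParams differentiation
#' @param n_perm number of permutations (>= 99).
#' @return list `p_value`, `observed`, `n_perm`, `perm_values`.
#' @export
permutation_test <- function(ds, grouping = "population",
                             statistic = c("gst", "gppst", "d"),
                             n_perm = 999, seed = 1L,
                             correction = c("nei_chesser", "none"),
                             d_multilocus = c("mean", "harmonic")) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  d_multilocus <- match.arg(d_multilocus)
  if (n_perm < 99) stop("n_perm must be >= 99")
  gfac <- .resolve_grouping(ds, grouping)
  if (nlevels(gfac) < 2 || min(table(gfac)) < 1) {
    stop("degenerate grouping")
  }
  obs <- .diff_value(ds, gfac, statistic, correction, d_multilocus)$value
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    gb <- factor(sample(as.character(gfac)), levels = levels(gfac))
    .diff_value(ds, gb, statistic, correction, d_multilocus)$value
  }, numeric(1))
  list(p_value = (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm),
       observed = obs, n_perm = n_perm, perm_values = perm)
}
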