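.check_freqs <- function(p) {
  if (!length(p)) stop("empty frequency vector")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("frequencies must be non-negative and sum to 1")
  }
}

#' Probability of identity of a locus
#'
#' Probability that two unrelated individuals drawn from a
#' Hardy-Weinberg population share a genotype at this locus:
#' \deqn{PID = 2 (\sum_i p_i^2)^2 - \sum_i p_i^4.}
#'
#' @param p numeric vector of allele frequencies (sums to 1).
#' @return a probability in (0, 1].
#' @export
#' @examples
#' pid_locus(c(0.5, 0.5))  # 0.375
pid_locus <- function(p) {
  .check_freqs(p)
  2 * sum(p^2)^2 - sum(p^4)
}

#' Probability of identity between full siblings
#'
#' The sibling variant is the conservative upper bound used when
#' relatives may be present in a sample:
#' \deqn{PID_{sibs} = 0.25 + 0.5 \sum p_i^2 + 0.5 (\sum p_i^2)^2
#'   - 0.25 \sum p_i^4.}
#'
#' @inheritParams pid_locus
#' @return a probability in (0, 1]; always at least [pid_locus()].
#' @export
pidsibs_locus <- function(p) {
  .check_freqs(p)
  0.25 + 0.5 * sum(p^2) + 0.5 * sum(p^2)^2 - 0.25 * sum(p^4)
}

#' Polymorphic information content of a locus
#'
#' Botstein's PIC:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2.}
#'
#' @inheritParams pid_locus
#' @return a value in \[0, 1).
#' @export
pic_locus <- function(p) {
  .check_freqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Combine per-locus identity probabilities across independent loci
#'
#' @param per_locus_values numeric vector of per-locus probabilities in
#'   (0, 1].
#' @return their product (the multilocus probability).
#' @export
combine_loci <- function(per_locus_values) {
  if (!length(per_locus_values)) stop("no per-locus values supplied")
  if (any(per_locus_values <= 0 | per_locus_values > 1)) {
    stop("per-locus probabilities must be in (0, 1]")
  }
  prod(per_locus_values)
}

#' Overall identity statistics of a data set
#'
#' Computes per-locus PID, PIDsibs and PIC from pooled allele
#' frequencies (all individuals, or a supplied subset convention applied
#' upstream), and the multilocus products.
#'
#' @param ds a [genotype_dataset()].
#' @return list with `per_locus` (data frame `locus`, `pid`, `pidsibs`,
#'   `pic`) and `overall` (named vector `pid`, `pidsibs`).
#' @export
identity_summary <- function(ds) {
  ft <- allele_frequencies(ds, "pooled")
  per <- do.call(rbind, lapply(ds$loci, function(loc) {
    p <- .freq_vector(ft, loc, "all")
    data.frame(locus = loc, pid = pid_locus(p), pidsibs = pidsibs_locus(p),
               pic = pic_locus(p), stringsAsFactors = FALSE)
  }))
  list(per_locus = per,
       overall = c(pid = combine_loci(per$pid),
                   pidsibs = combine_loci(per$pidsibs)))
}

#' Locus-resampling power curves
#'
#' Assesses how many loci are needed for individual discrimination by
#' sampling loci with replacement: for each panel size `k` in
#' `1..(L-1)`, `reps` random draws of `k` loci are taken (a locus may
#' repeat within a draw, and then its factor repeats in the product) and
#' the statistic is recomputed — multilocus PID or PIDsibs from pooled
#' frequencies, or the number of distinct MLGs detected with the drawn
#' panel (distance threshold 0).
#'
#' @param ds a [genotype_dataset()].
#' @param statistic `"pid"`, `"pidsibs"` or `"n_mlgs"`.
#' @param reps replicates per panel size.
#' @param seed RNG seed (recorded in the result).
#' @param k_values panel sizes; default `1:(n_loci(ds) - 1)`.
#' @return An object of class `resampling_curve`: a long data frame
#'   (`k`, `rep`, `value`) with attributes `statistic`, `seed` and
#'   `summary` (per-`k` median and quartiles).
#' @export
resample_loci <- function(ds, statistic = c("pid", "pidsibs", "n_mlgs"),
                          reps = 1000, seed = 1L, k_values = NULL) {
  statistic <- match.arg(statistic)
  if (reps < 1) stop("reps must be >= 1")
  L <- n_loci(ds)
  if (is.null(k_values)) k_values <- seq_len(max(L - 1L, 1L))
  if (reps * L * max(k_values) > 5e7) {
    stop("resampling workload too large; reduce reps or panel sizes")
  }
  set.seed(seed)
  per_locus <- if (statistic != "n_mlgs") {
    ft <- allele_frequencies(ds, "pooled")
    vapply(ds$loci, function(loc) {
      p <- .freq_vector(ft, loc, "all")
      if (statistic == "pid") pid_locus(p) else pidsibs_locus(p)
    }, numeric(1))
  }
  rows <- vector("list", length(k_values) * reps)
  i <- 0L
  for (k in k_values) {
    for (r in seq_len(reps)) {
      draw <- sample(L, k, replace = TRUE)
      val <- if (statistic == "n_mlgs") {
        .n_strict_mlgs(ds, draw)
      } else {
        prod(per_locus[draw])
      }
      i <- i + 1L
      rows[[i]] <- c(k, r, val)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("k", "rep", "value")
  summ <- do.call(rbind, lapply(k_values, function(k) {
    v <- out$value[out$k == k]
    data.frame(k = k, q25 = quantile(v, 0.25), median = stats::median(v),
               q75 = quantile(v, 0.75), row.names = NULL)
  }))
  attr(out, "statistic") <- statistic
  attr(out, "seed") <- seed
  attr(out, "summary") <- summ
  class(out) <- c("resampling_curve", "data.frame")
  out
}

# strict-MLG count on a multiset of locus indices: individuals with any
# missing drawn locus form their own class only if their visible string
# is unique; we key on the genotype string with NA kept explicit.
.n_strict_mlgs <- function(ds, loci_idx) {
  key <- apply(cbind(ds$a1[, loci_idx, drop = FALSE],
                     ds$a2[, loci_idx, drop = FALSE]), 1,
               paste, collapse = "/")
  length(unique(key))
}
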