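#' One-hot allele-dosage encoding
#'
#' Encodes genotypes as an individuals x (locus, allele) count matrix
#' (0/1/2 copies). Missing cells are filled with the column means of
#' that locus's columns (the observed mean dosage), with the imputed
#' rows recorded.
#'
#' @param ds a [genotype_dataset()].
#' @param loci optional subset of loci to encode.
#' @return numeric matrix with rownames `ds$ind` and colnames
#'   `<locus>.<allele>`; attribute `imputed` is a logical
#'   individuals x loci matrix.
#' @export
encode_genotypes <- function(ds, loci = NULL) {
  if (is.null(loci)) loci <- ds$loci
  blocks <- list()
  imputed <- matrix(FALSE, n_ind(ds), length(loci),
                    dimnames = list(ds$ind, loci))
  for (loc in loci) {
    x1 <- ds$a1[, loc]; x2 <- ds$a2[, loc]
    alleles <- sort(unique(c(x1, x2)))
    alleles <- alleles[!is.na(alleles)]
    m <- matrix(0, n_ind(ds), length(alleles),
                dimnames = list(ds$ind, paste0(loc, ".", alleles)))
    for (a in seq_along(alleles)) {
      m[, a] <- (x1 == alleles[a]) + (x2 == alleles[a])
    }
    miss <- is.na(x1)
    if (any(miss) && any(!miss)) {
      m[miss, ] <- matrix(colMeans(m[!miss, , drop = FALSE]),
                          sum(miss), length(alleles), byrow = TRUE)
    } else if (all(miss)) {
      m[miss, ] <- 0
    }
    imputed[, loc] <- miss
    blocks[[loc]] <- m
  }
  out <- do.call(cbind, blocks)
  attr(out, "imputed") <- imputed
  out
}

#' Draw a balanced training subset
#'
#' Equal-size random subsample per group, the standard guard against
#' unequal group sizes biasing an assignment test.
#'
#' @param ds a [genotype_dataset()].
#' @param groups group label per individual (or a grouping spec as in
#'   [allele_frequencies()]).
#' @param per_group_n individuals drawn per group.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return character vector of training individual IDs.
#' @export
balance_training <- function(ds, groups = "population", per_group_n,
                             seed = NULL) {
  gfac <- .resolve_grouping(ds, groups)
  sizes <- table(gfac)
  if (per_group_n > min(sizes)) {
    stop("per_group_n exceeds the smallest group; sizes: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(levels(gfac), function(lev) {
    sample(ds$ind[gfac == lev], per_group_n)
  }), use.names = FALSE)
}

# ---- classifiers -----------------------------------------------------

# Allele-frequency likelihood classifier: training frequencies per
# (group, locus); unseen alleles get pseudo-frequency 1/(2N) of that
# group-locus sample. Genotype probability under HWE; log-likelihood
# summed over non-missing loci.
.fit_freq_classifier <- function(ds, train_ids, gfac, loci) {
  idx <- match(train_ids, ds$ind)
  groups <- levels(gfac)
  fit <- list()
  for (g in groups) {
    rows <- idx[as.character(gfac[idx]) == g]
    per_locus <- list()
    for (loc in loci) {
      x1 <- ds$a1[rows, loc]; x2 <- ds$a2[rows, loc]
      ok <- !is.na(x1)
      n <- sum(ok)
      tab <- table(c(x1[ok], x2[ok]))
      per_locus[[loc]] <- list(
        freq = setNames(as.numeric(tab) / max(2 * n, 1), names(tab)),
        pseudo = 1 / max(2 * n, 1))
    }
    fit[[g]] <- per_locus
  }
  structure(list(fit = fit, loci = loci, groups = groups),
            class = "freq_classifier")
}

.predict_freq_classifier <- function(model, ds, test_ids) {
  idx <- match(test_ids, ds$ind)
  lookup <- function(fr, a) {
    v <- fr$freq[as.character(a)]
    ifelse(is.na(v), fr$pseudo, v)
  }
  pred <- character(length(idx))
  for (i in seq_along(idx)) {
    ll <- setNames(numeric(length(model$groups)), model$groups)
    for (g in model$groups) {
      tot <- 0
      for (loc in model$loci) {
        a1 <- ds$a1[idx[i], loc]; a2 <- ds$a2[idx[i], loc]
        if (is.na(a1)) next
        fr <- model$fit[[g]][[loc]]
        p1 <- lookup(fr, a1); p2 <- lookup(fr, a2)
        tot <- tot + if (a1 == a2) log(p1 * p2) else log(2 * p1 * p2)
      }
      ll[g] <- tot
    }
    pred[i] <- names(which.max(ll))
  }
  pred
}

# Nearest-centroid in PCA space: axes fitted on training encodings only
# (explaining >= var_target of variance, capped at max_axes).
.fit_pca_classifier <- function(ds, train_ids, gfac, loci,
                                var_target = 0.8, max_axes = 20) {
  enc <- encode_genotypes(ds, loci)
  tr <- enc[train_ids, , drop = FALSE]
  keep <- apply(tr, 2, function(v) stats::var(v) > 0)
  tr <- tr[, keep, drop = FALSE]
  pc <- prcomp(tr, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_axes <- min(max(which(cum >= var_target)[1], 1L), max_axes,
                ncol(pc$x))
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  gtr <- as.character(gfac[match(train_ids, ds$ind)])
  centroids <- do.call(rbind, lapply(unique(gtr), function(g) {
    colMeans(scores[gtr == g, , drop = FALSE])
  }))
  rownames(centroids) <- unique(gtr)
  structure(list(pc = pc, keep = keep, n_axes = n_axes,
                 centroids = centroids, loci = loci, enc = enc),
            class = "pca_classifier")
}

.predict_pca_classifier <- function(model, ds, test_ids) {
  te <- model$enc[test_ids, model$keep, drop = FALSE]
  sc <- predict(model$pc, te)[, seq_len(model$n_axes), drop = FALSE]
  pred <- character(length(test_ids))
  for (i in seq_along(test_ids)) {
    d2 <- rowSums((model$centroids -
                     matrix(sc[i, ], nrow(model$centroids),
                            ncol(sc), byrow = TRUE))^2)
    pred[i] <- rownames(model$centroids)[which.min(d2)]
  }
  pred
}

#' Monte-Carlo cross-validated assignment test
#'
#' For each combination of training proportion, panel size and
#' iteration: draw a balanced training set (per-group size =
#' `floor(prop * smallest group)`), draw that many loci at random
#' (without replacement, redrawn each iteration), fit the classifier on
#' the training individuals only, classify the held-out individuals and
#' record per-group correct-assignment rates. Held-out individuals never
#' influence training frequencies or PCA axes.
#'
#' The default classifier assigns each individual to the group
#' maximising the product over loci of its HWE genotype probability
#' under the group's training allele frequencies, with a pseudo-count
#' frequency of `1/(2N)` for alleles unseen in training (avoiding
#' `-Inf` log-likelihoods). `"nearest_centroid_pca"` instead classifies
#' by nearest group centroid in a PCA of the allele-dosage encoding
#' (axes explaining 80% variance, at most 20).
#'
#' @param ds a [genotype_dataset()].
#' @param groups grouping spec as in [allele_frequencies()].
#' @param train_props numeric vector of training proportions.
#' @param loci_counts integer vector of panel sizes.
#' @param iterations Monte-Carlo iterations per combination.
#' @param classifier `"frequency_likelihood"` or
#'   `"nearest_centroid_pca"`.
#' @param seed RNG seed.
#' @return An object of class `assignment_result`: a long data frame
#'   (`train_prop`, `n_loci`, `iteration`, `group`, `n_test`,
#'   `accuracy`) with attributes `classifier`, `seed` and `summary`
#'   (mean accuracy per `train_prop` x `n_loci` x `group`).
#' @export
cross_validate <- function(ds, groups = "population",
                           train_props = c(0.5, 0.7, 0.9),
                           loci_counts = NULL, iterations = 100,
                           classifier = c("frequency_likelihood",
                                          "nearest_centroid_pca"),
                           seed = 1L) {
  classifier <- match.arg(classifier)
  if (iterations < 1) stop("iterations must be >= 1")
  gfac <- .resolve_grouping(ds, groups)
  if (nlevels(gfac) < 2) stop("need >= 2 groups")
  if (is.null(loci_counts)) loci_counts <- n_loci(ds)
  if (any(loci_counts < 1 | loci_counts > n_loci(ds))) {
    stop("loci_counts must be between 1 and the panel size")
  }
  min_size <- min(table(gfac))
  set.seed(seed)
  rows <- list()
  for (prop in train_props) {
    n_tr <- max(1L, floor(prop * min_size))
    if (n_tr >= min_size) n_tr <- min_size - 1L
    if (n_tr < 1L) stop("smallest group too small for a held-out set")
    for (L in loci_counts) {
      for (it in seq_len(iterations)) {
        loci <- sample(ds$loci, L)
        train <- balance_training(ds, gfac, n_tr)
        test <- setdiff(ds$ind, train)
        truth <- as.character(gfac[match(test, ds$ind)])
        pred <- if (classifier == "frequency_likelihood") {
          model <- .fit_freq_classifier(ds, train, gfac, loci)
          .predict_freq_classifier(model, ds, test)
        } else {
          model <- .fit_pca_classifier(ds, train, gfac, loci)
          .predict_pca_classifier(model, ds, test)
        }
        for (g in levels(gfac)) {
          sel <- truth == g
          rows[[length(rows) + 1L]] <- data.frame(
            train_prop = prop, n_loci = L, iteration = it, group = g,
            n_test = sum(sel),
            accuracy = if (any(sel)) mean(pred[sel] == g) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- stats::aggregate(accuracy ~ train_prop + n_loci + group,
                           data = out, FUN = mean)
  attr(out, "classifier") <- classifier
  attr(out, "seed") <- seed
  attr(out, "summary") <- summ
  class(out) <- c("assignment_result", "data.frame")
  out
}
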