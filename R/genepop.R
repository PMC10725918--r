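#' Read a GENEPOP file
#'
#' Parses the classical GENEPOP dialect: a title line, one locus name per
#' line (or a single comma-separated line), then `Pop` blocks of
#' `individual , 100102 090090 ...` rows. Two- and three-digit allele
#' coding is auto-detected from token width; `000`/`00` codes mark a
#' missing allele. Both alleles of a cell must be present or absent:
#' a half-coded cell (one allele `000`) is rejected.
#'
#' GENEPOP carries no gene-pool annotation, so all individuals are
#' labelled with `gene_pool` (default `"wild"`); use
#' [subset.genotype_dataset()] or assemble via [genotype_dataset()] for
#' mixed panels. Population labels default to the ID of each block's last
#' individual (the GENEPOP convention) unless `pop_names` is supplied.
#'
#' @param path file path.
#' @param gene_pool single gene-pool label applied to all individuals.
#' @param pop_names optional character vector naming the `Pop` blocks in
#'   file order.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, gene_pool = "wild", pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("GENEPOP parse error: file too short")
  body <- lines[-1]  # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) {
    stop("GENEPOP parse error: no 'Pop' line found (line ",
         length(lines), " reached)")
  }
  loc_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GENEPOP parse error: no locus names before 'Pop'")

  ind <- character(); popid <- integer(); geno <- list()
  block <- 0L
  for (i in seq(first_pop, length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      block <- block + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) {
      stop("GENEPOP parse error at line ", i + 1L,
           ": expected 'id , alleles'")
    }
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != length(loci)) {
      stop("GENEPOP format error at line ", i + 1L, ": ", length(toks),
           " genotype tokens for ", length(loci), " loci")
    }
    ind <- c(ind, id)
    popid <- c(popid, block)
    geno[[length(geno) + 1L]] <- toks
  }
  if (!length(ind)) stop("GENEPOP parse error: no individuals")
  if (anyDuplicated(ind)) {
    stop("validation error: duplicate individual IDs: ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "))
  }

  widths <- unique(nchar(unlist(geno)))
  if (length(widths) != 1 || !(widths %in% c(4L, 6L))) {
    stop("GENEPOP format error: genotype tokens must be uniformly 4 ",
         "(2-digit) or 6 (3-digit) characters wide; saw widths ",
         paste(widths, collapse = ", "))
  }
  w <- widths / 2L

  n <- length(ind)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_len(n)) {
    toks <- geno[[j]]
    x1 <- as.integer(substr(toks, 1L, w))
    x2 <- as.integer(substr(toks, w + 1L, 2L * w))
    half <- xor(x1 == 0L, x2 == 0L)
    if (any(half)) {
      stop("GENEPOP format error: half-missing genotype for individual '",
           ind[j], "' at locus ", loci[which(half)[1]])
    }
    x1[x1 == 0L] <- NA_integer_
    x2[x2 == 0L] <- NA_integer_
    a1[j, ] <- x1
    a2[j, ] <- x2
  }

  if (is.null(pop_names)) {
    pop_names <- vapply(seq_len(max(popid)), function(b) {
      ind[max(which(popid == b))]
    }, character(1))
  }
  if (length(pop_names) < max(popid)) {
    stop("'pop_names' must name all ", max(popid), " Pop blocks")
  }
  # offset map written by write_genepop() when alleles exceed 3 digits
  off <- .parse_offset_header(lines[1])
  if (!is.null(off)) {
    for (loc in names(off)) {
      k <- match(loc, loci)
      if (!is.na(k)) {
        a1[, k] <- a1[, k] + off[[loc]]
        a2[, k] <- a2[, k] + off[[loc]]
      }
    }
  }
  genotype_dataset(ind, pop_names[popid], rep(gene_pool, n), loci, a1, a2)
}

.parse_offset_header <- function(title) {
  m <- regmatches(title, regexpr("offsets\\{[^}]*\\}", title))
  if (!length(m)) return(NULL)
  body <- sub("offsets\\{", "", sub("\\}$", "", m))
  pairs <- strsplit(strsplit(body, ";")[[1]], "=")
  off <- lapply(pairs, function(p) as.integer(p[2]))
  names(off) <- vapply(pairs, `[[`, character(1), 1)
  off
}

#' Write a GENEPOP file
#'
#' Writes 3-digit allele coding by default. Loci whose allele lengths
#' exceed 999 are shifted by a per-locus offset (a multiple of 100) that
#' is recorded in the title line as `offsets{locus=o;...}` so that
#' [read_genepop()] restores the original lengths.
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "ssrpopgen export") {
  offsets <- list()
  a1 <- ds$a1; a2 <- ds$a2
  for (k in seq_along(ds$loci)) {
    mx <- suppressWarnings(max(a1[, k], a2[, k], na.rm = TRUE))
    if (is.finite(mx) && mx > 999L) {
      mn <- min(a1[, k], a2[, k], na.rm = TRUE)
      off <- (mn %/% 100L) * 100L - 100L  # keep codes positive, 3-digit
      offsets[[ds$loci[k]]] <- off
      a1[, k] <- a1[, k] - off
      a2[, k] <- a2[, k] - off
      if (max(a1[, k], a2[, k], na.rm = TRUE) > 999L) {
        stop("locus ", ds$loci[k], " spans more than 999 bp; cannot ",
             "encode in 3 digits")
      }
    }
  }
  if (length(offsets)) {
    title <- paste0(title, " offsets{",
                    paste(names(offsets), unlist(offsets), sep = "=",
                          collapse = ";"), "}")
  }
  code <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  pops <- unique(ds$pop)
  for (p in pops) {
    writeLines("Pop", con)
    for (j in which(ds$pop == p)) {
      writeLines(paste0(ds$ind[j], " , ",
                        paste0(code(a1[j, ]), code(a2[j, ]),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a wide genotype table (CSV/TSV)
#'
#' One row per individual; two columns per locus named `<locus>_1` and
#' `<locus>_2`; columns `id`, `population` and optionally `gene_pool`.
#' Blank cells or the `missing` sentinel mark missing data (both allele
#' columns of a cell must then be missing).
#'
#' @param path file path.
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @param missing missing-data sentinel in addition to the empty string
#'   and `NA` (e.g. `"0"`).
#' @return a [genotype_dataset()].
#' @export
read_wide_table <- function(path, sep = ",", missing = "NA") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  need <- c("id", "population")
  if (!all(need %in% names(df))) {
    stop("wide-table format error: need columns ",
         paste(need, collapse = ", "))
  }
  meta <- intersect(c("id", "population", "gene_pool"), names(df))
  acols <- setdiff(names(df), meta)
  base <- sub("_[12]$", "", acols)
  sfx <- sub("^.*_([12])$", "\\1", acols)
  bad <- !grepl("_[12]$", acols)
  if (any(bad)) {
    stop("wide-table format error: allele column(s) without _1/_2 ",
         "suffix: ", paste(acols[bad], collapse = ", "))
  }
  loci <- unique(base)
  for (loc in loci) {
    if (!all(paste0(loc, c("_1", "_2")) %in% acols)) {
      stop("wide-table format error: unpaired columns for locus ", loc)
    }
  }
  n <- nrow(df)
  decode <- function(v, col) {
    v <- trimws(v)
    v[v %in% c("", missing) | is.na(v)] <- NA
    out <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop("wide-table format error: non-integer allele '", v[bad[1]],
           "' at row ", bad[1], ", column ", col)
    }
    out
  }
  a1 <- sapply(loci, function(l) decode(df[[paste0(l, "_1")]],
                                        paste0(l, "_1")))
  a2 <- sapply(loci, function(l) decode(df[[paste0(l, "_2")]],
                                        paste0(l, "_2")))
  if (n == 1) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1) }
  gp <- if ("gene_pool" %in% names(df)) df$gene_pool else rep("wild", n)
  genotype_dataset(df$id, df$population, gp, loci, a1, a2)
}

#' Write a wide genotype table
#'
#' Inverse of [read_wide_table()]; columns are `id`, `population`,
#' `gene_pool`, then `<locus>_1`, `<locus>_2` in locus order.
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param sep field separator.
#' @param missing sentinel written into missing cells.
#' @return `path`, invisibly.
#' @export
write_wide_table <- function(ds, path, sep = ",", missing = "NA") {
  out <- data.frame(id = ds$ind, population = ds$pop,
                    gene_pool = ds$gene_pool, stringsAsFactors = FALSE,
                    check.names = FALSE)
  enc <- function(x) ifelse(is.na(x), missing, as.character(x))
  for (loc in ds$loci) {
    out[[paste0(loc, "_1")]] <- enc(ds$a1[, loc])
    out[[paste0(loc, "_2")]] <- enc(ds$a2[, loc])
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
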