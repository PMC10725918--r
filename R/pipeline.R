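#' Pipeline configuration
#'
#' Validates and normalises the settings of [run_pipeline()]. A config
#' can also be read from YAML (`pipeline_config_from_yaml()`); the
#' resolved config is serialised into the output directory so every run
#' is reproducible from its own provenance record.
#'
#' @param input path to a genotype file, or `NULL` to simulate from
#'   `sim` settings.
#' @param format `"genepop"` or `"wide"`.
#' @param out_dir output directory (created if needed).
#' @param drop_loci loci excluded before analysis.
#' @param drop_populations populations excluded from population-level
#'   stages.
#' @param clone_threshold integer distance threshold, or `"auto"` to
#'   read it off the distance histogram.
#' @param exclude_outgroup drop outgroup individuals from
#'   structure-facing stages (diversity, differentiation, identity).
#' @param rarefy_g rarefaction size (gene copies) or `NULL` for the
#'   per-locus minimum.
#' @param n_boot bootstrap replicates for FIS CIs.
#' @param n_perm permutations for differentiation tests.
#' @param resample_reps locus-resampling replicates (0 disables).
#' @param seed master seed for all stochastic stages.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, format = c("wide", "genepop"),
                            out_dir = "ssrpopgen_out",
                            drop_loci = character(),
                            drop_populations = character(),
                            clone_threshold = "auto",
                            exclude_outgroup = TRUE,
                            rarefy_g = NULL, n_boot = 1000, n_perm = 999,
                            resample_reps = 0, seed = 1L,
                            sim = sim_config()) {
  format <- match.arg(format)
  if (!identical(clone_threshold, "auto")) {
    clone_threshold <- as.integer(clone_threshold)
    if (is.na(clone_threshold) || clone_threshold < 0) {
      stop("config error: clone_threshold must be \"auto\" or >= 0")
    }
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("config error: input file not found: ", input)
  }
  if (n_boot < 100 || n_perm < 99) {
    stop("config error: n_boot >= 100 and n_perm >= 99 required")
  }
  structure(list(input = input, format = format, out_dir = out_dir,
                 drop_loci = drop_loci,
                 drop_populations = drop_populations,
                 clone_threshold = clone_threshold,
                 exclude_outgroup = isTRUE(exclude_outgroup),
                 rarefy_g = rarefy_g, n_boot = n_boot, n_perm = n_perm,
                 resample_reps = resample_reps, seed = as.integer(seed),
                 sim = sim),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with fields named as the arguments above
#'   (`sim` as a nested map of [sim_config()] arguments).
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

.write_tsv <- function(df, dir, name) {
  write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
              row.names = FALSE, quote = FALSE)
}

#' Run the full SSR analysis pipeline
#'
#' Chains the package stages in the canonical order: load (or simulate)
#' genotypes, drop excluded loci/populations, compute pairwise distances
#' and contract clonal multilocus genotypes, keep one representative per
#' contracted MLG, optionally drop the outgroup, then compute identity
#' statistics, per-population diversity (with FIS bootstrap CIs),
#' wild-vs-cultivar and pairwise population differentiation with
#' permutation p-values, the allele rarefaction curve, and the TreeMix
#' microsatellite export. Every stage result is written as TSV into
#' `out_dir` together with a JSON summary, the serialised config and a
#' log; the seed fully determines every number.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (invisibly also written to
#'   `config$out_dir`): `dataset`, `mlgs`, `synonymy`, `identity`,
#'   `diversity`, `fis`, `differentiation`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), "-", ..., "\n",
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("ssrpopgen", as.character(utils::packageVersion("ssrpopgen")),
       "seed", config$seed)
  stage <- function(name, expr) {
    logf("stage:", name)
    tryCatch(expr, error = function(e) {
      logf("FAILED at stage", name, ":", conditionMessage(e))
      stop("pipeline aborted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  ds <- stage("load", {
    if (is.null(config$input)) {
      simulate_ssr_dataset(config$sim)
    } else if (config$format == "genepop") {
      read_genepop(config$input)
    } else {
      read_wide_table(config$input)
    }
  })
  if (length(config$drop_loci)) {
    ds <- stage("drop_loci", subset(
      ds, loci = setdiff(ds$loci, config$drop_loci)))
  }

  clones <- stage("clones", {
    dm <- pairwise_distance(ds)
    hist <- distance_histogram(dm)
    thr <- if (identical(config$clone_threshold, "auto")) {
      suppressWarnings(suggest_threshold(hist))
    } else config$clone_threshold
    mlgs <- contract_mlgs(ds, thr, dm)
    list(dm = dm, hist = hist, threshold = thr, mlgs = mlgs,
         synonymy = synonymy_report(mlgs, ds))
  })
  .write_tsv(clones$hist, config$out_dir, "distance_histogram")
  .write_tsv(as.data.frame(clones$mlgs), config$out_dir, "mlg_membership")
  .write_tsv(clones$synonymy, config$out_dir, "synonymy_report")

  ds_dedup <- stage("deduplicate",
                    deduplicate_mlgs(ds, clones$mlgs))
  ds_pop <- ds_dedup
  if (config$exclude_outgroup && any(ds_pop$gene_pool == "outgroup")) {
    ds_pop <- subset(ds_pop, gene_pools = setdiff(
      unique(ds_pop$gene_pool), "outgroup"))
  }
  if (length(config$drop_populations)) {
    ds_pop <- subset(ds_pop, populations = setdiff(
      unique(ds_pop$pop), config$drop_populations))
  }

  idn <- stage("identity", identity_summary(ds_pop))
  .write_tsv(idn$per_locus, config$out_dir, "identity_per_locus")
  resamp <- NULL
  if (config$resample_reps > 0) {
    resamp <- stage("resample", resample_loci(
      ds_pop, "pid", reps = config$resample_reps, seed = config$seed))
    .write_tsv(as.data.frame(resamp), config$out_dir, "pid_resampling")
  }

  div <- stage("diversity", locus_summary(ds_pop, "population"))
  ar <- stage("allelic_richness",
              allelic_richness(ds_pop, "population", config$rarefy_g))
  fis <- stage("fis", fis_estimate(ds_pop, "population",
                                   n_boot = config$n_boot,
                                   seed = config$seed))
  .write_tsv(div, config$out_dir, "diversity_per_locus")
  .write_tsv(ar, config$out_dir, "allelic_richness")
  .write_tsv(fis, config$out_dir, "fis")

  has_pools <- length(unique(ds_pop$gene_pool)) >= 2
  diff_pool <- if (has_pools) {
    stage("differentiation_pools", differentiation(
      ds_pop, "gene_pool", "gst", n_perm = config$n_perm,
      seed = config$seed))
  }
  n_pops <- length(unique(ds_pop$pop))
  diff_pair <- if (n_pops >= 3) {
    stage("differentiation_pairwise", pairwise_differentiation(
      ds_pop, "population", "gst"))
  }
  if (!is.null(diff_pair)) {
    .write_tsv(cbind(group = rownames(diff_pair),
                     as.data.frame(diff_pair)),
               config$out_dir, "pairwise_gst")
  }

  rar <- stage("rarefaction_curve",
               allele_rarefaction_curve(ds_pop, "gene_pool"))
  .write_tsv(rar, config$out_dir, "rarefaction_curve")
  tm <- stage("treemix_export", treemix_microsat_export(
    ds_dedup, "gene_pool",
    file.path(config$out_dir, "treemix_microsat.txt")))

  summary <- list(
    n_individuals = n_ind(ds),
    n_loci = n_loci(ds),
    n_mlgs = length(unique(clones$mlgs$mlg)),
    clone_threshold = clones$threshold,
    n_contracted_mlgs = sum(attr(clones$mlgs, "contracted")),
    overall_pid = unname(idn$overall["pid"]),
    overall_pidsibs = unname(idn$overall["pidsibs"]),
    mean_fis = mean(fis$fis, na.rm = TRUE),
    gst_gene_pools = if (!is.null(diff_pool)) diff_pool$value,
    gst_gene_pools_p = if (!is.null(diff_pool)) diff_pool$p_value,
    max_pairwise_gst = if (!is.null(diff_pair))
      max(diff_pair, na.rm = TRUE),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_out <- config
  cfg_out$sim <- unclass(cfg_out$sim)
  yaml::write_yaml(unclass(cfg_out), file.path(config$out_dir,
                                               "config.yaml"))
  logf("done")
  invisible(list(dataset = ds, mlgs = clones$mlgs,
                 synonymy = clones$synonymy, identity = idn,
                 resampling = resamp, diversity = div,
                 allelic_richness = ar, fis = fis,
                 differentiation = list(gene_pools = diff_pool,
                                        pairwise = diff_pair),
                 rarefaction = rar, treemix = tm, summary = summary))
}
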