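# Orchestration: one call that takes a configuration (R list or YAML
# path), runs the stages in order and writes deterministic tabular
# outputs plus a machine-readable manifest. The R functions are the
# interface; the config mirrors what each stage function takes.

#' Run the full TSS-seq downstream pipeline
#'
#' Stages, in order: read promoter annotation and stranded bedGraph pairs
#' for the WT and mutant libraries; merge replicates per genotype; build
#' 401-nt promoter-window count tables; apply the mean-WT-expression
#' filter; row-normalize and form mutant-minus-WT difference tables;
#' compute expression-spread-median metrics and shift/spread-change
#' tables with the Wilcoxon shift test; correlate all libraries pairwise
#' and cluster; PCA of the shift profiles (when >= 2 mutants). All
#' outputs are written under `config$out_dir` together with
#' `manifest.json` recording parameters and package version.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   `promoters` (annotation TSV path); `libraries` — a list of entries
#'   each with `id`, `genotype`, `role` ("wt"/"mutant"), `plus`, `minus`
#'   (bedGraph paths); optional `upstream` (250), `downstream` (150),
#'   `min_mean_reads` (100), `min_count` (3); `out_dir`.
#' @return The output directory, invisibly; stage results are returned as
#'   an attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  promoters <- read_promoters(cfg$promoters)
  libs <- purrr::map(cfg$libraries, function(l) {
    merge_signals(read_bedgraph(l$plus, "+"), read_bedgraph(l$minus, "-"),
                  library_id = l$id)
  })
  names(libs) <- purrr::map_chr(cfg$libraries, "id")
  roles <- purrr::map_chr(cfg$libraries, "role")
  genotypes <- purrr::map_chr(cfg$libraries, "genotype")

  # per-genotype replicate-summed signals; WT reference pools all WT libraries
  geno_signals <- purrr::map(split(seq_along(libs), genotypes), function(ix) {
    merge_signals(libs[ix])
  })
  wt_signal <- merge_signals(libs[roles == "wt"], library_id = "WT")

  wt_lib_tables <- purrr::map(libs[roles == "wt"], build_count_table,
                              promoters = promoters,
                              upstream = cfg$upstream,
                              downstream = cfg$downstream)
  keep <- filter_expressed(unname(wt_lib_tables),
                           min_mean_reads = cfg$min_mean_reads)

  wt_table <- subset_table(
    build_count_table(wt_signal, promoters, cfg$upstream, cfg$downstream,
                      source_label = "WT"), keep)
  wt_norm <- normalize_rows(wt_table)
  wt_metrics <- metrics_table(wt_table)
  write_count_table(wt_table, file.path(cfg$out_dir, "counts_WT.csv"))
  write_metrics(wt_metrics, file.path(cfg$out_dir, "metrics_WT.tsv"))

  mutant_genotypes <- setdiff(unique(genotypes[roles == "mutant"]), NULL)
  shift_tables <- list()
  shift_tests <- list()
  for (g in mutant_genotypes) {
    tab <- subset_table(
      build_count_table(geno_signals[[g]], promoters, cfg$upstream,
                        cfg$downstream, source_label = g), keep)
    metrics <- metrics_table(tab)
    shifts <- shift_table(metrics, wt_metrics)
    diffs <- diff_tables(normalize_rows(tab), wt_norm)
    write_count_table(tab, file.path(cfg$out_dir, paste0("counts_", g, ".csv")))
    write_metrics(metrics, file.path(cfg$out_dir, paste0("metrics_", g, ".tsv")))
    write_metrics(shifts, file.path(cfg$out_dir, paste0("shifts_", g, ".tsv")))
    write_count_table(diffs, file.path(cfg$out_dir, paste0("diff_", g, ".csv")))
    shift_tables[[g]] <- shifts
    if (sum(!is.na(shifts$shift)) >= 6) {
      shift_tests[[g]] <- test_shifts_nonzero(shifts)
    }
  }

  corr <- correlation_matrix(libs, min_count = cfg$min_count)
  utils::write.table(corr$r, file.path(cfg$out_dir, "correlation.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  clust <- if (!anyNA(corr$r)) cluster_rows(corr) else NULL
  if (!is.null(clust)) {
    writeLines(clust$newick, file.path(cfg$out_dir, "correlation_tree.nwk"))
  }

  pca <- NULL
  if (length(shift_tables) >= 2) {
    pca <- pca_shifts(shift_profile_matrix(shift_tables))
    readr::write_tsv(pca$scores, file.path(cfg$out_dir, "pca_scores.tsv"),
                     progress = FALSE)
  }

  manifest <- list(
    package = "scanseq",
    version = as.character(utils::packageVersion("scanseq")),
    parameters = cfg[c("upstream", "downstream", "min_mean_reads",
                       "min_count")],
    promoters = cfg$promoters,
    libraries = cfg$libraries,
    n_promoters = nrow(promoters),
    n_retained = length(keep),
    percentile_rule = "inclusive: smallest offset with cumulative >= q% of total",
    linkage = "average"
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  results <- list(retained = keep, wt_metrics = wt_metrics,
                  shift_tables = shift_tables, shift_tests = shift_tests,
                  correlation = corr, clustering = clust, pca = pca)
  out <- cfg$out_dir
  attr(out, "results") <- results
  invisible(out)
}

validate_config <- function(config) {
  defaults <- list(upstream = 250, downstream = 150, min_mean_reads = 100,
                   min_count = 3)
  cfg <- utils::modifyList(defaults, config)
  for (field in c("promoters", "libraries", "out_dir")) {
    if (is.null(cfg[[field]])) {
      abort(paste0("config validation: missing '", field, "'"))
    }
  }
  if (!file.exists(cfg$promoters)) {
    abort(paste0("config validation: promoter file not found: ",
                 cfg$promoters))
  }
  roles <- purrr::map_chr(cfg$libraries, function(l) l$role %||% "")
  if (!any(roles == "wt")) {
    abort("config validation: at least one WT library is required")
  }
  for (l in cfg$libraries) {
    for (f in c("plus", "minus")) {
      if (is.null(l[[f]]) || !file.exists(l[[f]])) {
        abort(paste0("config validation: missing bedGraph for library ",
                     l$id %||% "?", " (", f, " strand)"))
      }
    }
  }
  cfg
}

#' Simulate a ready-to-analyse synthetic dataset
#'
#' Generates a promoter set and one library per requested genotype under
#' a named design, writes the bedGraph pairs plus annotation to disk, and
#' returns the paths. Designs: `"wt-vs-processivity-lof"` (WT +
#' processivity-down), `"wt-vs-efficiency"` (WT + efficiency-up/-down),
#' `"four-class"` (WT + all four mutant classes).
#'
#' @param out_dir Output directory.
#' @param design Design name as above.
#' @param n_promoters Number of synthetic promoters.
#' @param flux Forays per promoter.
#' @param depth_factor Depth multiplier (> 0).
#' @param seed Integer seed.
#' @return Named list of per-genotype file paths, invisibly.
#' @export
simulate_dataset <- function(out_dir, design = "wt-vs-processivity-lof",
                             n_promoters = 50, flux = 1e4,
                             depth_factor = 1, seed = 1) {
  genos <- switch(design,
    "wt-vs-processivity-lof" = c("wt", "processivity-down"),
    "wt-vs-efficiency" = c("wt", "efficiency-up", "efficiency-down"),
    "four-class" = c("wt", "efficiency-up", "efficiency-down",
                     "processivity-up", "processivity-down"),
    abort(paste0("unknown design: ", design)))
  set <- synthetic_promoters(n_promoters, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(set$promoters, file.path(out_dir, "promoters.tsv"),
                   progress = FALSE)
  paths <- purrr::map(seq_along(genos), function(i) {
    sig <- emit_library(set, genotype = genos[i], flux = flux,
                        depth_factor = depth_factor, seed = seed + i)
    write_library(sig, set$promoters, out_dir, prefix = genos[i])
  })
  names(paths) <- genos
  invisible(paths)
}
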