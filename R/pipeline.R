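# End-to-end pipeline driver and configuration.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    # classifier construction
    n_down = 65L, n_up = 35L, padj_threshold = 0.05, ratio_threshold = 0.8,
    # methylation domains and consensus DMR calling
    domain_low = 25, domain_high = 70,
    n_groups = 3L, group_size = 4L, iterations = 100L,
    diff_threshold = 10, consensus = 0.5, alpha = 0.05, min_calls = 10L,
    # single-cell bisulfite QC
    qc_min_mapping = 10, qc_min_cpgs = 500000, qc_noncpg_lower = 1,
    # ChIP windows
    window_size = 2000L, input_low = 0.04, input_high = 2,
    enrich_threshold = 1,
    # inputs: either simulate (default) or paths to counts/meta TSVs
    simulate = TRUE,
    counts_file = NULL, meta_file = NULL,
    # simulation overrides (passed through to sim_config)
    sim = list(meth_n_nsn = 12L, meth_n_sn = 28L)
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML with a strict schema: unknown keys are rejected; absent keys take
#' the defaults, which are the analysis constants of the study design
#' (65 + 35 classifier markers; 25/70 domain bounds; 3 pseudobulk groups
#' of 4 over 100 iterations with a >10-point difference and 50% consensus;
#' QC at >10% mapping and >500,000 CpGs; 2-kb windows with the 0.04-2
#' input validity band and RPKM > 1 enrichment).
#'
#' @param path YAML file path, or a named list of overrides.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    abort("config must be a YAML path or a named list")
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  if (cfg$domain_low >= cfg$domain_high) {
    stop_cfg("domain_low/domain_high", "requires low < high")
  }
  if (cfg$consensus < 0 || cfg$consensus > 1) {
    stop_cfg("consensus", "must be in [0, 1]")
  }
  if (cfg$diff_threshold < 0) stop_cfg("diff_threshold", "must be >= 0")
  if (cfg$iterations < 1) stop_cfg("iterations", "must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the expression, classifier, methylome and chromatin stages in
#' order and writes every result table plus a manifest (package version,
#' seeds, thresholds and md5 of every output) so a run is exactly
#' reproducible. By default the stages run on synthetic data generated
#' from the configured seed; external count matrices can be supplied via
#' `counts_file` / `meta_file`. A stage failure aborts with the stage
#' name; outputs already written are renamed with a `.partial` suffix.
#'
#' @param config A [read_pipeline_config()] result, a YAML path, or a
#'   named list of overrides.
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out_dir`.
#' @return List of stage results (invisible elements: `detected`, `de`,
#'   `model`, `calls`, `qc`, `dmrs`, `windows`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% abort("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  fail <- function(stage, e) {
    for (p in written) file.rename(p, paste0(p, ".partial"))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  }
  if (!is.null(cfg$counts_file) &&
      (!file.exists(cfg$counts_file) ||
       (!is.null(cfg$meta_file) && !file.exists(cfg$meta_file)))) {
    abort("input path does not exist; nothing was run")
  }
  res <- list()
  sim_args <- cfg$sim[intersect(names(cfg$sim), names(formals(sim_config)))]

  # --- expression stage -----------------------------------------------
  tryCatch({
    if (!is.null(cfg$counts_file)) {
      counts <- read_count_matrix(cfg$counts_file)
      meta <- suppressMessages(readr::read_tsv(cfg$meta_file,
                                               show_col_types = FALSE))
      sim_rna <- NULL
    } else {
      sim_rna <- simulate_counts(do.call(
        sim_config, c(list(seed = cfg$seed), sim_args)))
      counts <- sim_rna$counts
      meta <- sim_rna$meta
    }
    inform(sprintf("[expr] %d transcripts x %d samples",
                   nrow(counts), nrow(meta)))
    detected <- detected_transcripts(counts, meta)
    missing_tx <- sn_missing_filter(counts, meta)
    de <- differential_expression(counts, meta)
    emit(detected, "detected_transcripts.tsv")
    emit(missing_tx, "sn_missing.tsv")
    emit(de, "de_table.tsv")
    res$detected <- detected; res$de <- de; res$counts <- counts
    res$meta <- meta; res$sim_rna <- sim_rna
  }, error = function(e) fail("expression", e))

  # --- classifier stage -----------------------------------------------
  tryCatch({
    ref_ids <- if (!is.null(res$sim_rna)) {
      c(res$sim_rna$truth$degraded_ids, res$sim_rna$truth$up_ids)
    } else {
      res$de$transcript_id[!is.na(res$de$padj) & res$de$padj < cfg$padj_threshold]
    }
    model <- build_classifier(res$de, ref_ids, n_down = cfg$n_down,
                              n_up = cfg$n_up,
                              padj_threshold = cfg$padj_threshold)
    model <- fit_reference(model, res$counts, res$meta)
    calls <- classify_stage(model, res$counts, res$meta,
                            ratio_threshold = cfg$ratio_threshold)
    inform(sprintf("[classify] %d markers; %d/%d samples classified",
                   nrow(model$markers), sum(calls$call != "unclassified"),
                   nrow(calls)))
    emit(tidy(model), "classifier_markers.tsv")
    emit(calls, "stage_calls.tsv")
    res$model <- model; res$calls <- calls
  }, error = function(e) fail("classifier", e))

  # --- methylome stage ------------------------------------------------
  tryCatch({
    meth_cfg <- do.call(sim_config, utils::modifyList(
      c(list(seed = cfg$seed), sim_args),
      list(n_nsn = cfg$sim$meth_n_nsn %||% 12L,
           n_sn = cfg$sim$meth_n_sn %||% 28L)))
    sim_m <- simulate_methylomes(meth_cfg)
    # QC CpG threshold scaled to the synthetic genome's CpG content.
    n_cpg_genome <- nrow(sim_m$truth$cpg_positions)
    qc <- qc_filter(sim_m$cells,
                    min_mapping = cfg$qc_min_mapping,
                    min_cpgs = min(cfg$qc_min_cpgs, 0.5 * meth_cfg$coverage_frac *
                                    n_cpg_genome),
                    noncpg_bounds = c(cfg$qc_noncpg_lower, 100))
    inform(sprintf("[meth] %d/%d cells pass QC", sum(qc$report$pass),
                   nrow(sim_m$cells)))
    dmrs <- call_dmrs(qc$cells, sim_m$domains, n_iter = cfg$iterations,
                      group_size = cfg$group_size, n_groups = cfg$n_groups,
                      diff_threshold = cfg$diff_threshold, alpha = cfg$alpha,
                      consensus = cfg$consensus, min_calls = cfg$min_calls,
                      seed = cfg$seed)
    inform(sprintf("[meth] %d consensus DMRs", nrow(dmrs$table)))
    emit(qc$report, "meth_qc_report.tsv")
    emit(sim_m$domains[, c("chrom", "start", "end", "class", "domain_id")],
         "domains.tsv")
    emit(dmrs$table, "dmrs.tsv")
    res$qc <- qc; res$dmrs <- dmrs; res$sim_meth <- sim_m
  }, error = function(e) fail("methylome", e))

  # --- chromatin stage ------------------------------------------------
  tryCatch({
    chip_cfg <- do.call(sim_config, utils::modifyList(
      c(list(seed = cfg$seed), sim_args),
      list(window_size = cfg$window_size)))
    sim_c <- simulate_chip_windows(chip_cfg)
    wins <- sim_c$windows %>%
      filter_windows(input_low = cfg$input_low, input_high = cfg$input_high) %>%
      assign_categories(enrich_threshold = cfg$enrich_threshold)
    inform(sprintf("[chip] %d/%d windows valid", sum(wins$valid), nrow(wins)))
    dmr_ivs <- res$dmrs$table
    enr <- if (nrow(dmr_ivs) > 0 && "chrom" %in% names(dmr_ivs)) {
      dmr_category_enrichment(wins, dmr_ivs[, c("chrom", "start", "end")],
                              n_random = 50, seed = cfg$seed)
    } else {
      NULL
    }
    emit(select(wins, -dplyr::any_of("calls")), "windows_categorized.tsv")
    if (!is.null(enr)) emit(enr$by_category, "category_enrichment.tsv")
    res$windows <- wins; res$enrichment <- enr
  }, error = function(e) fail("chromatin", e))

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "oostage",
    version = as.character(utils::packageVersion("oostage")),
    seed = cfg$seed,
    thresholds = cfg[c("n_down", "n_up", "padj_threshold", "ratio_threshold",
                       "domain_low", "domain_high", "n_groups", "group_size",
                       "iterations", "diff_threshold", "consensus", "alpha",
                       "min_calls", "qc_min_mapping", "qc_min_cpgs",
                       "window_size", "input_low", "input_high",
                       "enrich_threshold")],
    outputs = lapply(setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
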