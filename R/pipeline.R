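# End-to-end orchestration: validated config, staged execution
# (read -> match -> cascade -> screen -> summarize -> model -> network),
# a machine-readable report bundle and a run manifest with file digests.

#' Validate a pipeline configuration
#'
#' A config is a list (or path of a JSON file) with:
#' \itemize{
#'   \item `seed` integer (required).
#'   \item `out_dir` output directory (required).
#'   \item either `simulate` (a list of [sim_config()] overrides) or
#'     `inputs` (list with paths `prescriptions`, `kb`, `concepts`).
#'   \item `options`: `top_k_edges` (required for the network stage; no
#'     default), `min_specialty_volume` (default 5000), `bootstrap_B`
#'     (default 0 = no bootstrap), `topical_removal` (default "line").
#' }
#'
#' @param config list or JSON path.
#' @return the normalised config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) cfg_fail("config must be a list or JSON path")
  if (is.null(config$seed)) cfg_fail("config.seed is required")
  if (is.null(config$out_dir)) cfg_fail("config.out_dir is required")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$inputs)
  if (!has_sim && !has_in) {
    cfg_fail("config needs either 'simulate' or 'inputs'")
  }
  if (has_in) {
    for (f in c("prescriptions", "kb", "concepts")) {
      if (is.null(config$inputs[[f]])) {
        cfg_fail(sprintf("config.inputs.%s is required", f))
      }
      if (!file.exists(config$inputs[[f]])) {
        cfg_fail(sprintf("input file not found: %s", config$inputs[[f]]))
      }
    }
  }
  opt <- config$options
  if (is.null(opt)) opt <- list()
  if (is.null(opt$min_specialty_volume)) opt$min_specialty_volume <- 5000L
  if (is.null(opt$bootstrap_B)) opt$bootstrap_B <- 0L
  if (is.null(opt$topical_removal)) opt$topical_removal <- "line"
  config$options <- opt
  config$seed <- as.integer(config$seed)
  config
}

cfg_fail <- function(msg) stop(ddi_error("ddi_config_error", msg))

log_stage <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Run the screening pipeline end to end
#'
#' Executes the stages in order (simulate/read, match + cascade, screen,
#' summarize, model, network) and writes a report bundle to
#' `config$out_dir`: flow and match reports, summary CSV/JSON tables, model
#' fits, network files, and `manifest.json` listing every output with its
#' MD5 digest. With identical config and inputs the bundle is byte-identical
#' across runs.
#'
#' @param config list or JSON path, see [validate_config()].
#' @param stages subset of stages to emit outputs for (upstream stages are
#'   recomputed in memory as needed).
#' @return invisibly, a list with the in-memory objects (`cohort`, `kb`,
#'   `screen`, `summaries`, `fits`, `network`, `manifest`).
#' @export
run_pipeline <- function(config,
                         stages = c("screen", "summarize", "model", "network")) {
  config <- validate_config(config)
  stages <- match.arg(stages, c("screen", "summarize", "model", "network"),
                      several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(path) outputs[[length(outputs) + 1L]] <<- path

  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  # ingest ----------------------------------------------------------------
  s <- Sys.time()
  if (!is.null(config$simulate)) {
    log_stage("simulate: generating synthetic cohort (seed ", config$seed, ")")
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    gen <- generate_cohort(cfg,
                           csv_path = file.path(out_dir, "prescriptions.csv"),
                           truth_path = file.path(out_dir, "truth.json"))
    emit(file.path(out_dir, "prescriptions.csv"))
    emit(file.path(out_dir, "truth.json"))
    kb_src <- gen$kb$kb_rows
    concepts_src <- gen$kb$concepts
    items <- read_prescriptions(file.path(out_dir, "prescriptions.csv"))
  } else {
    log_stage("read: ", config$inputs$prescriptions)
    items <- read_prescriptions(config$inputs$prescriptions)
    kb_src <- config$inputs$kb
    concepts_src <- config$inputs$concepts
  }
  kb <- load_interaction_kb(kb_src)
  index <- build_alias_index(concepts_src)
  tick("ingest", s)

  # match + cascade --------------------------------------------------------
  s <- Sys.time()
  log_stage("cascade: matching and exclusion accounting")
  cohort <- apply_exclusion_cascade(items, index,
                                    topical_removal = config$options$topical_removal)
  if (cohort$flow$n_retained == 0L) {
    stop(ddi_error("ddi_data_error", "no prescriptions retained by the cascade"))
  }
  flow_report(cohort, file.path(out_dir, "flow_report.json"))
  emit(file.path(out_dir, "flow_report.json"))
  kb_report(kb, file.path(out_dir, "kb_report.json"))
  emit(file.path(out_dir, "kb_report.json"))
  tick("cascade", s)

  # screen -----------------------------------------------------------------
  s <- Sys.time()
  log_stage("screen: detecting interactions in ", cohort$flow$n_retained,
            " prescriptions")
  sr <- screen_cohort(cohort, kb)
  if ("screen" %in% stages) {
    write_screen_csv(sr, file.path(out_dir, "interactions.csv"),
                     file.path(out_dir, "pair_counts.csv"))
    emit(file.path(out_dir, "interactions.csv"))
    emit(file.path(out_dir, "pair_counts.csv"))
  }
  tick("screen", s)

  # summarize --------------------------------------------------------------
  summaries <- NULL
  if ("summarize" %in% stages) {
    s <- Sys.time()
    log_stage("summarize: prevalence, severity, profiles, strata")
    summaries <- list(prevalence = prevalence_summary(sr, cohort),
                      severity = severity_distribution(sr),
                      profiles = profile_distribution(sr),
                      coverage = pair_coverage(sr, kb),
                      top_pairs = top_interactions(sr, 10L),
                      by_sex = stratified_summary(sr, cohort, "sex"),
                      by_age = stratified_summary(sr, cohort, "age_group"),
                      by_specialty = stratified_summary(sr, cohort, "specialty"))
    data.table::fwrite(summaries$profiles,
                       file.path(out_dir, "profile_distribution.csv"))
    emit(file.path(out_dir, "profile_distribution.csv"))
    data.table::fwrite(summaries$top_pairs, file.path(out_dir, "top_pairs.csv"))
    emit(file.path(out_dir, "top_pairs.csv"))
    for (st in c("by_sex", "by_age", "by_specialty")) {
      p <- file.path(out_dir, paste0(st, ".csv"))
      data.table::fwrite(summaries[[st]]$table, p)
      emit(p)
    }
    jsonlite::write_json(
      list(prevalence = summaries$prevalence,
           severity = summaries$severity,
           coverage = summaries$coverage),
      file.path(out_dir, "summary_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit(file.path(out_dir, "summary_report.json"))
    tick("summarize", s)
  }

  # model ------------------------------------------------------------------
  fits <- NULL
  if ("model" %in% stages) {
    s <- Sys.time()
    log_stage("model: count, interaction-adjusted, contraindication models")
    fits <- tryCatch({
      design <- build_design(cohort, sr,
                             min_specialty_volume = config$options$min_specialty_volume)
      f1 <- fit_count_model(design)
      f2 <- fit_interaction_model(design)
      f3 <- tryCatch(fit_contra_model(design), error = function(e) e)
      B <- config$options$bootstrap_B
      bs <- if (B >= 100L) bootstrap_ci(fit_count_model, design, B = B,
                                        seed = config$seed) else NULL
      write_fit(f1, file.path(out_dir, "fit_count.csv"),
                file.path(out_dir, "fit_count.json"), bootstrap = bs)
      emit(file.path(out_dir, "fit_count.csv"))
      emit(file.path(out_dir, "fit_count.json"))
      write_fit(f2, file.path(out_dir, "fit_interaction.csv"),
                file.path(out_dir, "fit_interaction.json"))
      emit(file.path(out_dir, "fit_interaction.csv"))
      emit(file.path(out_dir, "fit_interaction.json"))
      if (!inherits(f3, "error")) {
        write_fit(f3, file.path(out_dir, "fit_contra.csv"),
                  file.path(out_dir, "fit_contra.json"))
        emit(file.path(out_dir, "fit_contra.csv"))
        emit(file.path(out_dir, "fit_contra.json"))
      } else {
        log_stage("model: contraindication model skipped (",
                  conditionMessage(f3), ")")
      }
      vif <- compute_vif(design)
      data.table::fwrite(vif, file.path(out_dir, "vif.csv"))
      emit(file.path(out_dir, "vif.csv"))
      list(count = f1, interaction = f2,
           contra = if (!inherits(f3, "error")) f3,
           vif = vif, design = design, bootstrap = bs)
    }, error = function(e) {
      stop(ddi_error("ddi_model_error",
                     paste("model stage failed:", conditionMessage(e))))
    })
    tick("model", s)
  }

  # network ----------------------------------------------------------------
  net <- NULL
  if ("network" %in% stages) {
    s <- Sys.time()
    top_k <- config$options$top_k_edges
    if (is.null(top_k)) {
      cfg_fail("options.top_k_edges is required for the network stage")
    }
    log_stage("network: top ", top_k, " edges")
    if (nrow(sr$per_pair) > 0L) {
      net <- build_network(sr, top_k = top_k)
      write_graph(net, file.path(out_dir, "network.graphml"), "graphml")
      write_graph(net, file.path(out_dir, "network.sif"), "sif")
      write_graph(net, file.path(out_dir, "network_edges.csv"), "edge-csv")
      for (f in c("network.graphml", "network.sif", "network_edges.csv")) {
        emit(file.path(out_dir, f))
      }
    } else {
      log_stage("network: no interactions detected, stage skipped")
    }
    tick("network", s)
  }

  # manifest ---------------------------------------------------------------
  digests <- tools::md5sum(outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ddiscreen")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    stage_seconds = timings,
    outputs = lapply(seq_along(outputs), function(i)
      list(path = basename(outputs[i]), md5 = unname(digests[i]))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: ", length(outputs), " outputs in ",
            format(difftime(Sys.time(), t0)))
  invisible(list(cohort = cohort, kb = kb, screen = sr, summaries = summaries,
                 fits = fits, network = net, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `build-kb`, `screen`, `summarize`, `model`,
#' `network`, `run`. Each takes `--config <path>` (JSON; see
#' [validate_config()]), with optional `--seed` and `--out-dir` overrides.
#' Exit codes: 0 success, 2 config error, 3 data validation error, 4 model
#' error. Run e.g. as
#' `Rscript -e 'ddiscreen::ddi_cli()' run --config cfg.json`.
#'
#' @param args character vector (defaults to `commandArgs(trailingOnly =
#'   TRUE)`).
#' @param exit call `quit()` with the status (default only when running
#'   non-interactively at a real command line); with `exit = FALSE` the
#'   status is returned instead.
#' @return exit status, invisibly.
#' @export
ddi_cli <- function(args = commandArgs(trailingOnly = TRUE),
                    exit = !interactive()) {
  subs <- c("simulate", "build-kb", "screen", "summarize", "model",
            "network", "run")
  status <- tryCatch({
    if (length(args) < 1L || !args[1] %in% subs) {
      cfg_fail(paste("usage: <subcommand> --config <path>; subcommands:",
                     paste(subs, collapse = ", ")))
    }
    sub <- args[1]
    opts <- parse_cli_opts(args[-1])
    if (is.null(opts$config)) cfg_fail("--config is required")
    config <- validate_config(opts$config)
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    if (!is.null(opts$`out-dir`)) config$out_dir <- opts$`out-dir`
    stage_map <- list(simulate = "screen", `build-kb` = "screen",
                      screen = "screen", summarize = "summarize",
                      model = "model", network = "network",
                      run = c("screen", "summarize", "model", "network"))
    run_pipeline(config, stages = stage_map[[sub]])
    0L
  },
  ddi_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  ddi_model_error = function(e) { message("model error: ", conditionMessage(e)); 4L },
  ddi_data_error = function(e) { message("data error: ", conditionMessage(e)); 3L },
  error = function(e) { message("data error: ", conditionMessage(e)); 3L })
  if (exit) quit(status = status, save = "no")
  invisible(status)
}

parse_cli_opts <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i + 1L > length(args)) cfg_fail(paste("missing value for", a))
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      cfg_fail(paste("unexpected argument:", a))
    }
  }
  out
}
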