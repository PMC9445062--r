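#' Load and validate a pipeline configuration
#'
#' A pipeline config is a YAML file (or equivalent list) with top-level
#' `seed`, `outdir`, and per-stage blocks `simulate`, `scan`, `select`,
#' `predict`. The `simulate` block is either `preset: demo` /
#' `preset: paper_mimic` or explicit [cohort_config()] fields plus a
#' `fraction` / `subcohort_size` (and optional `n_cases`) sampling spec.
#' A seed is mandatory whenever a stochastic stage is enabled.
#'
#' @param config path to a YAML file or a list.
#' @return validated config list with a `config_hash` attribute.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$outdir)) config$outdir <- "metabcc_out"
  stochastic <- !is.null(config$simulate) ||
    isTRUE((config$predict %||% list())$B > 0)
  if (stochastic && is.null(config$seed))
    stop("config error: 'seed' is mandatory when a stochastic stage is enabled")
  attr(config, "config_hash") <- config_hash(config)
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

# refuse to overwrite a stage output produced under a different config
check_output_hash <- function(path, hash, overwrite) {
  if (!file.exists(path) || overwrite) return(invisible(TRUE))
  lines <- readLines(path, n = 10L)
  old <- sub("^# config_hash: ", "", grep("^# config_hash: ", lines,
                                          value = TRUE))
  if (length(old) && old != hash)
    stop("output ", path, " was produced under a different config ",
         "(hash ", old, " != ", hash, "); refusing to overwrite. ",
         "Pass overwrite = TRUE or choose a fresh outdir.")
  invisible(TRUE)
}

pipeline_paths <- function(outdir) {
  list(cohort = file.path(outdir, "cohort.tsv"),
       dataset = file.path(outdir, "case_cohort.tsv"),
       panel = file.path(outdir, "panel.tsv"),
       cuboid = file.path(outdir, "cuboid.tsv"),
       scan = file.path(outdir, "scan.tsv"),
       selection_json = file.path(outdir, "selection.json"),
       selection_tsv = file.path(outdir, "selection.tsv"),
       prediction = file.path(outdir, "prediction.tsv"),
       prediction_json = file.path(outdir, "prediction_boot.json"))
}

resolve_simulate_block <- function(config) {
  sim <- config$simulate
  if (is.null(sim)) stop("config has no 'simulate' block")
  seed <- config$seed
  if (!is.null(sim$preset)) {
    preset <- switch(sim$preset,
                     demo = demo_preset(seed),
                     paper_mimic = paper_mimic_preset(seed),
                     stop("unknown preset: ", sim$preset))
    return(preset)
  }
  fields <- sim[setdiff(names(sim), c("fraction", "subcohort_size",
                                      "n_cases"))]
  fields$seed <- seed
  cfg <- do.call(cohort_config, fields)
  list(config = cfg, fraction = sim$fraction,
       subcohort_size = sim$subcohort_size, n_cases = sim$n_cases)
}

#' Run pipeline stages
#'
#' `pipeline_simulate()` generates the cohort and case-cohort dataset and
#' writes them (plus the panel spec and cuboid layout) to the output
#' directory; `pipeline_scan()`, `pipeline_select()` and
#' `pipeline_predict()` run the downstream stages from the files on disk;
#' `run_pipeline()` chains them. Every output carries the config hash and
#' seed in `#`-comment header lines, and a stage refuses to overwrite an
#' output written under a different config.
#'
#' @param config a config list or YAML path (see
#'   [read_pipeline_config()]).
#' @param overwrite allow overwriting outputs from a different config.
#' @return the main output path(s) of the stage, invisibly.
#' @export
pipeline_simulate <- function(config, overwrite = FALSE) {
  config <- read_pipeline_config(config)
  hash <- attr(config, "config_hash")
  paths <- pipeline_paths(config$outdir)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- resolve_simulate_block(config)
  cohort <- simulate_cohort(spec$config)
  dataset <- sample_case_cohort(cohort, fraction = spec$fraction,
                                subcohort_size = spec$subcohort_size,
                                n_cases = spec$n_cases,
                                seed = config$seed)
  extra <- c(config_hash = hash)
  check_output_hash(paths$cohort, hash, overwrite)
  check_output_hash(paths$dataset, hash, overwrite)
  write_dataset_tsv(cohort, paths$cohort, extra = extra)
  write_dataset_tsv(dataset, paths$dataset, extra = extra)
  write_panel_spec(spec$config$panel, paths$panel)
  message(sprintf("simulate: cohort n=%d, dataset rows=%d, cases=%d, subcohort=%d",
                  nrow(cohort), nrow(dataset), sum(dataset$is_case),
                  sum(dataset$in_subcohort)))
  invisible(paths$dataset)
}

load_stage_inputs <- function(config) {
  paths <- pipeline_paths(config$outdir)
  if (!file.exists(paths$dataset))
    stop("missing upstream output: ", paths$dataset,
         " (run the simulate stage first)")
  dataset <- read_dataset_tsv(paths$dataset)
  dataset$in_subcohort <- as.logical(dataset$in_subcohort)
  dataset$is_case <- as.logical(dataset$is_case)
  panel <- if (file.exists(paths$panel)) read_panel_spec(paths$panel)
  else default_panel()
  list(paths = paths, dataset = dataset, panel = panel)
}

#' @rdname pipeline_simulate
#' @export
pipeline_scan <- function(config, overwrite = FALSE) {
  config <- read_pipeline_config(config)
  hash <- attr(config, "config_hash")
  inp <- load_stage_inputs(config)
  tiers <- (config$scan %||% list())$tiers %||%
    c("basic", "full", "full_plus_glucose", "fig2")
  d <- standardize_biomarkers(inp$dataset, inp$panel)
  scan <- run_scan(d, inp$panel, tiers = tiers)
  check_output_hash(inp$paths$scan, hash, overwrite)
  write_association_tsv(scan, inp$paths$scan,
                        extra = c(config_hash = hash,
                                  seed = as.character(config$seed %||% "")))
  n_sig <- sum(scan$significant & scan$tier == tiers[1], na.rm = TRUE)
  message(sprintf("scan: %d markers x %d tiers; %d FDR discoveries in tier %s",
                  length(unique(scan$biomarker)), length(unique(scan$tier)),
                  n_sig, tiers[1]))
  invisible(inp$paths$scan)
}

#' @rdname pipeline_simulate
#' @export
pipeline_select <- function(config, overwrite = FALSE) {
  config <- read_pipeline_config(config)
  hash <- attr(config, "config_hash")
  inp <- load_stage_inputs(config)
  sel_cfg <- do.call(selection_config, config$select %||% list())
  d <- standardize_biomarkers(inp$dataset, inp$panel)
  cuboid <- assign_cuboid(inp$panel, sel_cfg$dims)
  result <- cuboid_select(d, inp$panel, cuboid, sel_cfg)
  check_output_hash(inp$paths$selection_tsv, hash, overwrite)
  write_cuboid_tsv(cuboid, inp$paths$cuboid)
  write_selection_json(result, inp$paths$selection_json)
  write_selection_tsv(result, inp$paths$selection_tsv)
  message(sprintf("select: %d pre-prune, %d selected",
                  length(result$pre_prune), length(result$selected)))
  invisible(inp$paths$selection_tsv)
}

#' @rdname pipeline_simulate
#' @export
pipeline_predict <- function(config, overwrite = FALSE) {
  config <- read_pipeline_config(config)
  hash <- attr(config, "config_hash")
  inp <- load_stage_inputs(config)
  if (!file.exists(inp$paths$selection_tsv))
    stop("missing upstream output: ", inp$paths$selection_tsv,
         " (run the select stage first)")
  sel <- utils::read.delim(inp$paths$selection_tsv,
                           stringsAsFactors = FALSE)
  B <- (config$predict %||% list())$B %||% 200L
  d <- standardize_biomarkers(inp$dataset, inp$panel)
  base <- fit_risk_model(d, tag = "base")
  markers <- sel$marker
  if (!length(markers)) {
    warning("selected biomarker set is empty; ",
            "comparing the base model against itself")
    enhanced <- base
    enhanced$tag <- "enhanced"
  } else {
    enhanced <- fit_risk_model(d, biomarkers = markers, tag = "enhanced")
  }
  cmp <- compare_models(base, enhanced, d, B = B,
                        seed = config$seed %||% 1L)
  check_output_hash(inp$paths$prediction, hash, overwrite)
  con <- file(inp$paths$prediction, "w", encoding = "UTF-8")
  writeLines(c(paste0("# config_hash: ", hash),
               paste0("# seed: ", config$seed %||% ""),
               paste0("# delta_c: ", format(cmp$delta_c, digits = 17)),
               paste0("# p: ", format(cmp$p, digits = 17))), con)
  utils::write.table(cmp$table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  jsonlite::write_json(
    list(delta_c = cmp$delta_c, delta_ci = cmp$delta_ci, p = cmp$p,
         B = cmp$B, seed = cmp$seed, boot_delta = cmp$boot_delta),
    inp$paths$prediction_json, auto_unbox = TRUE, digits = NA)
  message(sprintf("predict: c_base=%.3f c_enhanced=%.3f delta=%.3f p=%.3g",
                  cmp$table$c_base[1], cmp$table$c_enhanced[1],
                  cmp$delta_c, cmp$p))
  invisible(inp$paths$prediction)
}

#' @rdname pipeline_simulate
#' @param stages stages to run, in order; `"all"` expands to
#'   simulate, scan, select, predict.
#' @export
run_pipeline <- function(config, stages = "all", overwrite = FALSE) {
  if (identical(stages, "all"))
    stages <- c("simulate", "scan", "select", "predict")
  for (st in stages) {
    switch(st,
           simulate = pipeline_simulate(config, overwrite),
           scan = pipeline_scan(config, overwrite),
           select = pipeline_select(config, overwrite),
           predict = pipeline_predict(config, overwrite),
           stop("unknown stage: ", st))
  }
  invisible(read_pipeline_config(config)$outdir)
}
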