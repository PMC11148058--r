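## Run configuration, manifest and the umbrella pipeline runner. A run
## config (YAML or list) selects stages and their parameter blocks; every
## run writes its resolved config and a manifest (config hash, input
## checksums, per-stage row counts) so deterministic stages are verifiably
## reproducible.

RUN_STAGES <- c("simulate_screen", "score_screen", "simulate_ipms",
                "ipms_diff")

#' Read and validate a pipeline run configuration
#'
#' @param path YAML file with top-level keys `stages` (ordered stage
#'   names), `seed`, `out_dir`, `log_level`, plus one parameter block per
#'   selected stage. Unknown top-level keys are rejected.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a config given directly as a list.
#' @export
as_run_config <- function(config) {
  known <- c("stages", "seed", "out_dir", "log_level", RUN_STAGES)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || !all(config$stages %in% RUN_STAGES))
    stop("config must list stages from: ", paste(RUN_STAGES, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must set out_dir")
  if (is.null(config$log_level)) config$log_level <- "info"
  class(config) <- "run_config"
  config
}

log_stage <- function(level, stage, msg, cfg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s: %s", level, stage, msg))
}

## Stable md5 of an R object via its serialized bytes on disk.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

## Write through a ".partial" file so an interrupted stage never leaves a
## file that looks complete.
write_atomic <- function(writer, path) {
  partial <- paste0(path, ".partial")
  writer(partial)
  file.rename(partial, path)
  invisible(path)
}

#' Run configured pipeline stages and write a manifest
#'
#' Executes the selected stages in order (simulation stages feed their
#' in-memory outputs to the matching analysis stages), writing each table
#' under `out_dir` and finally `manifest.json` plus the resolved config
#' (`run-config.yaml`). A stage failure aborts the run with the stage name
#' in the error; partially written files keep a `.partial` suffix.
#'
#' @param config a `run_config` (see [read_run_config()] /
#'   [as_run_config()]).
#' @return the run manifest (list), invisibly: `tool_version`,
#'   `config_hash`, `inputs` (file checksums), `started`/`finished`
#'   timestamps and per-stage row counts.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else as_run_config(config)
  ## all referenced input files must exist before any stage runs
  for (st in cfg$stages) {
    blk <- cfg[[st]]
    for (key in intersect(names(blk), c("plates", "values", "matrix", "meta"))) {
      if (!file.exists(blk[[key]]))
        stop("input file for stage '", st, "' not found: ", blk[[key]])
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  counts <- list()
  inputs <- character()
  state <- new.env(parent = emptyenv())

  for (st in cfg$stages) {
    blk <- if (is.null(cfg[[st]])) list() else cfg[[st]]
    res <- tryCatch(switch(st,
      simulate_screen = {
        blk$rng_seed <- if (is.null(blk$rng_seed)) cfg$seed else blk$rng_seed
        sim <- simulate_screen(do.call(screen_sim_config, blk))
        state$wells <- sim$wells
        write_atomic(function(p) write_plate_tables(sim$wells, p),
                     file.path(cfg$out_dir, "wells.csv"))
        list(rows = nrow(sim$wells))
      },
      score_screen = {
        wells <- if (!is.null(blk$plates)) {
          inputs <<- c(inputs, blk$plates)
          read_plate_tables(blk$plates, blk$values)
        } else if (!is.null(state$wells)) state$wells
        else stop("no well table: give 'plates' or run simulate_screen first")
        args <- blk[setdiff(names(blk), c("plates", "values"))]
        sc <- do.call(score_screen, c(list(wells = wells), args))
        write_atomic(function(p) utils::write.csv(sc$plate_qc, p,
          row.names = FALSE), file.path(cfg$out_dir, "plate_qc.csv"))
        write_atomic(function(p) utils::write.csv(sc$sirna_scores, p,
          row.names = FALSE), file.path(cfg$out_dir, "sirna_scores.csv"))
        write_atomic(function(p) utils::write.csv(sc$gene_scores, p,
          row.names = FALSE), file.path(cfg$out_dir, "gene_scores.csv"))
        list(rows = nrow(sc$gene_scores), plates = nrow(sc$plate_qc))
      },
      simulate_ipms = {
        blk$rng_seed <- if (is.null(blk$rng_seed)) cfg$seed else blk$rng_seed
        sim <- simulate_ipms(do.call(ipms_sim_config, blk))
        state$ipms <- sim$matrix
        write_atomic(function(p) write_intensity_tsv(sim$matrix, p),
                     file.path(cfg$out_dir, "lfq_matrix.tsv"))
        list(rows = nrow(sim$matrix$values))
      },
      ipms_diff = {
        mat <- if (!is.null(blk$matrix)) {
          inputs <<- c(inputs, blk$matrix, blk$meta)
          read_intensity_tsv(blk$matrix, blk$meta)
        } else if (!is.null(state$ipms)) state$ipms
        else stop("no intensity matrix: give 'matrix' or run simulate_ipms first")
        args <- blk[setdiff(names(blk), c("matrix", "meta"))]
        if (is.null(args$rng_seed)) args$rng_seed <- cfg$seed
        dr <- do.call(ipms_diff, c(list(mat = mat), args))
        write_atomic(function(p) utils::write.table(dr$results, p,
          sep = "\t", row.names = FALSE, quote = FALSE),
          file.path(cfg$out_dir, "diff_results.tsv"))
        list(rows = nrow(dr$results))
      }),
      error = function(e) stop("stage '", st, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    counts[[st]] <- res
    log_stage("info", st, paste("rows:", res$rows), cfg)
  }

  write_atomic(function(p) writeLines(yaml::as.yaml(unclass(cfg)), p),
               file.path(cfg$out_dir, "run-config.yaml"))
  manifest <- list(
    tool_version = as.character(utils::packageVersion("ectopiscan")),
    config_hash = config_hash(cfg),
    inputs = as.list(if (length(inputs))
      vapply(unique(inputs), function(f) unname(tools::md5sum(f)),
             character(1)) else character()),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_counts = counts)
  write_atomic(function(p) jsonlite::write_json(manifest, p,
    auto_unbox = TRUE, pretty = TRUE), file.path(cfg$out_dir,
    "manifest.json"))
  invisible(manifest)
}
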