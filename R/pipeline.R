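#' Pipeline configuration
#'
#' Loads, validates and defaults a nested pipeline configuration from a
#' JSON file or list. Unknown top-level keys are rejected. Presets:
#' `"igm"` (small-database score floors), `"dg75"` (2% total FDR),
#' `"igm_yeast"` (simulate the interference mixture instead of reading
#' an input run).
#'
#' @param config path to a JSON file, or a named list.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("input", "output_dir", "preset", "merge", "search", "quant", "sim",
             "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("pipeline_config: unknown keys: ", paste(unknown, collapse = ", "))
  preset <- config$preset %||% "none"
  search_args <- config$search %||% list()
  if (preset %in% c("igm", "dg75")) search_args$preset <- preset
  cfg <- list(
    input = config$input %||% list(),
    output_dir = config$output_dir %||% "glycoquant_out",
    preset = preset,
    merge = do.call(merge_config, config$merge %||% list()),
    search = do.call(search_config, search_args),
    quant = utils::modifyList(
      list(reference_channel = "126", tol = 0.003,
           condition_channels = character()),
      config$quant %||% list()),
    sim = config$sim %||% list(),
    seed = config$seed %||% 1L)
  structure(cfg, class = "PipelineConfig")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Stages, in order: read (or simulate) the run, merge MS2/MS3 fragments
#' and correct precursors, two-step database search at the configured
#' FDR, reporter extraction, propagation to glycoform/glycosite/glycan
#' tables, optional proteome-median normalization, and Z-score
#' regulation calls. Every stage writes its TSV artifact into the output
#' directory and one log line; reruns with the same config and seed give
#' identical tables.
#'
#' @param cfg a [pipeline_config()] (or path/list coercible to one).
#' @param run optional pre-loaded [scan_hierarchy()] (overrides
#'   `input$run`).
#' @param proteins optional protein `data.table` (overrides
#'   `input$fasta`).
#' @return The output directory, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, run = NULL, proteins = NULL) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- pipeline_config(cfg)
  out <- cfg$output_dir
  log_lines <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("%s\tok\t%.2fs", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  # -- validation before any stage runs
  sim_mode <- cfg$preset == "igm_yeast" || length(cfg$sim)
  if (!sim_mode) {
    if (is.null(run) && is.null(cfg$input$run))
      stop("run_pipeline: no input run configured")
    if (!is.null(cfg$input$run) && is.null(run) && !file.exists(cfg$input$run))
      stop("run_pipeline: input run not found: ", cfg$input$run)
    if (is.null(proteins)) {
      if (is.null(cfg$input$fasta))
        stop("run_pipeline: no FASTA database configured")
      if (!file.exists(cfg$input$fasta))
        stop("run_pipeline: FASTA not found: ", cfg$input$fasta)
    }
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (sim_mode) {
    sim <- stage("simulate", {
      if (cfg$preset == "igm_yeast") {
        mix <- do.call(simulate_interference_mixture,
                       c(list(seed = cfg$seed), cfg$sim))
        mix$sps
      } else {
        do.call(simulate_run,
                list(do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))))
      }
    })
    run <- sim$run
    proteins <- sim$proteins
    truth <- sim$truth
    export_ground_truth(sim, file.path(out, "ground_truth.tsv"))
    write_mgf(run, file.path(out, "simulated_run.mgf"))
    export_sim_config(sim$cfg, file.path(out, "sim_config.json"))
  } else {
    if (is.null(run)) run <- stage("read", read_run(cfg$input$run))
    if (is.null(proteins)) proteins <- stage("read", read_fasta(cfg$input$fasta))
  }
  glycans <- if (!is.null(cfg$input$glycan_library))
    read_glycan_library(cfg$input$glycan_library) else default_glycan_library()

  stage("link_table", write_scan_link_table(run, file.path(out, "scan_links.tsv")))
  pseudo <- stage("merge", build_pseudo_spectra(run, cfg$merge))
  write_mgf(pseudo, file.path(out, "pseudo_spectra.mgf"))
  write_merge_report(pseudo, file.path(out, "merge_report.tsv"))

  res <- stage("search", two_step_search(pseudo, proteins, glycans, cfg$search))
  write_gpsm_table(res, file.path(out, "gpsms_accepted.tsv"))
  write_gpsm_table(res, file.path(out, "gpsms_all.tsv"), what = "all")

  channels <- reporter_channels()
  quant <- stage("quant", {
    acc <- attach_quant(res$accepted, run, channels, cfg$quant$tol)
    propagate(acc, channels)
  })
  gf <- channel_ratios(quant$glycoform, channels, cfg$quant$reference_channel)
  if (!is.null(cfg$input$proteome_ratios)) {
    gf <- stage("normalize", normalize_ratios(
      gf, data.table::fread(cfg$input$proteome_ratios), channels))
    if (length(cfg$quant$condition_channels)) {
      reg <- stage("regulate",
                   call_regulation(gf, cfg$quant$condition_channels))
      data.table::fwrite(reg, file.path(out, "regulation.tsv"), sep = "\t")
    }
  }
  data.table::fwrite(gf, file.path(out, "quant_glycoform.tsv"), sep = "\t")
  data.table::fwrite(quant$glycosite, file.path(out, "quant_glycosite.tsv"), sep = "\t")
  data.table::fwrite(quant$glycan, file.path(out, "quant_glycan.tsv"), sep = "\t")

  log_lines <- c(sprintf("glycoquant\t%s\tseed=%d\tpreset=%s",
                         as.character(utils::packageVersion("glycoquant")),
                         cfg$seed, cfg$preset), log_lines)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(out)
}

#' Command-line interface
#'
#' Subcommands `simulate`, `merge`, `search`, `quant`, `report`, and
#' `run`, each mapping 1:1 to the module entry points. Flags: `--config
#' FILE` (JSON), `--preset igm|dg75|igm_yeast`, `--fdr X`,
#' `--merge-tol-ppm X`, `--seed N`, `--out DIR`, `--in FILE`,
#' `--fasta FILE`; flags override the config file. Exit codes: 0 ok,
#' 1 validation error, 2 runtime error.
#'
#' @param args character vector of arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (the `inst/cli/glycoquant`
#'   wrapper passes it to `quit()`).
#' @export
glyco_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: glycoquant <simulate|merge|search|quant|report|run> [options]",
    "  --config FILE     JSON pipeline config",
    "  --preset NAME     igm | dg75 | igm_yeast",
    "  --fdr X           total FDR threshold",
    "  --merge-tol-ppm X fragment merge tolerance",
    "  --seed N          RNG seed",
    "  --in FILE         input run (mgf/mzML)",
    "  --fasta FILE      protein database",
    "  --out DIR         output directory", sep = "\n")
  fail <- function(msg, code) {
    message(msg)
    invisible(code)
  }
  if (!length(args)) return(fail(usage, 1L))
  cmd <- args[1L]
  if (!cmd %in% c("simulate", "merge", "search", "quant", "report", "run"))
    return(fail(paste0("unknown command '", cmd, "'\n", usage), 1L))
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args))
      return(fail(paste0("malformed option '", key, "'\n", usage), 1L))
    opts[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  conf <- tryCatch({
    raw <- if (!is.null(opts$config))
      jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
    if (!is.null(opts$preset)) raw$preset <- opts$preset
    if (!is.null(opts$fdr)) raw$search$total_fdr <- as.numeric(opts$fdr)
    if (!is.null(opts[["merge-tol-ppm"]]))
      raw$merge$merge_tol_ppm <- as.numeric(opts[["merge-tol-ppm"]])
    if (!is.null(opts$seed)) raw$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) raw$output_dir <- opts$out
    if (!is.null(opts[["in"]])) raw$input$run <- opts[["in"]]
    if (!is.null(opts$fasta)) raw$input$fasta <- opts$fasta
    pipeline_config(raw)
  }, error = function(e) e)
  if (inherits(conf, "error"))
    return(fail(paste0("configuration error: ", conditionMessage(conf)), 1L))
  res <- tryCatch({
    switch(cmd,
      run = , search = , quant = , report = run_pipeline(conf),
      simulate = {
        dir.create(conf$output_dir, showWarnings = FALSE, recursive = TRUE)
        sim <- if (conf$preset == "igm_yeast") {
          do.call(simulate_interference_mixture,
                  c(list(seed = conf$seed), conf$sim))$sps
        } else {
          simulate_run(do.call(sim_config, c(list(seed = conf$seed), conf$sim)))
        }
        write_mgf(sim$run, file.path(conf$output_dir, "simulated_run.mgf"))
        export_ground_truth(sim, file.path(conf$output_dir, "ground_truth.tsv"))
        write_fasta(sim$proteins, file.path(conf$output_dir, "proteins.fasta"))
        export_sim_config(sim$cfg, file.path(conf$output_dir, "sim_config.json"))
        conf$output_dir
      },
      merge = {
        run <- read_run(conf$input$run)
        pseudo <- build_pseudo_spectra(run, conf$merge)
        dir.create(conf$output_dir, showWarnings = FALSE, recursive = TRUE)
        write_mgf(pseudo, file.path(conf$output_dir, "pseudo_spectra.mgf"))
        write_merge_report(pseudo, file.path(conf$output_dir, "merge_report.tsv"))
        conf$output_dir
      })
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(fail(paste0("runtime error: ", conditionMessage(res)), 2L))
  invisible(0L)
}
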