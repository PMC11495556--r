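## End-to-end orchestration: ingest -> dedup/filter -> descriptives ->
## SOC & PT screening -> unexpected flags -> time to onset, with a run
## manifest that makes every record drop auditable.

#' Default pipeline configuration
#'
#' @return a list with every recognised configuration field set to its
#'   default; see [run_pipeline()] for the meaning of each field.
#' @export
default_pipeline_config <- function() {
  list(
    input = NULL,            # list(demo=,drug=,reac=,ther=,outc=) file paths
    synthetic = NULL,        # list of synthetic_config() arguments
    target_names = NULL,     # character vector, required
    meddra_map = NULL,       # path, or NULL when synthetic supplies one
    label_pts = NULL,        # path to one-PT-per-line file, optional
    exclusions = "default",  # "default", NULL/"none", or path/vector
    role = "PS",
    substring = FALSE,
    year_field = "fda_dt",
    unit = "drug_event_pair",
    zero_cell = "undefined",
    top_n_countries = 5,
    bin_edges = c(30, 60, 90, 180, 360),
    seed = 1L,
    out_dir = NULL
  )
}

read_term_file <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

resolve_exclusions <- function(excl) {
  if (is.null(excl) || identical(excl, "none")) return(NULL)
  if (identical(excl, "default")) return(default_exclusions())
  if (length(excl) == 1L && file.exists(excl)) return(read_term_file(excl))
  as.character(excl)
}

#' Run the full signal-detection pipeline
#'
#' Stages: (1) ingest the five quarterly tables (or generate a synthetic
#' dataset when the config carries a `synthetic` block); (2) deduplicate
#' cases, flag target primary-suspect reports, standardise PTs/SOCs;
#' (3) clinical-characteristics table; (4) disproportionality screening at
#' SOC and PT level with the four algorithms and signal criteria;
#' (5) unexpected-signal flagging against a label-PT list; (6) time to
#' onset.  All tabular outputs are CSV; the manifest (JSON) records input
#' checksums, per-stage counts, the config snapshot, seed and version.
#'
#' @param config a list (see [default_pipeline_config()]) or the path of a
#'   JSON file holding one.  Required fields: `target_names`, and either
#'   `input` (five file paths) or `synthetic`; `meddra_map` is required with
#'   `input`.
#' @param stages subset of `c("ingest", "descriptives", "screen", "tto")`;
#'   `"ingest"` is always implied.
#' @return (invisibly) a list with `acases`, `characteristics`,
#'   `signals_soc`, `signals_pt`, `unexpected`, `tto`, `tto_summary`,
#'   `manifest`, and `out_dir` when files were written.
#' @export
run_pipeline <- function(config,
                         stages = c("descriptives", "screen", "tto")) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      config_error(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  stages <- match.arg(stages, c("ingest", "descriptives", "screen", "tto"),
                      several.ok = TRUE)
  if (is.null(cfg$target_names) || !length(cfg$target_names))
    config_error("config must name at least one target drug (target_names)")
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    config_error("config must supply either 'input' file paths or a 'synthetic' block")

  manifest <- list(tool = "faersignal",
                   version = as.character(utils::packageVersion("faersignal")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), c("input"))])

  ## stage: ingest
  if (!is.null(cfg$synthetic)) {
    syn_args <- cfg$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- cfg$seed
    if (!is.null(syn_args$planted))
      syn_args$planted <- unlist(syn_args$planted)
    scfg <- do.call(synthetic_config, syn_args)
    gen <- generate_dataset(scfg)
    bundle <- gen$bundle
    map <- gen$map
    manifest$synthetic_seed <- scfg$seed
  } else {
    paths <- cfg$input
    bundle <- read_quarter_tables(paths, quarter_label =
                                    cfg$quarter_label %||% "input")
    if (is.null(cfg$meddra_map))
      config_error("config must supply 'meddra_map' with file input")
    map <- read_meddra_map(cfg$meddra_map)
    manifest$inputs <- lapply(paths, function(pp)
      list(path = pp, md5 = unname(tools::md5sum(pp))))
  }
  manifest$ingest_log <- bundle$log

  acases <- assemble_case_table(bundle, cfg$target_names, map,
                                role = cfg$role, substring = cfg$substring,
                                year_field = cfg$year_field)
  manifest$counts <- acases$manifest

  res <- list(acases = acases, manifest = manifest)

  if ("descriptives" %in% stages) {
    res$characteristics <- summarize_characteristics(
      acases, top_n_countries = cfg$top_n_countries)
  }

  if ("screen" %in% stages) {
    excl <- resolve_exclusions(cfg$exclusions)
    label_pts <- if (!is.null(cfg$label_pts)) {
      if (length(cfg$label_pts) == 1L && file.exists(cfg$label_pts))
        read_term_file(cfg$label_pts) else as.character(cfg$label_pts)
    } else NULL
    res$signals_soc <- screen_signals(acases, level = "SOC", unit = cfg$unit,
                                      zero_cell = cfg$zero_cell,
                                      exclusions = NULL)
    sig_pt <- screen_signals(acases, level = "PT", unit = cfg$unit,
                             zero_cell = cfg$zero_cell, exclusions = excl)
    sig_pt <- flag_unexpected(sig_pt, label_pts)
    res$signals_pt <- sig_pt
    res$unexpected <- sig_pt[!is.na(sig_pt$unexpected) & sig_pt$unexpected, ,
                             drop = FALSE]
    manifest$counts$n_significant_pt <- sum(sig_pt$significant, na.rm = TRUE)
    manifest$counts$n_soc_observed <- nrow(res$signals_soc)
  }

  if ("tto" %in% stages) {
    tto <- compute_tto(acases)
    res$tto <- tto
    res$tto_summary <- summarize_tto(tto, bin_edges = cfg$bin_edges)
    manifest$counts$n_tto_computable <- sum(!is.na(tto$tto_days))
    manifest$tto_exclusions <- as.list(table(tto$excluded_reason))
  }
  res$manifest <- manifest

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) utils::write.csv(
      df, file.path(cfg$out_dir, name), row.names = FALSE, na = "")
    if (!is.null(res$characteristics))
      wcsv(res$characteristics, "characteristics.csv")
    if (!is.null(res$signals_soc)) wcsv(res$signals_soc, "signals_soc.csv")
    if (!is.null(res$signals_pt)) wcsv(res$signals_pt, "signals_pt.csv")
    if (!is.null(res$unexpected)) wcsv(res$unexpected, "unexpected.csv")
    if (!is.null(res$tto)) {
      wcsv(res$tto, "tto_cases.csv")
      s <- res$tto_summary
      wcsv(cbind(data.frame(n = s$n, median = s$median), s$bins),
           "tto_summary.csv")
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
    res$out_dir <- cfg$out_dir
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `generate` (emit a synthetic dataset), `ingest` (parse and
#' preprocess only), `screen`, `tto`, `report` (descriptives), `all` (the
#' full pipeline).  Flags: `--config FILE` (JSON), `--drug-name NAME`
#' (repeatable), `--unit report|pair`, `--zero-cell undefined|haldane`,
#' `--label-pts FILE`, `--exclude FILE`, `--seed INT`, `--out DIR`.
#' Exit status: 0 success, 2 configuration error, 3 data error.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status, invisibly.  When called from `Rscript` the status is
#'   raised via `quit()` unless `args` was supplied explicitly.
#' @export
faers_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args))
      config_error("usage: faersignal <generate|ingest|report|screen|tto|all> [flags]")
    sub <- args[[1]]
    rest <- args[-1]
    if (!sub %in% c("generate", "ingest", "report", "screen", "tto", "all"))
      config_error(sprintf("unknown subcommand '%s'", sub))
    flags <- list()
    i <- 1L
    while (i <= length(rest)) {
      key <- rest[[i]]
      if (!startsWith(key, "--"))
        config_error(sprintf("unexpected argument '%s'", key))
      if (i + 1L > length(rest))
        config_error(sprintf("flag '%s' needs a value", key))
      val <- rest[[i + 1L]]
      nm <- substring(key, 3L)
      if (nm == "drug-name") flags$target_names <- c(flags$target_names, val)
      else flags[[gsub("-", "_", nm)]] <- val
      i <- i + 2L
    }
    cfg <- if (!is.null(flags$config)) {
      if (!file.exists(flags$config))
        config_error(sprintf("config file not found: %s", flags$config))
      jsonlite::read_json(flags$config, simplifyVector = TRUE)
    } else list()
    if (!is.null(flags$target_names)) cfg$target_names <- flags$target_names
    if (!is.null(flags$unit))
      cfg$unit <- c(report = "report", pair = "drug_event_pair",
                    drug_event_pair = "drug_event_pair")[[flags$unit]]
    if (!is.null(flags$zero_cell)) cfg$zero_cell <- flags$zero_cell
    if (!is.null(flags$label_pts)) cfg$label_pts <- flags$label_pts
    if (!is.null(flags$exclude)) cfg$exclusions <- flags$exclude
    if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
    if (!is.null(flags$out)) cfg$out_dir <- flags$out

    if (sub == "generate") {
      if (is.null(cfg$out_dir)) config_error("generate requires --out DIR")
      syn_args <- cfg$synthetic %||% list()
      if (is.null(syn_args$seed)) syn_args$seed <- cfg$seed %||% 1L
      if (!is.null(syn_args$planted))
        syn_args$planted <- unlist(syn_args$planted)
      gen <- generate_dataset(do.call(synthetic_config, syn_args),
                              dir = cfg$out_dir)
      message(sprintf("wrote synthetic dataset (%d reports) to %s",
                      gen$config$n_reports, cfg$out_dir))
    } else {
      stages <- switch(sub,
        ingest = "ingest",
        report = "descriptives",
        screen = "screen",
        tto = "tto",
        all = c("descriptives", "screen", "tto"))
      run_pipeline(cfg, stages = stages)
      message(sprintf("pipeline '%s' finished", sub))
    }
    0L
  },
  faers_config_error = function(e) { message("config error: ",
                                             conditionMessage(e)); 2L },
  faers_data_error = function(e) { message("data error: ",
                                           conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
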