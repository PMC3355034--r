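# Results serialisation: deterministic file names, publication-precision
# CSV cells, and a run manifest per output directory.

write_manifest <- function(out_dir, files, seed = NULL, config_path = NULL,
                           subcommand = NULL) {
  manifest <- list(
    package = "azolecea",
    version = as.character(utils::packageVersion("azolecea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    subcommand = subcommand,
    seed = seed,
    config = if (!is.null(config_path))
      list(path = config_path,
           md5 = unname(tools::md5sum(config_path))) else NULL,
    files = files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

#' Write analysis results to an output directory
#'
#' Serialises any of the package's result objects with deterministic file
#' names (CSV for tables, JSON for summaries) and writes a `manifest.json`
#' recording package version, seed and config checksum.  The directory is
#' created if missing.
#'
#' @param x A `base_case_result`, `dsa_result`, `psa_result`,
#'   `crossover_result`, `recovery_report`, or plain data frame.
#' @param out_dir Output directory.
#' @param seed,config_path,subcommand Optional provenance recorded in the
#'   manifest.
#' @return Invisibly, the vector of files written (manifest included).
#' @export
write_results <- function(x, out_dir, seed = NULL, config_path = NULL,
                          subcommand = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(out_dir, name)
  files <- character()
  put_csv <- function(df, name) {
    write.csv(df, fp(name), row.names = FALSE)
    files <<- c(files, name)
  }
  if (inherits(x, "base_case_result")) {
    put_csv(x$table, "base_case.csv")
    put_csv(acute_outcome_table(x$acute), "acute_outcomes.csv")
    subs <- attr(x$config, "substitutions")
    if (!is.null(subs) && nrow(subs)) put_csv(subs, "effective_values.csv")
  } else if (inherits(x, "dsa_result")) {
    put_csv(as.data.frame(x), "dsa.csv")
  } else if (inherits(x, "psa_result")) {
    put_csv(x$draws, "psa_draws.csv")
    put_csv(ceac(x), "ceac.csv")
    jsonlite::write_json(
      list(n_draws = x$n_draws, seed = x$seed,
           p_cost_saving = x$p_cost_saving,
           threshold = x$threshold,
           p_below_threshold = x$p_below_threshold),
      fp("psa_summary.json"), auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, "psa_summary.json")
  } else if (inherits(x, "crossover_result")) {
    put_csv(x$table, "crossover.csv")
    jsonlite::write_json(
      list(dp_base = x$dp_base, dp_star = x$dp_star, status = x$status,
           threshold = x$threshold),
      fp("crossover_summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    files <- c(files, "crossover_summary.json")
  } else if (inherits(x, "recovery_report")) {
    put_csv(x$replicates, "recovery_replicates.csv")
    jsonlite::write_json(
      list(truth = x$truth, bias = x$bias, coverage = x$coverage),
      fp("recovery_summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    files <- c(files, "recovery_summary.json")
  } else if (is.data.frame(x)) {
    put_csv(x, "results.csv")
  } else {
    stop("no serialisation rule for class ", paste(class(x), collapse = "/"))
  }
  write_manifest(out_dir, files, seed = seed, config_path = config_path,
                 subcommand = subcommand)
  invisible(file.path(out_dir, c(files, "manifest.json")))
}
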