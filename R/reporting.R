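file_hash <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

write_manifest <- function(out_dir, files, config = NULL, life_table = NULL,
                           seed = NULL) {
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    software = paste0("protonCEA ",
                      as.character(utils::packageVersion("protonCEA"))),
    config = list(path = config, md5 = file_hash(config)),
    life_table = list(path = life_table, md5 = file_hash(life_table)),
    seed = seed,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = file_hash(f)))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  path
}

resolve_inputs <- function(config, life_table) {
  p <- if (is.null(config)) default_params() else load_params(config)
  lt <- if (is.null(life_table)) synthetic_lifetable()
        else load_life_table(life_table)
  list(params = p, life_table = lt)
}

write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  path
}

#' Run the base-case analysis and write its report files
#'
#' Orchestrates a deterministic base-case run: resolves the parameter
#' configuration (defaults, optionally overridden by a YAML file) and the
#' life table, fits the model, and writes to `out_dir`:
#' `ce_results.csv` (per-index cost/QALY/ICER table), `trace_xrt.csv` and
#' `trace_pt.csv` (mixed state traces), `params.json` (resolved parameter
#' provenance dump) and `manifest.json` (input hashes and output list).
#' The resolved parameter set is echoed to `message()` unless `quiet`.
#'
#' @param config Optional path to a YAML configuration file.
#' @param life_table Optional path to a life-table CSV.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress the parameter echo.
#' @return Invisibly, a list with the fitted `cea` object and the written
#'   file paths.
#' @export
run_base_case <- function(config = NULL, life_table = NULL, out_dir,
                          quiet = FALSE) {
  inp <- resolve_inputs(config, life_table)
  if (!quiet)
    message(paste(utils::capture.output(print(inp$params)), collapse = "\n"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- cea(inp$params, inp$life_table)
  files <- character()
  f <- file.path(out_dir, "ce_results.csv")
  utils::write.csv(as.data.frame(fit), f, row.names = FALSE)
  files <- c(files, f)
  files <- c(files,
             write_trace_csv(fit$traces$XRT, file.path(out_dir, "trace_xrt.csv")),
             write_trace_csv(fit$traces$PT, file.path(out_dir, "trace_pt.csv")))
  files <- c(files, params_to_json(inp$params, file.path(out_dir, "params.json")))
  write_manifest(out_dir, files, config = config, life_table = life_table)
  invisible(list(fit = fit, files = files))
}

#' Run the sensitivity analyses and write their report files
#'
#' Orchestrates the uncertainty analyses: a one-way (tornado) analysis
#' per utility index, a triangular-distribution Monte Carlo PSA, and the
#' acceptability curves.  Writes to `out_dir`: `tornado_<index>.csv` per
#' index, `psa_samples.csv` (one row per draw and index with the drawn
#' values), `ceac.csv` (per-index and integrated curves), `params.json`
#' and `manifest.json`.
#'
#' @inheritParams run_base_case
#' @param n Number of PSA draws per utility index.
#' @param seed Integer seed for the PSA.
#' @return Invisibly, a list with the `cea_psa`, `cea_ceac` and tornado
#'   objects and the written file paths.
#' @export
run_sensitivity <- function(config = NULL, life_table = NULL, out_dir,
                            n = 10000, seed = 1L, quiet = FALSE) {
  inp <- resolve_inputs(config, life_table)
  if (!quiet)
    message(paste(utils::capture.output(print(inp$params)), collapse = "\n"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  tornados <- list()
  for (ix in utility_indexes()) {
    tor <- one_way(inp$params, inp$life_table, ix)
    f <- file.path(out_dir,
                   sprintf("tornado_%s.csv", gsub("[^A-Za-z0-9]", "", ix)))
    utils::write.csv(as.data.frame(tor), f, row.names = FALSE)
    files <- c(files, f)
    tornados[[ix]] <- tor
  }
  psa <- run_psa(inp$params, inp$life_table, n = n, seed = seed)
  f <- file.path(out_dir, "psa_samples.csv")
  utils::write.csv(as.data.frame(psa), f, row.names = FALSE)
  files <- c(files, f)
  curve <- ceac(psa)
  f <- file.path(out_dir, "ceac.csv")
  utils::write.csv(as.data.frame(curve), f, row.names = FALSE)
  files <- c(files, f)
  files <- c(files, params_to_json(inp$params, file.path(out_dir, "params.json")))
  write_manifest(out_dir, files, config = config, life_table = life_table,
                 seed = seed)
  invisible(list(psa = psa, ceac = curve, tornado = tornados, files = files))
}
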