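# Configuration files, result serialization and run manifests.

#' Load a simulation configuration
#'
#' Reads a flat YAML file of configuration keys mirroring the
#' [sim_config()] fields (with `steps` for the time horizon) plus the
#' optional DFE parameters `p`, `f`, `n`, `s`, and applies programmatic
#' overrides on top (overrides win over file values, file values over
#' defaults). With no file and no overrides the result is the default
#' study configuration.
#'
#' @param path Optional path to a YAML file.
#' @param overrides Named list of values overriding the file.
#' @return List with `config` (a [sim_config()]) and `dfe` (a
#'   [dfe_params()] or `NULL` when no DFE keys were given).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    # quote bare keys before parsing: single-letter keys such as N and n
    # are YAML 1.1 booleans and would otherwise collide
    txt <- readLines(path, warn = FALSE)
    txt <- sub("^(\\s*)([A-Za-z_][A-Za-z0-9_.]*)(\\s*):",
               "\\1\"\\2\":", txt)
    vals <- yaml::yaml.load(paste(txt, collapse = "\n"))
    if (!is.list(vals)) stop("config file must be a mapping", call. = FALSE)
  }
  vals <- modifyList(vals, overrides)
  dfe_keys <- c("p", "f", "n", "s")
  dfe <- NULL
  if (all(dfe_keys %in% names(vals))) {
    dfe <- dfe_params(vals$p, vals$f, vals$n, vals$s)
  } else if (any(dfe_keys %in% names(vals))) {
    stop("incomplete DFE specification: need all of p, f, n, s",
         call. = FALSE)
  }
  cfg_keys <- names(formals(sim_config))
  cfg_args <- vals[intersect(names(vals), cfg_keys)]
  unknown <- setdiff(names(vals), c(cfg_keys, dfe_keys))
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  config <- tryCatch(do.call(sim_config, cfg_args), error = function(e)
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE))
  list(config = config, dfe = dfe)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run byte-for-byte: the
#' full configuration, DFE, base seed and package version.
#'
#' @param config A [sim_config()].
#' @param dfe Optional [dfe_params()].
#' @param seed_base Base seed of the run.
#' @param extra Named list of additional fields to record.
#' @return A `gb_manifest` list.
#' @export
run_manifest <- function(config, dfe = NULL, seed_base = NULL,
                         extra = list()) {
  m <- list(
    package = "genebirth",
    version = as.character(packageVersion("genebirth")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed_base = seed_base,
    config = unclass(config),
    dfe = if (!is.null(dfe)) unclass(as_dfe_params(dfe)))
  m <- c(m, extra)
  class(m) <- "gb_manifest"
  m
}

#' Write result tables and a manifest to a directory
#'
#' Each named element of `tables` is written as `<name>.csv` with a
#' stable column order; the manifest (if any) goes to `manifest.json`.
#' Re-running with identical inputs overwrites identically.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @param manifest Optional [run_manifest()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, manifest = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(manifest)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
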