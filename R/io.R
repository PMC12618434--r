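# Model/arrangement file parsing and report writing.

#' Read a model definition from JSON
#'
#' Expected schema: `{"variables": [...], "parameters": [...],
#' "rates": ["expr", ...], "fixed": {"name": "p/q", ...}, "name": "..."}`.
#' Expressions follow the exact-rational grammar (no float literals).
#'
#' @param path file path.
#' @return an [ode_system].
#' @export
parse_model_file <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (fld in c("variables", "parameters", "rates"))
    if (is.null(spec[[fld]])) stop("model file missing field '", fld, "'",
                                   call. = FALSE)
  ode_system(spec$variables, spec$parameters, spec$rates,
             fixed = as.list(spec$fixed), name = spec$name)
}

#' Write a model definition to JSON
#' @param sys an [ode_system].
#' @param path output path.
#' @export
write_model_file <- function(sys, path) {
  spec <- list(name = sys$name, variables = sys$variables,
               parameters = sys$parameters_all, rates = sys$rates_text)
  if (length(sys$fixed_text)) spec$fixed <- sys$fixed_text
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a raw hypersurface arrangement from JSON
#'
#' Schema: `{"parameters": [...], "polynomials": ["expr", ...]}`.
#' Polynomials are normalized (squarefree irreducible factors).
#'
#' @param path file path.
#' @param normalized skip factorization when the inputs are already
#'   irreducible.
#' @return a [hypersurface_arrangement()].
#' @export
parse_arrangement_file <- function(path, normalized = FALSE) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  hypersurface_arrangement(as.list(spec$polynomials), spec$parameters,
                           normalized = normalized)
}

#' Write an arrangement (with degrees and provenance) to JSON
#' @param arr a [hypersurface_arrangement()].
#' @param path output path.
#' @export
write_arrangement_file <- function(arr, path) {
  jsonlite::write_json(list(
    parameters = arr$parameters,
    polynomials = vapply(arr$polys, qp_string, ""),
    degrees = arr$degrees,
    coordinate = arr$is_coordinate,
    provenance = arr$provenance), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a region report as CSV + JSON with stable field ordering
#'
#' @param report a `region_report` (or plain data.frame of regions).
#' @param path output basename; writes `<path>.csv` and `<path>.json`.
#' @return the paths written, invisibly.
#' @export
write_region_report <- function(report, path) {
  if (is.null(report) || nrow(report) == 0)
    stop("empty region report", call. = FALSE)
  df <- as.data.frame(report)
  df <- df[order(df$region), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(nrow(df), " regions written; stable sets: ",
          paste(sort(unique(df$stable_set)), collapse = ", "))
  invisible(c(csv, js))
}

#' Write a run manifest next to outputs
#' @param config named list (seeds, tolerances, mode ...).
#' @param path output path (JSON).
#' @export
write_manifest <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("stabscape"))
  config$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
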