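#' Write a run manifest
#'
#' Each analysis step records what produced its outputs: the command
#' name, parameters, seed, input-file checksums, package version,
#' timestamp and the list of output files. Deterministic steps re-run
#' with the same manifest reproduce their outputs byte-identically.
#'
#' @param out_dir directory the manifest describes; written as
#'   `manifest.json` inside it.
#' @param command short name of the analysis step.
#' @param parameters named list of parameter values.
#' @param inputs character vector of input file paths (checksummed).
#' @param outputs character vector of output file paths (must exist and
#'   be non-empty).
#' @param seed the seed used, or `NULL` for deterministic steps.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, parameters = list(),
                               inputs = character(0),
                               outputs = character(0), seed = NULL) {
  missing_out <- outputs[!file.exists(outputs) | file.size(outputs) == 0L]
  if (length(missing_out)) {
    stop("declared outputs missing or empty: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  manifest <- list(
    command = command,
    parameters = parameters,
    seed = seed,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL,
    outputs = basename(outputs),
    tool = "barcodegap",
    version = as.character(utils::packageVersion("barcodegap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
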