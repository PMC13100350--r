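#' Write a reproducibility manifest for a pipeline run
#'
#' Records the command, its parameters, md5 digests of the input files, the
#' package version, a timestamp and the seed as `run_manifest.json` in the
#' output directory, so that a run can be reproduced and its inputs
#' verified.
#'
#' @param command name of the pipeline step.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths (digested with md5).
#' @param outdir directory receiving the manifest.
#' @param seed integer seed used, or `NA` for deterministic steps.
#' @return The manifest path, invisibly.
#' @export
writeRunManifest <- function(command, params, inputs, outdir, seed = NA_integer_) {
    digests <- vapply(inputs, function(f)
        if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
        character(1))
    manifest <- list(
        command = command,
        parameters = params,
        inputs = as.list(stats::setNames(digests, inputs)),
        package_version = as.character(utils::packageVersion("RegRatio")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed)
    path <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}
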