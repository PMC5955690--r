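# File-based stage execution with integrity manifests.
#
# Each stage writes its outputs plus a manifest recording the MD5 of every
# input and output file, the stage parameters and seed, and the MD5 of the
# upstream manifest, so stage chains are hash-linked and tampering with an
# intermediate is detected before recomputation.

#' Run a pipeline stage with a manifest
#'
#' Verifies the upstream manifest (if given), checks that the declared
#' input files still match their recorded hashes, runs `fn(output_dir)`,
#' and writes `<output_dir>/manifest.json`.
#'
#' @param name stage name.
#' @param fn function of one argument (the output directory) performing the
#'   work; its return value is stored in the result.
#' @param output_dir directory for outputs (created if needed).
#' @param inputs character vector of input file paths.
#' @param params list of stage parameters recorded in the manifest.
#' @param seed seed recorded in the manifest.
#' @param upstream_manifest path of the upstream stage's manifest, if any.
#' @return list with `value` (fn's return) and `manifest` (path).
#' @export
run_stage <- function(name, fn, output_dir, inputs = character(0),
                      params = list(), seed = NA_integer_,
                      upstream_manifest = NULL) {
  if (!is.null(upstream_manifest)) verify_manifest(upstream_manifest)
  miss <- inputs[!file.exists(inputs)]
  if (length(miss))
    stop(sprintf("stage '%s': missing upstream artifact(s): %s", name,
                 paste(miss, collapse = ", ")))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  before <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
  value <- fn(output_dir)
  after <- setdiff(list.files(output_dir, recursive = TRUE, full.names = TRUE),
                   file.path(output_dir, "manifest.json"))
  manifest <- list(
    stage = name,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    params = params,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(after)),
    upstream = if (!is.null(upstream_manifest))
      unname(tools::md5sum(upstream_manifest)) else NULL,
    package_version = as.character(utils::packageVersion("oscmotor"))
  )
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(value = value, manifest = mpath)
}

#' Verify a stage manifest
#'
#' Recomputes the MD5 of every recorded output file and fails with an
#' integrity error on any mismatch or missing file.
#'
#' @param manifest_path path to a `manifest.json`.
#' @return `TRUE` invisibly.
#' @export
verify_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path))
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (f in names(m$outputs)) {
    if (!file.exists(f))
      stop(sprintf("integrity error: output '%s' of stage '%s' is missing",
                   f, m$stage))
    h <- unname(tools::md5sum(f))
    if (!identical(h, m$outputs[[f]]))
      stop(sprintf("integrity error: output '%s' of stage '%s' was modified",
                   f, m$stage))
  }
  invisible(TRUE)
}

#' Write / read a pipeline configuration as YAML
#'
#' Sources and behavior parameters are stored structurally; reading
#' reconstructs the `pipeline_config`.
#'
#' @param cfg a `pipeline_config`; @param path file path.
#' @export
write_config <- function(cfg, path) {
  # yaml drops names of atomic vectors; store named vectors as maps
  named2list <- function(x) {
    if (is.list(x)) lapply(x, named2list)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  ser <- unclass(cfg)
  ser$behavior <- named2list(unclass(ser$behavior))
  ser$sources <- lapply(ser$sources, function(s) named2list(unclass(s)))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- replica_config()
  for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  unvec <- function(v) if (is.list(v)) unlist(v) else v
  cfg$behavior <- do.call(behavior_params, lapply(y$behavior, unvec))
  cfg$sources <- lapply(y$sources, function(s) {
    env <- lapply(s$envelope, function(e)
      list(times = as.numeric(unlist(e$times)), amps = as.numeric(unlist(e$amps))))
    if (!length(env)) env <- NULL
    source_spec(
      center_electrode = s$center_electrode,
      spatial_width = s$spatial_width,
      band = as.numeric(unlist(s$band)),
      amplitude = s$amplitude,
      envelope = env,
      lateralization = s$lateralization,
      phase_mode = s$phase_mode,
      seed_source = s$seed_source,
      concentration = unvec(s$concentration)
    )
  })
  class(cfg) <- "pipeline_config"
  cfg
}
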