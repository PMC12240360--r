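#' Read a model/ensemble configuration file
#'
#' YAML configuration with up to two sections: `params` (flat key-value
#' `mest_params` fields; absent keys take the reference defaults) and
#' `ensemble` ([ensemble_spec()] fields). Unknown keys in either section are
#' rejected with a message listing them.
#'
#' @param path file path.
#' @param strict enforce the documented study ranges on the parameters
#'   (see [as_mest_params()]).
#' @return list with elements `params` (a `mest_params` or `NULL`) and
#'   `ensemble` (an `ensemble_spec` or `NULL`).
#' @export
read_mest_config <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c("params", "ensemble"))
  if (length(bad))
    stop("unknown config sections: ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- if (!is.null(cfg$params))
    as_mest_params(cfg$params, strict = strict) else NULL
  ens <- NULL
  if (!is.null(cfg$ensemble)) {
    known <- names(formals(ensemble_spec))
    extra <- setdiff(names(cfg$ensemble), known)
    if (length(extra))
      stop("unknown ensemble keys: ", paste(extra, collapse = ", "),
           call. = FALSE)
    ens <- do.call(ensemble_spec, cfg$ensemble)
  }
  list(params = params, ensemble = ens)
}

#' Write a configuration file
#'
#' @param params optional [mest_params()].
#' @param ensemble optional [ensemble_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mest_config <- function(path, params = NULL, ensemble = NULL) {
  cfg <- list()
  if (!is.null(params)) cfg$params <- as.list(params)
  if (!is.null(ensemble)) cfg$ensemble <- unclass(ensemble)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Run manifest
#'
#' Records, for one analysis session, the commands run, the seeds used and
#' every file written, so a run can be reproduced bit-identically.
#'
#' @param path where the manifest JSON will be written.
#' @return an environment of class `mest_manifest`; pass it to
#'   [write_results()] or record entries with [manifest_record()].
#' @export
mest_manifest <- function(path) {
  m <- new.env(parent = emptyenv())
  m$path <- path
  m$created <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  m$version <- as.character(utils::packageVersion("mestweb"))
  m$entries <- list()
  class(m) <- "mest_manifest"
  m
}

#' @param manifest a [mest_manifest()].
#' @param command free-text description of the producing call.
#' @param seed seed(s) used, recorded before execution.
#' @param files output files produced.
#' @param meta any further metadata (parameters, tolerances, grids).
#' @rdname mest_manifest
#' @export
manifest_record <- function(manifest, command, seed = NULL, files = character(),
                            meta = NULL) {
  stopifnot(inherits(manifest, "mest_manifest"))
  manifest$entries[[length(manifest$entries) + 1L]] <-
    list(command = command, seed = seed, files = as.character(files),
         meta = meta, time = format(Sys.time(), tz = "UTC", usetz = TRUE))
  manifest_write(manifest)
  invisible(manifest)
}

manifest_write <- function(manifest) {
  jsonlite::write_json(
    list(created = manifest$created, package_version = manifest$version,
         entries = manifest$entries),
    manifest$path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest$path)
}

#' @export
print.mest_manifest <- function(x, ...) {
  cat(sprintf("Run manifest (%s): %d entries\n", x$path, length(x$entries)))
  for (e in x$entries)
    cat(sprintf("  %s [seed %s] -> %s\n", e$command,
                paste(e$seed, collapse = ","),
                paste(e$files, collapse = ", ")))
  invisible(x)
}

manifest_files <- function(manifest) {
  unlist(lapply(manifest$entries, `[[`, "files"))
}

#' Write an analysis result to disk
#'
#' Writes tidy CSV (one row per observation, documented column names) with a
#' JSON metadata sidecar (`<stem>_meta.json`) and, when a manifest is given,
#' records both files in it. Supported inputs: `mest_sim` (columns `time,
#' variable, value`), `mest_bifurcation` (`g, type, value`),
#' `mest_stability_map` (`u1, beta, feasible, re_lambda_max`),
#' `persistence_surface` (surface columns plus a `<stem>_replicates.csv`
#' replicate manifest), `mest_loops` (JSON only), and plain data.frames.
#'
#' @param x the result object.
#' @param path output file (`.csv`, or `.json` for loop lists).
#' @param manifest optional [mest_manifest()].
#' @param meta optional extra metadata for the sidecar.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(x, path, manifest = NULL, meta = NULL) {
  files <- character()
  stem <- sub("\\.[^.]+$", "", path)
  sidecar <- paste0(stem, "_meta.json")
  info <- list(class = class(x)[1], written = format(Sys.time(), tz = "UTC"),
               meta = meta)
  if (inherits(x, "mest_sim")) {
    utils::write.csv(as.data.frame(x, long = TRUE), path, row.names = FALSE)
    info$params <- as.list(x$params)
    info$tolerances <- list(rtol = x$rtol, atol = x$atol, method = x$method)
    files <- path
  } else if (inherits(x, "mest_bifurcation")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    files <- path
  } else if (inherits(x, "mest_stability_map")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    msk <- attr(x, "mask")
    info$mask <- names(msk)[msk]
    info$scope <- attr(x, "scope")
    files <- path
  } else if (inherits(x, "persistence_surface")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    repfile <- paste0(stem, "_replicates.csv")
    utils::write.csv(attr(x, "replicates"), repfile, row.names = FALSE)
    info$spec <- unclass(attr(x, "spec"))
    files <- c(path, repfile)
  } else if (inherits(x, "mest_loops")) {
    jsonlite::write_json(lapply(unclass(x), function(l)
      list(nodes = l$nodes, signs = l$signs, sign = l$sign,
           length = l$length)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- path
  } else if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
    files <- path
  } else {
    stop("no writer for objects of class ", class(x)[1], call. = FALSE)
  }
  jsonlite::write_json(info, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  files <- c(files, sidecar)
  if (!is.null(manifest))
    manifest_record(manifest, command = paste("write_results", class(x)[1]),
                    files = files, meta = meta)
  invisible(files)
}
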