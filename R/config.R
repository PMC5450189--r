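#' Analysis configuration
#'
#' Bundles the sectoring and reproducibility settings shared by the pipeline
#' stages. Sector counts outside the conventional 12--24 range are allowed
#' but trigger a warning, since very coarse or very fine sectoring changes
#' the granularity at which coat patchiness is resolved.
#'
#' @param n_sectors number of angular sectors (integer).
#' @param angle_origin_deg angle of sector 0's start edge, degrees. 0 points
#'   along +x (image right), increasing counter-clockwise.
#' @param alignment_target_sector sector index profile maxima are rotated to
#'   by [align_profile()].
#' @param random_seed integer seed for stochastic stages.
#' @param output_dir directory for command-line outputs.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(n_sectors = 24L, angle_origin_deg = 0,
                            alignment_target_sector = 0L,
                            random_seed = 1L, output_dir = ".") {
  n_sectors <- as.integer(n_sectors)
  stopifnot(length(n_sectors) == 1L, n_sectors >= 2L)
  if (n_sectors < 12L || n_sectors > 24L) {
    warning("n_sectors = ", n_sectors,
            " is outside the conventional 12-24 range")
  }
  structure(
    list(n_sectors = n_sectors,
         angle_origin_deg = angle_origin_deg,
         alignment_target_sector = as.integer(alignment_target_sector),
         random_seed = as.integer(random_seed),
         output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from JSON
#'
#' Fields absent from the file keep their defaults; `overrides` (typically
#' parsed command-line flags) take precedence over file values.
#'
#' @param path JSON file path, or `NULL` for defaults only.
#' @param overrides named list of values overriding the file.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path)
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  keep <- intersect(names(vals), names(formals(analysis_config)))
  do.call(analysis_config, vals[keep])
}

#' Write a run log capturing seed, configuration hash and package version
#'
#' Every command-line run drops a `run_log.json` in its output directory so
#' stochastic results can be regenerated exactly.
#'
#' @param config an [analysis_config()].
#' @param dir output directory.
#' @param extra named list of additional fields to record.
#' @return path of the log file, invisibly.
#' @export
write_run_log <- function(config, dir, extra = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  log <- c(list(
    package = "vesicoat",
    version = as.character(utils::packageVersion("vesicoat")),
    seed = config$random_seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp))
  ), extra)
  unlink(tmp)
  path <- file.path(dir, "run_log.json")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
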