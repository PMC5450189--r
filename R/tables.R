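#' Write homogeneous result records to a CSV file
#'
#' Records are serialized as comma-delimited UTF-8 text with a mandatory
#' header row, "." decimal separator and full (round-trippable) numeric
#' precision. Row order is the input order, so output is deterministic.
#'
#' @param records a data.frame, or a list of named lists sharing one schema.
#' @param path output file path; its directory must exist.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!dir.exists(dirname(path))) {
    stop("output directory does not exist: ", dirname(path))
  }
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L) {
      stop("cannot infer a schema from an empty list; pass a data.frame ",
           "with the desired columns")
    }
    schema <- names(records[[1]])
    for (i in seq_along(records)) {
      ni <- names(records[[i]])
      if (!identical(sort(ni), sort(schema))) {
        bad <- union(setdiff(ni, schema), setdiff(schema, ni))
        stop("records do not share one schema; offending fields: ",
             paste(bad, collapse = ", "))
      }
    }
    df <- do.call(rbind, lapply(records, function(r) {
      as.data.frame(r[schema], stringsAsFactors = FALSE)
    }))
  } else {
    stop("`records` must be a data.frame or a list of named lists")
  }
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      sprintf("%.17g", col)
    } else {
      as.character(col)
    }
  })
  lines <- c(
    paste(names(df), collapse = ","),
    if (nrow(df) > 0L) do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read table: file does not exist: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read FRAP traces from CSV
#'
#' Expected columns: `trace_id`, `time_s`, `intensity`, `phase`
#' (values `"pre"` or `"post"`).
#'
#' @param path CSV file path.
#' @return a list of [frap_trace()] objects, one per `trace_id`.
#' @export
read_frap_traces <- function(path) {
  df <- read_table_csv(path)
  need <- c("trace_id", "time_s", "intensity", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("FRAP trace table is missing columns: ", paste(miss, collapse = ", "))
  }
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time_s), ]
    frap_trace(d$trace_id[1], d$time_s, d$intensity,
               phase = d$phase)
  })
}

#' Read retention curves from CSV
#'
#' Expected columns: `strain`, `replicate_id`, `time_min`, `fluorescence`.
#'
#' @param path CSV file path.
#' @return a list of normalized retention curves (see [normalize_retention()]).
#' @export
read_retention_curves <- function(path) {
  df <- read_table_csv(path)
  need <- c("strain", "replicate_id", "time_min", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("retention table is missing columns: ", paste(miss, collapse = ", "))
  }
  key <- paste(df$strain, df$replicate_id, sep = "\r")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_min), ]
    normalize_retention(d$time_min, d$fluorescence,
                        replicate_id = d$replicate_id[1],
                        strain = d$strain[1])
  })
  names(out) <- NULL
  out
}

#' Flatten a sector profile into tabular records
#'
#' @param profile a [sector_profile()] result.
#' @param vesicle_id optional identifier column.
#' @return data.frame with columns `sector_index`, `angle_start_deg`,
#'   `channel`, `signal` (plus `vesicle_id` when given).
#' @export
profile_to_table <- function(profile, vesicle_id = NULL) {
  stopifnot(inherits(profile, "sector_profile"))
  n <- profile$n_sectors
  w <- 360 / n
  chans <- profile$channel_names
  df <- data.frame(
    sector_index = rep(seq_len(n) - 1L, times = length(chans)),
    angle_start_deg = rep((profile$angle_origin_deg + (seq_len(n) - 1L) * w) %% 360,
                          times = length(chans)),
    channel = rep(chans, each = n),
    signal = as.vector(profile$signal),
    stringsAsFactors = FALSE
  )
  if (!is.null(vesicle_id)) df <- cbind(vesicle_id = vesicle_id, df)
  df
}
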