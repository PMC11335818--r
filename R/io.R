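#' Read a timestamped CSV table
#'
#' Columns are matched by name, so header order is free. Timestamps must be
#' monotone non-decreasing; a violation is reported with the file line
#' number of the offending row (header = line 1).
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param time_col Name of the timestamp column checked for monotonicity
#'   (`NULL` to skip).
#' @return A data frame.
#' @export
read_timeseries_csv <- function(path, required = character(),
                                time_col = "timestamp") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(time_col) && time_col %in% names(df) && nrow(df) > 1) {
    bad <- which(diff(df[[time_col]]) < 0)
    if (length(bad)) {
      stop("non-monotone timestamp in ", path, " at line ", bad[1] + 2,
           " (value ", df[[time_col]][bad[1] + 1], " follows ",
           df[[time_col]][bad[1]], ")")
    }
  }
  df
}

#' Marker, eye, target and pose table I/O
#'
#' Thin schema-checked wrappers around CSV reading/writing. All numeric
#' fields round-trip losslessly (values are written with full precision).
#'
#' @param path File path.
#' @return The table read, or (for writers) the input invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_marker_csv <- function(path) {
  read_timeseries_csv(path, c("timestamp", paste0("x", 0:3), paste0("y", 0:3),
                              "valid"))
}

#' @rdname table_io
#' @export
read_eye_csv <- function(path) {
  read_timeseries_csv(path, c("timestamp", "x_px", "y_px", "valid"))
}

#' @rdname table_io
#' @export
read_targets_csv <- function(path) {
  read_timeseries_csv(path, c("t0", "t1", "azimuth_deg"), time_col = "t0")
}

#' @rdname table_io
#' @param df Table to write.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Camera model JSON I/O
#'
#' Schema: `{"width": px, "height": px, "focal_length_px": px,
#' "principal_point": [x, y]}`.
#'
#' @param path File path.
#' @return A [camera_model()].
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("width", "height", "focal_length_px")
  if (!all(need %in% names(j))) {
    stop("camera JSON must contain fields: ", paste(need, collapse = ", "))
  }
  camera_model(j$width, j$height, focal_length = j$focal_length_px,
               principal_point = j$principal_point)
}

#' @rdname read_camera_json
#' @param camera A [camera_model()] to write.
#' @export
write_camera_json <- function(camera, path) {
  stopifnot(inherits(camera, "camera_model"))
  jsonlite::write_json(
    list(width = camera$width, height = camera$height,
         focal_length_px = camera$focal_length,
         principal_point = camera$principal_point),
    path, auto_unbox = TRUE, digits = NA)
  invisible(camera)
}

#' Gaze record CSV I/O
#'
#' Schema: `time,E_deg,H_deg,G_deg,dE_dps,dH_dps,dG_dps,valid`. The rate and
#' the calibration constant are stored in `# key: value` comment lines ahead
#' of the header and restored on read.
#'
#' @param record A `gaze_record`.
#' @param path File path.
#' @return The record (invisibly for the writer).
#' @export
write_gaze_record_csv <- function(record, path) {
  stopifnot(inherits(record, "gaze_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %.17g", attr(record, "rate_hz")),
               sprintf("# c_deg: %.17g", attr(record, "c_deg"))), con)
  utils::write.csv(format(as.data.frame(record), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(record)
}

#' @rdname write_gaze_record_csv
#' @export
read_gaze_record_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("# ", key, ":"), meta, fixed = TRUE)]
    if (!length(ln)) return(NA_real_)
    as.numeric(sub(paste0("# ", key, ": "), "", ln[1], fixed = TRUE))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "E_deg", "H_deg", "G_deg", "dE_dps", "dH_dps", "dG_dps",
            "valid")
  if (!all(need %in% names(df))) {
    stop("not a gaze record CSV (missing columns): ", path)
  }
  df$valid <- as.logical(df$valid)
  attr(df, "rate_hz") <- get_meta("rate_hz")
  attr(df, "c_deg") <- get_meta("c_deg")
  class(df) <- c("gaze_record", "data.frame")
  df
}

#' Write a JSON report
#'
#' @param x A list (e.g. quality report or coordination summary).
#' @param path File path.
#' @return `x` invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(x)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    y <- lapply(x, strip_classes)
    names(y) <- names(x)
    return(y)
  }
  x
}
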