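# Readers and writers for the OpenSim-style .sto/.mot text-table dialect and
# an equivalent plain-CSV form.  The table always starts with a `time`
# column; angles are written in radians unless `in_degrees = TRUE`, in which
# case columns whose name ends in `_angle` are converted at the boundary.
# Numeric round trips are lossless to at least 12 significant digits.

STO_DIGITS <- "%.15g"

#' Write a time-series table as an OpenSim-style .sto/.mot file
#'
#' @param x A data frame whose first column is `time`, or a [gait_trial()]
#'   (converted with [as.data.frame.gait_trial()]).
#' @param path Output file path.
#' @param name Table name written in the header (defaults to the file name).
#' @param in_degrees Write `_angle` columns in degrees (`inDegrees=yes`)?
#' @return `path`, invisibly.
#' @export
write_sto <- function(x, path, name = basename(path), in_degrees = FALSE) {
  df <- as.data.frame(x)
  if (names(df)[1L] != "time") stop_invalid("first column must be `time`")
  if (in_degrees) {
    ang <- grepl("_angle$", names(df))
    df[ang] <- lapply(df[ang], function(v) v * 180 / pi)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    name,
    sprintf("nRows=%d", nrow(df)),
    sprintf("nColumns=%d", ncol(df)),
    sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
    "endheader",
    paste(names(df), collapse = "\t")
  ), con)
  body <- do.call(paste, c(lapply(df, function(v) sprintf(STO_DIGITS, v)),
                           sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an OpenSim-style .sto/.mot file
#'
#' @param path File path.
#' @return A data frame with the table columns; attributes `name` and
#'   `in_degrees` carry the header fields.  Angle columns are converted back
#'   to radians when the file declares `inDegrees=yes`.
#' @export
read_sto <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path)
  end <- which(lines == "endheader")[1L]
  if (is.na(end)) stop_invalid("%s: missing `endheader` line", path)
  header <- lines[seq_len(end - 1L)]
  in_degrees <- any(grepl("^inDegrees\\s*=\\s*yes$", header))
  cols <- strsplit(lines[end + 1L], "\t", fixed = TRUE)[[1L]]
  df <- utils::read.table(
    text = lines[-seq_len(end + 1L)], sep = "\t",
    col.names = cols, colClasses = "numeric"
  )
  if (in_degrees) {
    ang <- grepl("_angle$", names(df))
    df[ang] <- lapply(df[ang], function(v) v * pi / 180)
  }
  attr(df, "name") <- header[1L]
  attr(df, "in_degrees") <- in_degrees
  df
}

#' Write a trial table as plain CSV
#'
#' Identical columns to the .sto dialect, comma-separated with a header row.
#'
#' @inheritParams write_sto
#' @export
write_trial_csv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(
    do.call(cbind, lapply(df, function(v) sprintf(STO_DIGITS, v))),
    path, sep = ",", quote = FALSE, row.names = FALSE, col.names = names(df)
  )
  invisible(path)
}

#' Read a plain-CSV trial table
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  utils::read.csv(path, colClasses = "numeric")
}

#' Rebuild a gait trial from a table plus metadata
#'
#' Event indices are recomputed from the stance-fraction and ankle-angle
#' columns, so a written-then-read trial is equivalent to the original.
#'
#' @param df Data frame as produced by [read_sto()] or [read_trial_csv()].
#' @param side `"left"` or `"right"`.
#' @param subject_mass Body mass [kg].
#' @param subject_height Body height [m].
#' @return A [gait_trial()].
#' @export
as_gait_trial <- function(df, side, subject_mass, subject_height) {
  gait_trial(
    time = df$time, stance_fraction = df$stance_fraction,
    ankle_angle = df$ankle_angle, knee_angle = df$knee_angle,
    hip_angle = df$hip_angle,
    ankle_moment = df$ankle_moment, knee_moment = df$knee_moment,
    hip_moment = df$hip_moment,
    side = side, subject_mass = subject_mass, subject_height = subject_height
  )
}
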