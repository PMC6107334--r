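#' Cell track tables
#'
#' A track table is the substrate of all motility analysis: one row per cell
#' per frame, with 3D positions in micrometres, time in minutes, a cell class
#' (`dc_candidate`, `interfollicular` or `reference` for non-motile fiducial
#' cells used in drift correction) and any number of logical marker columns
#' (e.g. `sox2`, `fucci_g1`, `tdtomato`).
#'
#' Required columns: `track_id`, `frame` (0-based integer), `time_min`,
#' `x_um`, `y_um`, `z_um`, `cell_class`. Within a track, frames must be
#' strictly increasing and `time_min = frame * frame_interval`.
#'
#' @param df a data.frame with at least the required columns.
#' @return a validated `track_table` (a data.frame subclass).
#' @export
track_table <- function(df) {
  req <- c("track_id", "frame", "time_min", "x_um", "y_um", "z_um", "cell_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stopf("track table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df$track_id <- as.character(df$track_id)
  df$frame <- as.integer(df$frame)
  df$cell_class <- as.character(df$cell_class)
  bad_class <- setdiff(unique(df$cell_class),
                       c("dc_candidate", "interfollicular", "reference"))
  if (length(bad_class)) {
    stopf("unknown cell_class value(s): %s", paste(bad_class, collapse = ", "))
  }
  pos <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(pos))) stopf("track positions must be finite")
  ord <- order(df$track_id, df$frame)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  # frames strictly increasing within track
  dup <- stats::ave(df$frame, df$track_id, FUN = function(f) c(1L, diff(f)))
  if (any(dup <= 0L)) {
    bad <- unique(df$track_id[dup <= 0L])
    stopf("non-monotone frames within track(s): %s", paste(bad, collapse = ", "))
  }
  class(df) <- unique(c("track_table", class(df)))
  df
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d tracks, %d rows, frames %d..%d\n",
              length(unique(x$track_id)), nrow(x), min(x$frame), max(x$frame)))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$cell_class[!duplicated(x$track_id)])),
                            table(x$cell_class[!duplicated(x$track_id)])), collapse = ", ")))
  mk <- marker_columns(x)
  if (length(mk)) cat("  markers:", paste(mk, collapse = ", "), "\n")
  invisible(x)
}

#' Names of logical marker columns in a track table or scene cell table
#' @param df a track_table or cell data.frame.
#' @return character vector of marker column names.
#' @export
marker_columns <- function(df) {
  fixed <- c("track_id", "frame", "time_min", "x_um", "y_um", "z_um",
             "cell_class", "id")
  cand <- setdiff(names(df), fixed)
  cand[vapply(df[cand], is.logical, logical(1))]
}

#' Read / write track tables as delimited text
#'
#' The native dialect is comma-separated UTF-8 with a mandatory header
#' `track_id,frame,time_min,x_um,y_um,z_um,cell_class,<marker columns>`.
#' A `column_map` turns other dialects (e.g. TrackMate spot exports) into the
#' native one: a named character vector `c(native_name = "FILE_COLUMN", ...)`.
#' When the source has no `time_min`, supply `frame_interval` to derive it.
#'
#' @param path file path.
#' @param column_map optional named character vector remapping file columns to
#'   native names.
#' @param frame_interval minutes per frame, used to reconstruct `time_min`
#'   (and/or `frame`) when the source dialect lacks one of them.
#' @param cell_class default cell class for dialects that do not carry one.
#' @return a `track_table`.
#' @export
read_tracks <- function(path, column_map = NULL, frame_interval = NULL,
                        cell_class = "dc_candidate") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (native in names(column_map)) {
      src <- column_map[[native]]
      if (!src %in% names(raw)) stopf("column_map source column '%s' not in file", src)
      raw[[native]] <- raw[[src]]
    }
    raw <- raw[, !(names(raw) %in% setdiff(unname(column_map), names(column_map))),
               drop = FALSE]
  }
  if (!"time_min" %in% names(raw) && "frame" %in% names(raw) &&
      !is.null(frame_interval)) {
    raw$time_min <- raw$frame * frame_interval
  }
  if (!"frame" %in% names(raw) && "time_min" %in% names(raw) &&
      !is.null(frame_interval)) {
    raw$frame <- as.integer(round(raw$time_min / frame_interval))
  }
  if (!"cell_class" %in% names(raw)) raw$cell_class <- cell_class
  req <- c("track_id", "frame", "time_min", "x_um", "y_um", "z_um", "cell_class")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stopf("file '%s' is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  # marker columns arrive as "TRUE"/"FALSE" or 0/1
  for (nm in setdiff(names(raw), req)) {
    v <- raw[[nm]]
    if (is.logical(v)) next
    if (is.numeric(v) && all(v %in% c(0, 1, NA))) raw[[nm]] <- v == 1
    if (is.character(v) && all(toupper(v) %in% c("TRUE", "FALSE", "NA")))
      raw[[nm]] <- as.logical(v)
  }
  track_table(raw[, c(req, setdiff(names(raw), req)), drop = FALSE])
}

#' @rdname read_tracks
#' @param tracks a `track_table`.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_table"))
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Translate every frame by a cumulative drift vector
#'
#' Adds `k * drift_per_frame` to every position at frame `k`, emulating
#' translational tissue drift during time-lapse acquisition. All other fields
#' are unchanged; `correct_drift()` inverts it when reference cells exist.
#'
#' @param tracks a `track_table`.
#' @param drift_per_frame numeric length-3 drift per frame, micrometres.
#' @return the drifted `track_table`.
#' @export
inject_drift <- function(tracks, drift_per_frame) {
  stopifnot(inherits(tracks, "track_table"), length(drift_per_frame) == 3)
  if (nrow(tracks) == 0L) stopf("track table is empty")
  k <- tracks$frame
  tracks$x_um <- tracks$x_um + k * drift_per_frame[1]
  tracks$y_um <- tracks$y_um + k * drift_per_frame[2]
  tracks$z_um <- tracks$z_um + k * drift_per_frame[3]
  tracks
}
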