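#' Read and write cell-tracking tables
#'
#' Track tables are exchanged as tab-delimited text with a header row
#' (`cell_id, t_h, x_um, y_um, r_um, phenotype`); event logs as
#' (`cell_id, t_h, from, to`).
#'
#' @param tracks A [as_track_table()].
#' @param path File path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   `track_table`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.table(as.data.frame(tracks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param spheroid_radius,frame_interval Metadata not stored in the delimited
#'   file; `frame_interval` is inferred from the time grid when omitted.
#' @export
read_tracks <- function(path, spheroid_radius, frame_interval = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_track_table(df, spheroid_radius = spheroid_radius,
                 frame_interval = frame_interval)
}

#' Read and write exact transition event logs
#'
#' @param events Data frame with `cell_id`, `t_h`, `from`, `to`.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read and write rate matrices in the 4x4 interchange format
#'
#' Tab-delimited 4x4 table with phenotype labels as header row and first
#' column; rows are source states, columns destinations.
#'
#' @param rates A [rate_matrix()].
#' @param path File path.
#' @export
write_rate_matrix <- function(rates, path) {
  m <- unclass(rate_matrix(rates))
  utils::write.table(data.frame(phenotype = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  rate_matrix(m)
}

write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
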