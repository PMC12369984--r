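#' Cell-tracking tables
#'
#' A `track_table` is a data frame of per-cell, per-frame observations with
#' columns `cell_id`, `t_h` (time in hours on the frame grid), `x_um`, `y_um`
#' (position), `r_um` (distance to the spheroid center) and `phenotype`
#' (one of BB, AE, LA, FP, or INTERMEDIATE for unclassifiable frames).
#' It carries the spheroid radius (um) and frame interval (h) as attributes;
#' invasion depth is `r_um - spheroid_radius`.
#'
#' @param x Data frame with at least `cell_id`, `t_h`, `r_um`, `phenotype`
#'   (missing `x_um`/`y_um` are filled assuming motion along the x axis).
#' @param spheroid_radius Spheroid radius r_s, um.
#' @param frame_interval Frame interval, h; inferred from the time grid when
#'   omitted.
#' @return Object of class `track_table` (a data frame).
#' @export
as_track_table <- function(x, spheroid_radius, frame_interval = NULL) {
  x <- as.data.frame(x)
  need <- c("cell_id", "t_h", "r_um", "phenotype")
  if (!all(need %in% names(x)))
    stop("track table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(x$x_um)) x$x_um <- x$r_um
  if (is.null(x$y_um)) x$y_um <- rep(0, nrow(x))
  x <- x[order(x$cell_id, x$t_h),
         c("cell_id", "t_h", "x_um", "y_um", "r_um", "phenotype")]
  rownames(x) <- NULL
  bad <- !x$phenotype %in% c(PHENOTYPES, INTERMEDIATE) | is.na(x$phenotype)
  if (any(bad))
    stop("unlabeled or unknown phenotype rows for cell_ids: ",
         paste(unique(x$cell_id[bad]), collapse = ", "), call. = FALSE)
  if (is.null(frame_interval)) {
    dts <- diff(sort(unique(x$t_h)))
    frame_interval <- if (length(dts)) min(dts) else NA_real_
  }
  structure(x, spheroid_radius = spheroid_radius,
            frame_interval = frame_interval,
            class = c("track_table", "data.frame"))
}

#' @export
print.track_table <- function(x, n = 6, ...) {
  cat(sprintf(paste0("Track table: %d cells, %d frame rows, r_s = %g um,",
                     " frame = %g h\n"),
              length(unique(x$cell_id)), nrow(x), attr(x, "spheroid_radius"),
              attr(x, "frame_interval")))
  print(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

spheroid_radius_of <- function(tracks, r_s = NULL) {
  if (!is.null(r_s)) return(r_s)
  rs <- attr(tracks, "spheroid_radius")
  if (is.null(rs))
    stop("spheroid radius unknown: supply r_s or use a track_table",
         call. = FALSE)
  rs
}

frame_interval_of <- function(tracks, frame_interval = NULL) {
  if (!is.null(frame_interval)) return(frame_interval)
  dt <- attr(tracks, "frame_interval")
  if (is.null(dt) || is.na(dt))
    stop("frame interval unknown: supply frame_interval", call. = FALSE)
  dt
}

# consecutive within-cell frame pairs: data frame with from/to labels, the
# earlier frame's time, radius and step (delta r)
frame_pairs <- function(tracks) {
  tracks <- tracks[order(tracks$cell_id, tracks$t_h), ]
  n <- nrow(tracks)
  if (n < 2L)
    return(data.frame(cell_id = integer(), t_h = numeric(), r_um = numeric(),
                      from = character(), to = character(), dr = numeric()))
  same <- tracks$cell_id[-1] == tracks$cell_id[-n]
  data.frame(cell_id = tracks$cell_id[-n][same],
             t_h = tracks$t_h[-n][same],
             r_um = tracks$r_um[-n][same],
             from = tracks$phenotype[-n][same],
             to = tracks$phenotype[-1][same],
             dr = (tracks$r_um[-1] - tracks$r_um[-n])[same])
}
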