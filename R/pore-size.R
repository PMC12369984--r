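#' Pore sizes of a fibrous matrix image by maximal inscribed disks
#'
#' Binarizes a grayscale matrix image into fiber and pore phases, computes
#' the Euclidean distance transform of the pore phase (distance to the
#' nearest fiber pixel), and reports one diameter per pore region (connected
#' component of the pore phase): twice the maximum of the distance transform
#' within the region — the diameter of the largest disk inscribed in that
#' pore — converted to micrometers.
#'
#' @param image Numeric matrix of intensities, an `EBImage::Image`, or a path
#'   to a TIFF/PNG/JPEG file.
#' @param pixel_size Physical pixel size, um/px (default 1).
#' @param threshold `"otsu"` (default, automatic global threshold) or a
#'   numeric cutoff on the same scale as the image.
#' @param fiber Which phase is the fiber signal: `"bright"` (default,
#'   reflection imaging convention) or `"dark"`.
#' @param min_area Minimum pore area in px to report (default 4; suppresses
#'   single-pixel binarization speckle).
#' @return Object of class `pore_size_result`: list with `diameters_um`
#'   (one per pore, descending), `mean_um`, `median_um`, `n_pores`,
#'   `fiber_fraction` and `threshold`.
#' @examples
#' img <- generate_fiber_image(n_fibers = 30, seed = 1)
#' pore_sizes(img, pixel_size = 0.5)
#' @export
pore_sizes <- function(image, pixel_size = 1, threshold = "otsu",
                       fiber = c("bright", "dark"), min_area = 4) {
  fiber <- match.arg(fiber)
  stopifnot(pixel_size > 0)
  img <- load_image(image)
  if (any(!is.finite(img))) stop("image contains non-finite intensities",
                                 call. = FALSE)
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0)
      stop("binarization failed: image is constant", call. = FALSE)
    scaled <- (img - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled))
    fiber_mask <- scaled > thr
    threshold_used <- rng[1] + thr * diff(rng)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    fiber_mask <- img > threshold
    threshold_used <- threshold
  }
  if (fiber == "dark") fiber_mask <- !fiber_mask
  if (all(fiber_mask))
    stop("binarization produced no pore pixels (all fiber)", call. = FALSE)
  if (!any(fiber_mask))
    stop("binarization produced no fiber pixels (all pore)", call. = FALSE)
  pore_mask <- !fiber_mask
  dist <- EBImage::distmap(EBImage::Image(pore_mask * 1))
  labels <- EBImage::bwlabel(EBImage::Image(pore_mask * 1))
  lab <- as.integer(EBImage::imageData(labels))
  dd <- as.numeric(EBImage::imageData(dist))
  keep <- lab > 0L
  area <- tabulate(lab[keep])
  max_dist <- vapply(split(dd[keep], lab[keep]), max, numeric(1))
  ok <- area >= min_area
  diameters <- sort(2 * max_dist[ok] * pixel_size, decreasing = TRUE)
  structure(list(diameters_um = unname(diameters),
                 mean_um = mean(diameters), median_um = stats::median(diameters),
                 n_pores = length(diameters),
                 fiber_fraction = mean(fiber_mask),
                 threshold = threshold_used, pixel_size = pixel_size),
            class = "pore_size_result")
}

#' @export
print.pore_size_result <- function(x, ...) {
  cat(sprintf(paste0("Pore sizes from maximal inscribed disks: %d pores, ",
                     "mean %.2f um, median %.2f um\n"),
              x$n_pores, x$mean_um, x$median_um))
  cat(sprintf("Fiber area fraction %.3f (threshold %.4g, pixel %.3g um)\n",
              x$fiber_fraction, x$threshold, x$pixel_size))
  invisible(x)
}

#' @export
summary.pore_size_result <- function(object, ...) {
  print(object)
  print(summary(object$diameters_um))
  invisible(object)
}

load_image <- function(image) {
  if (is.character(image)) {
    img <- EBImage::readImage(image)
    img <- EBImage::imageData(img)
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean) # to gray
    return(img)
  }
  if (inherits(image, "Image")) {
    img <- EBImage::imageData(image)
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    return(img)
  }
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("image must be a numeric matrix, an EBImage Image, or a file path",
       call. = FALSE)
}

#' Generate a synthetic fiber image
#'
#' Renders `n_fibers` randomly placed straight fibers (full-width chords at a
#' uniform random point and orientation) of the given width, bright on a dark
#' background, as a stand-in for confocal reflection images of a collagen
#' network. Seeded and reproducible.
#'
#' @param n_fibers Number of fibers (>= 0).
#' @param fiber_width Fiber width, px (default 3).
#' @param size Image side, px (default 256; square).
#' @param seed Integer seed.
#' @param intensity Fiber intensity in \\[0, 1\\] (default 1; background 0).
#' @return Numeric `size` x `size` matrix in \\[0, 1\\].
#' @export
generate_fiber_image <- function(n_fibers, fiber_width = 3, size = 256,
                                 seed, intensity = 1) {
  stopifnot(n_fibers >= 0, fiber_width > 0, size >= 8)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  img <- matrix(0, size, size)
  if (n_fibers == 0) return(img)
  px <- matrix(rep(seq_len(size), size), size, size)       # row coord
  py <- matrix(rep(seq_len(size), each = size), size, size) # col coord
  for (i in seq_len(n_fibers)) {
    x0 <- stats::runif(1, 1, size); y0 <- stats::runif(1, 1, size)
    th <- stats::runif(1, 0, pi)
    d <- abs((px - x0) * sin(th) - (py - y0) * cos(th))
    img[d <= fiber_width / 2] <- intensity
  }
  img
}
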