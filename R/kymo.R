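# Kymograph construction: time-lapse stack + axon path -> calibrated 2-D
# (time x position) array oriented so that increasing position points away
# from the soma (anterograde).

PIXEL_SIZE_630X <- 0.160508  # um/pixel at 630x magnification

#' Construct a movie stack
#'
#' @param data 3-D numeric array `c(rows, cols, frames)`.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @return object of class `movie_stack`.
#' @export
movie_stack <- function(data, pixel_size, frame_interval) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d x %d pixels, %d frames (%.3g um/px, %.3g s/frame)\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Define an axon path
#'
#' @param x,y polyline vertex coordinates in pixels (1-based image
#'   coordinates; `x` = column, `y` = row). At least two vertices.
#' @param soma_end which end of the polyline faces the cell body:
#'   `"start"` or `"end"`.
#' @param sampling_width pixels sampled perpendicular to the path (odd).
#' @return object of class `axon_path`.
#' @export
axon_path <- function(x, y, soma_end = c("start", "end"), sampling_width = 5) {
  soma_end <- match.arg(soma_end)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (sum(seg) <= 0) stop("axon path has zero arc length", call. = FALSE)
  sampling_width <- check_count(sampling_width, "sampling_width", 1L)
  structure(list(x = as.numeric(x), y = as.numeric(y), soma_end = soma_end,
                 sampling_width = sampling_width),
            class = "axon_path")
}

#' Read an axon path from a two-column CSV of x,y vertices
#'
#' @param path CSV file with columns `x`, `y`.
#' @inheritParams axon_path
#' @export
read_axon_path <- function(path, soma_end = "start", sampling_width = 5) {
  df <- utils::read.csv(path)
  axon_path(df$x, df$y, soma_end = soma_end, sampling_width = sampling_width)
}

# Resample a polyline at 1-pixel arc-length steps. Returns points, unit
# tangents and normals at each sample.
resample_path <- function(path) {
  x <- path$x; y <- path$y
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_cols <- round(total)
  # sample at column midpoints: reversing the path then mirroring the columns
  # is an exact involution on this grid (s = 0.5, 1.5, ... is symmetric)
  s <- seq(0.5, by = 1, length.out = n_cols)
  px <- stats::approx(cum, x, xout = s, rule = 2)$y
  py <- stats::approx(cum, y, xout = s, rule = 2)$y
  # tangent by central differences
  tx <- c(px[2] - px[1], (px[-(1:2)] - px[1:(n_cols - 2)]) / 2,
          px[n_cols] - px[n_cols - 1])
  ty <- c(py[2] - py[1], (py[-(1:2)] - py[1:(n_cols - 2)]) / 2,
          py[n_cols] - py[n_cols - 1])
  norm <- sqrt(tx^2 + ty^2)
  norm[norm == 0] <- 1
  tx <- tx / norm; ty <- ty / norm
  list(x = px, y = py, nx = -ty, ny = tx, n_cols = n_cols)
}

# Bilinear intensity interpolation; coordinates outside the image raise an
# error (the path must lie within frame bounds).
bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  if (any(x < 1 - 1e-9) || any(x > nx + 1e-9) ||
      any(y < 1 - 1e-9) || any(y > ny + 1e-9))
    stop("axon path (with sampling width) lies outside image bounds",
         call. = FALSE)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Build a kymograph from a movie stack and an axon path
#'
#' The path is resampled at 1-pixel arc-length steps; at each sample the
#' maximum intensity over `sampling_width` pixels perpendicular to the path is
#' taken (maximum projection suits punctate cargo on a dim background). Rows
#' are frames, columns are positions along the path, and the column order is
#' normalized so that increasing column index points away from the soma, i.e.
#' anterograde motion has positive slope.
#'
#' @param stack a [movie_stack()].
#' @param path an [axon_path()].
#' @return object of class `kymograph`: list with `data` (frames x positions
#'   matrix), `pixel_size`, `frame_interval`.
#' @export
build_kymograph <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"), inherits(path, "axon_path"))
  rs <- resample_path(path)
  n_frames <- dim(stack$data)[3]
  offsets <- seq(-(path$sampling_width - 1) / 2, (path$sampling_width - 1) / 2)
  kymo <- matrix(0, n_frames, rs$n_cols)
  for (f in seq_len(n_frames)) {
    img <- stack$data[, , f]
    prof <- matrix(0, length(offsets), rs$n_cols)
    for (k in seq_along(offsets)) {
      prof[k, ] <- bilinear(img, rs$x + offsets[k] * rs$nx,
                            rs$y + offsets[k] * rs$ny)
    }
    kymo[f, ] <- apply(prof, 2, max)
  }
  if (path$soma_end == "end") kymo <- kymo[, rev(seq_len(ncol(kymo))), drop = FALSE]
  structure(list(data = kymo, pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions (%.4g um wide, %.4g s)\n",
              nrow(x$data), ncol(x$data), kymograph_length(x),
              nrow(x$data) * x$frame_interval))
  invisible(x)
}

#' Physical length of a kymograph in um
#' @param kymo a `kymograph`.
#' @export
kymograph_length <- function(kymo) ncol(kymo$data) * kymo$pixel_size

#' Convert pixel distances to um
#'
#' @param pixels pixel count (>= 0, vectorized).
#' @param pixel_size um per pixel; default is the 630x magnification
#'   calibration, 0.160508 um/pixel.
#' @return distance in um.
#' @export
calibrate_distance <- function(pixels, pixel_size = PIXEL_SIZE_630X) {
  if (any(pixels < 0)) stop("pixel count must be non-negative", call. = FALSE)
  check_positive(pixel_size, "pixel_size")
  pixels * pixel_size
}

#' Write a kymograph to disk
#'
#' Writes the raw matrix as a 32-bit float TIFF and, optionally, an 8-bit PNG
#' preview (contrast-stretched).
#'
#' @param kymo a `kymograph`.
#' @param tiff_path output TIFF path; `NULL` to skip.
#' @param png_path output PNG path; `NULL` to skip.
#' @export
write_kymograph <- function(kymo, tiff_path = NULL, png_path = NULL) {
  if (!is.null(tiff_path)) write_tiff(kymo$data, tiff_path, bits = 32L)
  if (!is.null(png_path)) {
    rng <- range(kymo$data)
    scaled <- if (diff(rng) > 0) (kymo$data - rng[1]) / diff(rng) else
      kymo$data * 0
    grDevices::png(png_path, width = ncol(kymo$data), height = nrow(kymo$data))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(scaled)[, nrow(scaled):1], col = grDevices::gray.colors(256),
                    axes = FALSE, useRaster = TRUE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(kymo)
}
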