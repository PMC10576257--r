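# Spot (puncta) detection and two-channel colocalization for lysosomal
# rupture assays: connected-component detection above a robust background
# threshold, one-to-one greedy matching by center distance, and per-cell
# rupture metrics (percent of LAMP1 puncta colocalized with an autophagy
# marker, and colocalized-marker fluorescence per cell).

#' Spot detection configuration
#'
#' The three parameters mirror the fixed analysis parameters of a
#' ComDet-style workflow and must be held identical across all images of one
#' experiment.
#'
#' @param min_size minimum punctum area, pixels.
#' @param intensity_threshold detection threshold in robust SDs above
#'   background (median + k * MAD).
#' @param coloc_max_distance maximum center-to-center distance (pixels) for a
#'   cross-channel pair.
#' @param smooth_sigma Gaussian matched-filter sigma (pixels) applied before
#'   thresholding and segmentation; intensities are still measured on the raw
#'   image. 0 (default) disables smoothing so size/threshold semantics are
#'   exact on sharp objects; use the point-spread sigma on noisy data.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(min_size = 4, intensity_threshold = 5,
                             coloc_max_distance = 4, smooth_sigma = 0) {
  min_size <- check_count(min_size, "min_size", 1L)
  check_positive(intensity_threshold, "intensity_threshold")
  check_positive(coloc_max_distance, "coloc_max_distance")
  check_nonneg(smooth_sigma, "smooth_sigma")
  structure(list(min_size = min_size,
                 intensity_threshold = intensity_threshold,
                 coloc_max_distance = coloc_max_distance,
                 smooth_sigma = smooth_sigma),
            class = "detection_config")
}

# separable Gaussian blur with reflected edges
gaussian_blur <- function(img, sigma) {
  half <- ceiling(3 * sigma)
  kk <- exp(-(-half:half)^2 / (2 * sigma^2))
  kk <- kk / sum(kk)
  conv1 <- function(m) {
    # convolve each column, reflecting edges
    n <- nrow(m)
    pad <- rbind(m[half:1, , drop = FALSE], m,
                 m[n:(n - half + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(kk))
      out <- out + kk[o] * pad[(o - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# 4-connected component labeling by row-run scanning with union-find.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  next_label <- 0L
  for (r in seq_len(ny)) {
    c0 <- 1L
    while (c0 <= nx) {
      if (!mask[r, c0]) { c0 <- c0 + 1L; next }
      c1 <- c0
      while (c1 < nx && mask[r, c1 + 1L]) c1 <- c1 + 1L
      # labels of the run above this one
      up <- if (r > 1L) unique(labels[r - 1L, c0:c1]) else integer(0)
      up <- up[up > 0L]
      up <- unique(vapply(up, find, integer(1)))
      if (length(up) == 0L) {
        next_label <- next_label + 1L
        parent <- c(parent, next_label)
        lab <- next_label
      } else {
        lab <- min(up)
        for (u in up) parent[u] <- lab
      }
      labels[r, c0:c1] <- lab
      c0 <- c1 + 1L
    }
  }
  if (next_label > 0L) {
    roots <- vapply(seq_len(next_label), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  labels
}

#' Detect puncta in a single-channel image
#'
#' Pixels above `median + intensity_threshold * MAD` of the image are
#' segmented into 4-connected components; components of at least `min_size`
#' pixels are reported with intensity-weighted centroids and
#' background-subtracted integrated intensities.
#'
#' @param image 2-D numeric matrix.
#' @param config a [detection_config()].
#' @param background,background_sd optional externally measured background
#'   level and noise SD; by default both are estimated robustly from the image
#'   (median and MAD).
#' @return data.frame of class `puncta`: `id`, `x`, `y` (centroid, pixels),
#'   `area`, `integrated_intensity`, `mean_intensity`.
#' @export
detect_puncta <- function(image, config = detection_config(),
                          background = NULL, background_sd = NULL) {
  stopifnot(is.matrix(image))
  work <- if (config$smooth_sigma > 0)
    gaussian_blur(image, config$smooth_sigma) else image
  bg_w <- if (is.null(background)) stats::median(work) else background
  sdev <- if (is.null(background_sd)) stats::mad(work) else background_sd
  thr <- bg_w + config$intensity_threshold * sdev
  mask <- work > thr
  if (all(mask))
    stop("saturated image: every pixel is above threshold", call. = FALSE)
  bg <- stats::median(image)   # intensities measured on the raw image
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), integrated_intensity = numeric(0),
                      mean_intensity = numeric(0))
  if (!any(mask)) return(structure(empty, class = c("puncta", "data.frame")))
  labels <- label_components(mask)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  w <- pmax(image[idx] - bg, 0)
  area <- tabulate(lab)
  keep <- which(area >= config$min_size)
  if (length(keep) == 0L) return(structure(empty, class = c("puncta", "data.frame")))
  sum_w <- vapply(keep, function(l) sum(w[lab == l]), numeric(1))
  cx <- vapply(keep, function(l) sum(cols[lab == l] * w[lab == l]), numeric(1)) / sum_w
  cy <- vapply(keep, function(l) sum(rows[lab == l] * w[lab == l]), numeric(1)) / sum_w
  out <- data.frame(id = seq_along(keep), x = cx, y = cy,
                    area = area[keep], integrated_intensity = sum_w,
                    mean_intensity = sum_w / area[keep])
  structure(out, class = c("puncta", "data.frame"))
}

#' Match puncta across two channels by center distance
#'
#' One-to-one matching: candidate pairs with center distance <=
#' `max_distance` are accepted greedily in ascending distance order, each
#' punctum participating in at most one pair. On well-separated fields this
#' equals the optimal minimum-distance assignment.
#'
#' @param a,b `puncta` data.frames (or any data.frame with `x`, `y`).
#' @param max_distance maximum center distance, pixels (inclusive).
#' @return data.frame with `index_a`, `index_b`, `distance` (row indices into
#'   `a` and `b`).
#' @export
colocalize <- function(a, b, max_distance) {
  check_positive(max_distance, "max_distance")
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      distance = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  cand <- which(d <= max_distance, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  out <- vector("list", nrow(cand))
  n <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    n <- n + 1L
    out[[n]] <- data.frame(index_a = i, index_b = j, distance = d[i, j])
  }
  do.call(rbind, out[seq_len(n)])
}

#' Per-cell lysosomal rupture metrics
#'
#' For each cell ROI: puncta are assigned to ROIs by centroid (even-odd
#' point-in-polygon; a punctum inside several overlapping ROIs goes to the
#' first in list order). Marker (p62/LC3) puncta not colocalized with a LAMP1
#' punctum are treated as background and removed. Reported per cell: LAMP1
#' and marker counts, colocalized count, percent of LAMP1 puncta colocalized
#' (the rupture readout), and colocalized-marker integrated intensity (RFU).
#'
#' @param rois list of polygon data.frames with columns `x`, `y`.
#' @param lamp1 `puncta` for the lysosome channel.
#' @param marker `puncta` for the p62/LC3 channel.
#' @param config a [detection_config()] (supplies `coloc_max_distance`).
#' @return data.frame: `cell`, `n_lamp1`, `n_marker`, `n_coloc`,
#'   `percent_coloc`, `rfu` (one row per ROI).
#' @export
rupture_metrics <- function(rois, lamp1, marker, config = detection_config()) {
  stopifnot(is.list(rois))
  assign_roi <- function(p) {
    if (nrow(p) == 0) return(integer(0))
    roi_id <- rep(NA_integer_, nrow(p))
    for (ri in seq_along(rois)) {
      poly <- rois[[ri]]
      inside <- point_in_polygon(p$x, p$y, poly$x, poly$y)
      roi_id[is.na(roi_id) & inside] <- ri
    }
    if (anyNA(roi_id))
      message(sum(is.na(roi_id)), " puncta outside all ROIs excluded")
    roi_id
  }
  roi_l <- assign_roi(lamp1)
  roi_m <- assign_roi(marker)
  out <- lapply(seq_along(rois), function(ri) {
    l <- lamp1[which(roi_l == ri), , drop = FALSE]
    m <- marker[which(roi_m == ri), , drop = FALSE]
    pairs <- colocalize(l, m, config$coloc_max_distance)
    n_coloc <- nrow(pairs)
    data.frame(
      cell = ri, n_lamp1 = nrow(l), n_marker = nrow(m), n_coloc = n_coloc,
      percent_coloc = if (nrow(l) > 0) 100 * n_coloc / nrow(l) else NA_real_,
      rfu = if (n_coloc > 0)
        sum(m$integrated_intensity[pairs$index_b]) else 0)
  })
  do.call(rbind, out)
}

#' Focus-project a Z-stack to a single plane
#'
#' Substitute for proprietary best-focus projections: per-plane sharpness is
#' the variance of the discrete Laplacian. `method = "plane"` returns the
#' globally sharpest plane; `method = "pixel"` picks, per pixel, the plane
#' with the largest local (3x3) Laplacian energy.
#'
#' @param stack 3-D array `c(rows, cols, planes)`.
#' @param method `"plane"` or `"pixel"`.
#' @return 2-D matrix.
#' @export
focus_project <- function(stack, method = c("plane", "pixel")) {
  method <- match.arg(method)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  np <- dim(stack)[3]
  if (np == 1L) return(stack[, , 1])
  laplacian <- function(img) {
    ny <- nrow(img); nx <- ncol(img)
    l <- matrix(0, ny, nx)
    l[2:(ny - 1), 2:(nx - 1)] <-
      img[1:(ny - 2), 2:(nx - 1)] + img[3:ny, 2:(nx - 1)] +
      img[2:(ny - 1), 1:(nx - 2)] + img[2:(ny - 1), 3:nx] -
      4 * img[2:(ny - 1), 2:(nx - 1)]
    l
  }
  if (method == "plane") {
    sharp <- vapply(seq_len(np), function(p)
      stats::var(as.vector(laplacian(stack[, , p]))), numeric(1))
    return(stack[, , which.max(sharp)])
  }
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  energy <- array(0, dim = dim(stack))
  box3 <- function(m) {
    # 3x3 box sum via shifted adds (edges handled by zero padding)
    p <- matrix(0, ny + 2, nx + 2)
    p[2:(ny + 1), 2:(nx + 1)] <- m
    out <- matrix(0, ny, nx)
    for (dr in 0:2) for (dc in 0:2)
      out <- out + p[(1 + dr):(ny + dr), (1 + dc):(nx + dc)]
    out
  }
  for (p in seq_len(np)) energy[, , p] <- box3(laplacian(stack[, , p])^2)
  sharp <- vapply(seq_len(np), function(p)
    stats::var(as.vector(laplacian(stack[, , p]))), numeric(1))
  default_plane <- which.max(sharp)
  best <- apply(energy, c(1, 2), which.max)
  # zero-contrast pixels (uniform in every plane) carry no focus information;
  # fall back to the globally sharpest plane there
  no_info <- apply(energy, c(1, 2), max) == 0
  best[no_info] <- default_plane
  out <- matrix(0, ny, nx)
  for (p in seq_len(np)) {
    sel <- best == p
    out[sel] <- stack[, , p][sel]
  }
  out
}
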