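# Field-of-view intensity quantification: background-multiple thresholding
# (default 3x background) with per-cell normalization by a manual cell count.

#' Threshold-based field intensity statistics
#'
#' Applies a threshold of `multiplier * background` (default 3x) to the image
#' and reports average pixel intensity, integrated pixel intensity, and total
#' pixel area over the thresholded mask.
#'
#' @param image 2-D numeric matrix (a single plane; Z-stacks should be
#'   projected first, e.g. with [focus_project()]).
#' @param background background intensity estimate (> 0), e.g. from
#'   [estimate_background()].
#' @param multiplier threshold as a multiple of background (default 3).
#' @param whole_field if `TRUE`, `average` is computed over the whole field
#'   rather than above threshold (area and integrated are unchanged).
#' @return list of class `field_intensity`: `area` (pixels), `integrated`,
#'   `average` (`NA` when the mask is empty), `background`, `multiplier`.
#' @export
threshold_stats <- function(image, background, multiplier = 3,
                            whole_field = FALSE) {
  stopifnot(is.matrix(image))
  check_positive(background, "background")
  check_positive(multiplier, "multiplier")
  mask <- image >= multiplier * background
  area <- sum(mask)
  integrated <- if (area > 0) sum(image[mask]) else 0
  avg <- if (whole_field) mean(image)
         else if (area > 0) integrated / area else NA_real_
  structure(list(area = area, integrated = integrated, average = avg,
                 background = background, multiplier = multiplier),
            class = "field_intensity")
}

#' @export
print.field_intensity <- function(x, ...) {
  cat(sprintf("field_intensity: area %d px, integrated %.6g, average %s (%.3gx background %.4g)\n",
              x$area, x$integrated,
              if (is.na(x$average)) "NA" else sprintf("%.6g", x$average),
              x$multiplier, x$background))
  invisible(x)
}

#' Estimate image background
#'
#' Median over a user-specified cell-free rectangular region, or, with no
#' region, the image mode (most frequent rounded intensity) as a fallback.
#'
#' @param image 2-D numeric matrix.
#' @param roi optional `c(row_min, row_max, col_min, col_max)` of a cell-free
#'   region.
#' @return scalar background estimate.
#' @export
estimate_background <- function(image, roi = NULL) {
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L)
    return(stats::median(image[roi[1]:roi[2], roi[3]:roi[4]]))
  }
  tab <- table(round(image))
  as.numeric(names(tab)[which.max(tab)])
}

#' Relative fluorescence units per cell
#'
#' Integrated above-threshold intensity divided by the number of cells in the
#' field of view (counted manually from phase-contrast images).
#'
#' @param field a `field_intensity` (or a bare integrated-intensity value).
#' @param n_cells cell count (>= 1).
#' @return RFU per cell.
#' @export
per_cell_rfu <- function(field, n_cells) {
  n_cells <- check_count(n_cells, "n_cells", 1L)
  integrated <- if (inherits(field, "field_intensity")) field$integrated
                else field
  integrated / n_cells
}
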