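#' Per-eye fovea-referenced thickness grid
#'
#' Holds a rows x cols matrix of retinal thickness in axial pixels, with NA
#' marking missing (QC-failed or shifted-in) pixels, plus the physical pixel
#' scales and the eye side. Rows run superior to inferior, columns temporal
#' to nasal after anatomical alignment.
#'
#' @param values numeric matrix, axial px; NA = missing.
#' @param eye "left" or "right".
#' @param row_scale,col_scale physical pixel size, um.
#' @param fovea optional c(row, col) of the detected fovea (1-based).
#' @param id optional scan identifier.
#' @return An object of class `thickness_grid`.
#' @export
thickness_grid <- function(values, eye = c("right", "left"),
                           row_scale = 46.88, col_scale = 23.44,
                           fovea = NULL, id = NULL) {
  eye <- match.arg(eye)
  stopifnot(is.matrix(values), row_scale > 0, col_scale > 0)
  if (any(values <= 0, na.rm = TRUE)) {
    stop("thickness values must be positive where present")
  }
  if (!is.null(fovea)) {
    stopifnot(length(fovea) == 2,
              fovea[1] >= 1, fovea[1] <= nrow(values),
              fovea[2] >= 1, fovea[2] <= ncol(values))
  }
  structure(list(values = values, eye = eye, row_scale = row_scale,
                 col_scale = col_scale, fovea = fovea, id = id),
            class = "thickness_grid")
}

#' @export
print.thickness_grid <- function(x, ...) {
  cat(sprintf("thickness_grid: %d x %d px (%s eye), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$eye,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Complete individuals-by-pixels phenotype matrix
#'
#' The universal outcome object of the pipeline: one row per individual, one
#' column per retained pixel, no missing values (post imputation and eye
#' averaging).
#'
#' @param matrix numeric individuals x pixels matrix, axial px.
#' @param pixel_index data frame with columns `row`, `col` (0-based grid
#'   indices) and `row_mu`, `col_mu` (um from the fovea reference).
#' @param eye_code character per individual: "left", "right" or "mean".
#' @param row_scale,col_scale physical pixel size, um.
#' @return An object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(matrix, pixel_index, eye_code = NULL,
                          row_scale = 46.88, col_scale = 23.44) {
  stopifnot(is.matrix(matrix), !anyNA(matrix),
            nrow(pixel_index) == ncol(matrix),
            all(c("row", "col") %in% names(pixel_index)))
  if (is.null(eye_code)) eye_code <- rep("mean", nrow(matrix))
  stopifnot(length(eye_code) == nrow(matrix))
  if (!all(c("row_mu", "col_mu") %in% names(pixel_index))) {
    nr <- max(pixel_index$row) + 1L
    nc <- max(pixel_index$col) + 1L
    co <- grid_coords(nr, nc, row_scale, col_scale)
    pixel_index$row_mu <- co$row_mu[pixel_index$row + 1L]
    pixel_index$col_mu <- co$col_mu[pixel_index$col + 1L]
  }
  structure(list(matrix = matrix, pixel_index = pixel_index,
                 eye_code = eye_code, row_scale = row_scale,
                 col_scale = col_scale),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("cohort_matrix: %d individuals x %d pixels\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' OCT B-scan volume
#'
#' Stack of intensity images for one eye: slices (B-scans) x rows (axial,
#' anterior to posterior) x cols (A-scan locations).
#'
#' @param intensity 3-d numeric array, finite and non-negative.
#' @param axial_scale um per axial pixel.
#' @param eye "left" or "right".
#' @return An object of class `bscan_volume`.
#' @export
bscan_volume <- function(intensity, axial_scale = 3.5,
                         eye = c("right", "left")) {
  eye <- match.arg(eye)
  stopifnot(is.array(intensity), length(dim(intensity)) == 3,
            all(is.finite(intensity)), all(intensity >= 0), axial_scale > 0)
  structure(list(intensity = intensity, axial_scale = axial_scale,
                 eye = eye),
            class = "bscan_volume")
}

#' @export
print.bscan_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("bscan_volume: %d B-scans x %d axial px x %d locations\n",
              d[1], d[2], d[3]))
  invisible(x)
}
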