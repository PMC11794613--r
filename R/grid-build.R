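#' Locate the fovea as the centre of the thinnest region
#'
#' Takes the `k` thinnest observed pixels and returns the centroid of their
#' (row, col) indices, rounded to the nearest grid index. Ties at the k-th
#' thinnest value are broken deterministically in (row, col) lexicographic
#' order, so the result is reproducible.
#'
#' @param grid a [thickness_grid()].
#' @param k neighbourhood size (number of thinnest pixels averaged).
#' @return Integer c(row, col), 1-based.
#' @export
detect_fovea <- function(grid, k = 25) {
  stopifnot(inherits(grid, "thickness_grid"))
  v <- grid$values
  obs <- which(!is.na(v))
  if (length(obs) == 0) stop("all pixels missing; cannot locate fovea")
  k <- min(k, length(obs))
  # order by (value, row, col); arrayInd of column-major index gives
  # (row, col), and column-major order is (col, row)-lexicographic, so
  # order on value then explicit row/col keys
  idx <- arrayInd(obs, dim(v))
  o <- order(v[obs], idx[, 1], idx[, 2])[seq_len(k)]
  centre <- colMeans(idx[o, , drop = FALSE])
  as.integer(round(centre))
}

#' Align a thickness grid to the central fovea reference
#'
#' Left-eye grids are first column-mirrored about the fovea so that the
#' nasal side lies to the right, matching right-eye anatomy; the grid is
#' then translated (integer shifts only, no resampling) so the fovea sits
#' at the centre index of the grid. Cells shifted in from outside the scan
#' are missing.
#'
#' @param grid a [thickness_grid()].
#' @param fovea optional c(row, col); detected with [detect_fovea()] when
#'   NULL.
#' @param k passed to [detect_fovea()].
#' @return An aligned `thickness_grid` (eye label preserved, fovea set to
#'   the centre index).
#' @export
align_scan <- function(grid, fovea = NULL, k = 25) {
  stopifnot(inherits(grid, "thickness_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (grid$eye == "left") {
    # mirror first, then locate the fovea on the anatomically oriented
    # grid: reflection and translation commute on the retained values, and
    # detecting after the flip keeps left/right rounding identical
    v <- v[, rev(seq_len(nc)), drop = FALSE]
    if (!is.null(fovea)) fovea[2] <- nc + 1L - fovea[2]
  }
  if (is.null(fovea)) {
    fovea <- detect_fovea(thickness_grid(v, eye = "right",
                                         row_scale = grid$row_scale,
                                         col_scale = grid$col_scale), k)
  }
  if (fovea[1] < 1 || fovea[1] > nr || fovea[2] < 1 || fovea[2] > nc) {
    stop("fovea outside grid")
  }
  ref <- c(as.integer(round((nr + 1) / 2)), as.integer(round((nc + 1) / 2)))
  shift <- ref - fovea
  out <- matrix(NA_real_, nr, nc)
  src_r <- seq_len(nr) - shift[1]
  src_c <- seq_len(nc) - shift[2]
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- v[src_r[ok_r], src_c[ok_c]]
  thickness_grid(out, eye = grid$eye, row_scale = grid$row_scale,
                 col_scale = grid$col_scale, fovea = ref, id = grid$id)
}

#' Two-stage pixel-grid trim over a stack of aligned scans
#'
#' Stage 1 removes pixels missing in more than `pixel_thresh` of scans;
#' stage 2 then removes entire rows or columns in which more than
#' `line_thresh` of pixels were stage-1 removed.
#'
#' @param grids list of aligned [thickness_grid()] objects (identical
#'   dimensions), or a list of plain logical missingness matrices.
#' @param pixel_thresh stage-1 missingness fraction (exclusive; default
#'   0.10, i.e. removal when missing in > 10% of scans).
#' @param line_thresh stage-2 removed-pixel fraction per row/column
#'   (exclusive; default 0.50).
#' @return List: `retained` data frame of (row, col) 1-based retained
#'   indices, `keep` logical matrix, `stage1_removed` logical matrix,
#'   `n_removed`.
#' @export
trim_pixel_grid <- function(grids, pixel_thresh = 0.10, line_thresh = 0.50) {
  stopifnot(length(grids) >= 1)
  miss <- lapply(grids, function(g) {
    if (inherits(g, "thickness_grid")) is.na(g$values) else as.matrix(g)
  })
  dims <- dim(miss[[1]])
  miss_frac <- Reduce(`+`, miss) / length(miss)
  stage1 <- miss_frac > pixel_thresh
  keep <- !stage1
  bad_rows <- rowMeans(stage1) > line_thresh
  bad_cols <- colMeans(stage1) > line_thresh
  keep[bad_rows, ] <- FALSE
  keep[, bad_cols] <- FALSE
  if (!any(keep)) stop("trim removed every pixel")
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(retained = data.frame(row = idx[, 1], col = idx[, 2]),
       keep = keep, stage1_removed = stage1,
       n_removed = prod(dims) - sum(keep))
}

#' Select the best scan(s) per individual
#'
#' Applies the selection rules on an inventory of candidate scans: scans
#' with more than `max_missing` missingness on the trimmed grid, or without
#' refractive error, are excluded; per eye and instance the
#' lowest-missingness scan is kept (seeded random tie-break); the instance
#' with both eyes and the fewest total missing pixels is preferred;
#' individuals without a two-eyed instance contribute their single best
#' eye (random tie-break).
#'
#' @param inventory data frame with columns `individual`, `scan_id`, `eye`
#'   ("left"/"right"), `instance` (0/1), `n_missing` (missing pixels on the
#'   trimmed grid), `n_pixels` and logical `has_refraction`.
#' @param max_missing maximum tolerated missingness fraction (default 0.10,
#'   exclusive).
#' @param seed integer seed for tie-breaks.
#' @return List: `selected` subset of the inventory (one or two rows per
#'   retained individual), `excluded` data frame of individuals with no
#'   eligible scan.
#' @export
select_scans <- function(inventory, max_missing = 0.10, seed = 1) {
  need <- c("individual", "scan_id", "eye", "instance", "n_missing",
            "n_pixels", "has_refraction")
  stopifnot(all(need %in% names(inventory)))
  restore <- scoped_seed(seed)
  on.exit(restore(), add = TRUE)
  inv <- inventory[inventory$has_refraction &
                     inventory$n_missing / inventory$n_pixels <= max_missing,
                   , drop = FALSE]
  selected <- list()
  excluded <- character(0)
  for (ind in unique(inventory$individual)) {
    cand <- inv[inv$individual == ind, , drop = FALSE]
    if (nrow(cand) == 0) { excluded <- c(excluded, ind); next }
    # best scan per (eye, instance): lowest missingness, random tie-break
    best <- do.call(rbind, lapply(split(cand,
                                        list(cand$eye, cand$instance),
                                        drop = TRUE), function(g) {
      g <- g[g$n_missing == min(g$n_missing), , drop = FALSE]
      g[sample.int(nrow(g), 1), , drop = FALSE]
    }))
    # prefer an instance with both eyes and fewest total missing
    two_eyed <- vapply(split(best, best$instance),
                       function(g) length(unique(g$eye)) == 2, logical(1))
    if (any(two_eyed)) {
      insts <- names(two_eyed)[two_eyed]
      totals <- vapply(insts, function(i) {
        sum(best$n_missing[best$instance == as.integer(i)])
      }, numeric(1))
      pick <- insts[totals == min(totals)]
      pick <- if (length(pick) > 1) sample(pick, 1) else pick
      sel <- best[best$instance == as.integer(pick), , drop = FALSE]
    } else {
      best <- best[best$n_missing == min(best$n_missing), , drop = FALSE]
      sel <- best[sample.int(nrow(best), 1), , drop = FALSE]
    }
    selected[[ind]] <- sel
  }
  sel <- if (length(selected)) {
    do.call(rbind, c(selected, list(make.row.names = FALSE)))
  } else NULL
  list(selected = sel, excluded = data.frame(individual = excluded))
}

#' Impute missing pixels of one scan with a tensor-product spline surface
#'
#' Fits `Z = b0 + f(x, y) + e` to the observed pixels, where `f` is a
#' penalized tensor-product smooth with 12 x 12 marginal basis functions
#' (smoothing parameter by GCV), then replaces missing pixels with fitted
#' values. Observed pixels are returned unchanged.
#'
#' @param grid a [thickness_grid()] with < ~10% missingness.
#' @param k marginal basis dimensions, length-2 integer.
#' @return A complete `thickness_grid`.
#' @export
impute_scan <- function(grid, k = c(12, 12)) {
  stopifnot(inherits(grid, "thickness_grid"))
  v <- grid$values
  if (!anyNA(v)) return(grid)
  nr <- nrow(v); nc <- ncol(v)
  co <- grid_coords(nr, nc, grid$row_scale, grid$col_scale)
  df <- data.frame(z = as.vector(v),
                   x = rep(co$col_mu, each = nr),
                   y = rep(co$row_mu, nc))
  obs <- !is.na(df$z)
  fit <- tryCatch(
    mgcv::bam(z ~ te(x, y, k = k), data = df[obs, ], method = "fREML",
              discrete = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) stop("imputation model failed to fit; scan dropped")
  pred <- stats::predict(fit, newdata = df[!obs, ])
  out <- v
  out[!obs] <- pmax(as.numeric(pred), 0.1)
  thickness_grid(out, eye = grid$eye, row_scale = grid$row_scale,
                 col_scale = grid$col_scale, fovea = grid$fovea,
                 id = grid$id)
}

#' Assemble the final individuals-by-pixels phenotype matrix
#'
#' Averages left and right imputed scans where both exist, restricts to the
#' retained pixel set, and applies the final filter: individuals with any
#' pixel < `low` or > `high` axial px, or with scan-wise SD > `sd_max`
#' (strict inequalities), are removed.
#'
#' @param scans list per individual: `$left` and/or `$right` complete
#'   [thickness_grid()] objects (NULL when that eye is absent).
#' @param keep logical retention matrix from [trim_pixel_grid()].
#' @param low,high final admissible thickness range, axial px.
#' @param sd_max maximum scan-wise SD, axial px.
#' @param ids optional individual identifiers.
#' @return List: `cohort` ([cohort_matrix()]), `removed` character vector
#'   of filtered individuals.
#' @export
assemble_phenotypes <- function(scans, keep, low = 30, high = 150,
                                sd_max = 15, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_along(scans))
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  flat <- (idx[, 2] - 1L) * nrow(keep) + idx[, 1]
  rows <- list(); eye_code <- character(0); kept_ids <- character(0)
  removed <- character(0)
  rs <- cs <- NULL
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    gl <- sc$left; gr <- sc$right
    g <- if (!is.null(gl) && !is.null(gr)) {
      (gl$values + gr$values) / 2
    } else if (!is.null(gr)) gr$values else gl$values
    ec <- if (!is.null(gl) && !is.null(gr)) "mean"
          else if (!is.null(gr)) "right" else "left"
    ref <- if (!is.null(gr)) gr else gl
    if (is.null(rs)) { rs <- ref$row_scale; cs <- ref$col_scale }
    vals <- g[flat]
    if (anyNA(vals) || any(vals < low) || any(vals > high) ||
        stats::sd(vals) > sd_max) {
      removed <- c(removed, ids[i]); next
    }
    rows[[length(rows) + 1L]] <- vals
    eye_code <- c(eye_code, ec)
    kept_ids <- c(kept_ids, ids[i])
  }
  if (length(rows) == 0) stop("final filter removed every individual")
  mat <- do.call(rbind, rows)
  rownames(mat) <- kept_ids
  pixel_index <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
  co <- grid_coords(nrow(keep), ncol(keep), rs, cs)
  pixel_index$row_mu <- co$row_mu[idx[, 1]]
  pixel_index$col_mu <- co$col_mu[idx[, 2]]
  list(cohort = cohort_matrix(mat, pixel_index, eye_code, rs, cs),
       removed = removed)
}
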