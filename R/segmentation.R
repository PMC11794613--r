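#' Convert axial pixels to micrometres
#'
#' @param px thickness in axial pixels.
#' @param scale micrometres per axial pixel (device-dependent; the emulated
#'   scanner resolves ~3.5 um per pixel at export, 6 um natively).
#' @return Thickness in micrometres.
#' @examples
#' axial_to_micron(30, 3.5)   # 105
#' axial_to_micron(165, 3.5)  # 577.5
#' @export
axial_to_micron <- function(px, scale = 3.5) {
  stopifnot(scale > 0)
  px * scale
}

# minimum-cost left-to-right band path on one B-scan image.
# cost per cell = (max - intensity) + lambda * |row step|, moves restricted
# to column+1 with |row change| <= max_jump. Solved exactly by dynamic
# programming over columns. `rows` restricts the admissible row range per
# column (matrix or NULL). Returns row indices (one per column).
band_path <- function(img, max_jump = 3, lambda_frac = 0.1,
                      row_min = 1, row_max = nrow(img),
                      depth_bias = 0) {
  n_row <- nrow(img); n_col <- ncol(img)
  rng <- max(img) - min(img)
  lambda <- lambda_frac * rng
  # depth bias (ILM search): strong enough to out-vote accumulated noise
  # when both bands are equally bright, far below within-band contrasts
  cost <- (max(img) - img) + depth_bias * rng * 1e-2 *
    matrix(seq_len(n_row), n_row, n_col)
  if (length(row_min) == 1) row_min <- rep(row_min, n_col)
  if (length(row_max) == 1) row_max <- rep(row_max, n_col)
  big <- sum(abs(cost)) + 1e6
  for (cc in seq_len(n_col)) {
    bad <- seq_len(n_row) < row_min[cc] | seq_len(n_row) > row_max[cc]
    cost[bad, cc] <- big
  }
  d <- matrix(Inf, n_row, n_col)
  back <- matrix(NA_integer_, n_row, n_col)
  d[, 1] <- cost[, 1]
  steps <- -max_jump:max_jump
  for (cc in 2:n_col) {
    best <- rep(Inf, n_row)
    arg <- rep(NA_integer_, n_row)
    for (k in steps) {
      # candidate predecessor row is rr - k
      if (k >= 0) {
        cand <- c(rep(Inf, k), d[seq_len(n_row - k), cc - 1])
      } else {
        cand <- c(d[(1 - k):n_row, cc - 1], rep(Inf, -k))
      }
      cand <- cand + lambda * abs(k)
      better <- cand < best
      best[better] <- cand[better]
      arg[better] <- (seq_len(n_row) - k)[better]
    }
    d[, cc] <- best + cost[, cc]
    back[, cc] <- arg
  }
  path <- integer(n_col)
  path[n_col] <- which.min(d[, n_col])
  for (cc in (n_col - 1):1) path[cc] <- back[path[cc + 1], cc + 1]
  path
}

#' Track ILM and RPE boundaries across a volume
#'
#' For each B-scan the inner (ILM) and outer (RPE) boundary are recovered
#' as minimum-cost left-to-right paths following the bright bands:
#' the per-cell cost is (max intensity - intensity) plus a small penalty
#' per row change, with moves restricted to the next column and a bounded
#' row jump. The ILM is found first from the top (a tiny depth bias breaks
#' the tie between equally bright bands in favour of the upper one); the
#' RPE is then searched strictly below the ILM.
#'
#' @param volume a [bscan_volume()].
#' @param max_jump maximum row change per column step.
#' @param lambda_frac step penalty as a fraction of the intensity range.
#' @param min_sep minimum ILM-RPE separation during the RPE search, axial
#'   px.
#' @param snap per-column snap-to-peak refinement window, axial px: after
#'   the smoothness-constrained path is found, each boundary is moved to
#'   the local intensity maximum within this window, so genuine band
#'   displacements (spikes, wobble) are followed and visible to QC. Set 0
#'   to disable (pure minimum-cost path).
#' @return List of class `boundary_trace`: `ilm_row`, `rpe_row` (slices x
#'   locations) and a logical `valid` mask (FALSE where no informative path
#'   exists, e.g. a structure-free B-scan).
#' @export
track_boundaries <- function(volume, max_jump = 3, lambda_frac = 0.1,
                             min_sep = 10, snap = 45) {
  stopifnot(inherits(volume, "bscan_volume"))
  d <- dim(volume$intensity)
  n_slice <- d[1]; n_row <- d[2]; n_loc <- d[3]
  ilm <- matrix(NA_integer_, n_slice, n_loc)
  rpe <- matrix(NA_integer_, n_slice, n_loc)
  valid <- matrix(FALSE, n_slice, n_loc)
  for (s in seq_len(n_slice)) {
    img <- volume$intensity[s, , ]
    if (max(img) - min(img) < 1e-8) next     # structureless scan
    p1 <- band_path(img, max_jump, lambda_frac, depth_bias = 1)
    lower_ok <- p1 + min_sep <= n_row
    if (!all(lower_ok)) {
      ilm[s, ] <- p1; valid[s, ] <- FALSE
      next
    }
    p2 <- band_path(img, max_jump, lambda_frac,
                    row_min = p1 + min_sep, row_max = n_row)
    if (snap > 0) {
      p1 <- snap_to_peak(img, p1, snap, lo = rep(1L, n_loc),
                         hi = pmax(p2 - min_sep, 1L))
      p2 <- snap_to_peak(img, p2, snap, lo = pmin(p1 + min_sep, n_row),
                         hi = rep(n_row, n_loc))
    }
    ilm[s, ] <- p1
    rpe[s, ] <- p2
    valid[s, ] <- TRUE
  }
  structure(list(ilm_row = ilm, rpe_row = rpe, valid = valid),
            class = "boundary_trace")
}

# move each boundary row to the column's intensity peak inside
# [row - snap, row + snap] intersected with [lo, hi]
snap_to_peak <- function(img, path, snap, lo, hi) {
  n_loc <- ncol(img)
  out <- path
  for (cc in seq_len(n_loc)) {
    a <- max(lo[cc], path[cc] - snap)
    b <- min(hi[cc], path[cc] + snap)
    if (a > b) next
    rows <- a:b
    out[cc] <- rows[which.max(img[rows, cc])]
  }
  out
}

#' QC thresholds for location-level filtering
#'
#' @param thin_px,thick_px admissible thickness range, axial px (defaults
#'   30 and 165, i.e. 105-577.5 um at 3.5 um/px).
#' @param window_sd_px rolling-window SD limit, axial px (default 20, i.e.
#'   70 um).
#' @param faint_frac faintness threshold as a fraction of the volume's 99th
#'   intensity percentile.
#' @param disc_jump_px boundary discontinuity limit, axial px per location.
#' @param adj_px adjacency margin (locations/pixels) for the cut-off
#'   criterion.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(thin_px = 30, thick_px = 165, window_sd_px = 20,
                          faint_frac = 0.15, disc_jump_px = 10, adj_px = 2) {
  vals <- c(thin_px, thick_px, window_sd_px, faint_frac, disc_jump_px,
            adj_px)
  if (any(vals <= 0)) stop("QC thresholds must be positive")
  structure(list(thin_px = thin_px, thick_px = thick_px,
                 window_sd_px = window_sd_px, faint_frac = faint_frac,
                 disc_jump_px = disc_jump_px, adj_px = adj_px),
            class = "qc_thresholds")
}

# SD over a centred window of `width` locations (floor((width)/2) left,
# the rest right), truncated at the edges
rolling_sd <- function(x, width = 10) {
  n <- length(x)
  left <- floor(width / 2)
  right <- width - left - 1
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - left):min(n, i + right)
    stats::sd(x[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Six-criterion location quality control
#'
#' A location's thickness is retained only if it passes all of:
#' c1 whole-B-scan faintness (mean slice intensity above threshold);
#' c2 local-region faintness (mean intensity of the location's column
#'    above threshold);
#' c3 thickness within the admissible range (default 30-165 axial px);
#' c4 boundary not adjacent to a faint region or the image edge (cut-off);
#' c5 no boundary discontinuity (row jump between neighbouring locations
#'    within the limit, for either boundary);
#' c6 SD of the 10-location rolling window enclosing the location within
#'    the limit (default 20 axial px).
#'
#' @param volume a [bscan_volume()].
#' @param trace the [track_boundaries()] result for this volume.
#' @param thresholds a [qc_thresholds()].
#' @return List of class `qc_report`: logical matrices `c1`..`c6` (TRUE =
#'   pass), `pass` (all six and a valid trace), and `thickness` (axial px,
#'   NA where rejected).
#' @export
qc_locations <- function(volume, trace, thresholds = qc_thresholds()) {
  stopifnot(inherits(volume, "bscan_volume"),
            inherits(trace, "boundary_trace"),
            inherits(thresholds, "qc_thresholds"))
  d <- dim(volume$intensity)
  n_slice <- d[1]; n_row <- d[2]; n_loc <- d[3]
  tau <- thresholds$faint_frac *
    stats::quantile(volume$intensity, 0.99, names = FALSE)

  thick <- trace$rpe_row - trace$ilm_row
  c1 <- matrix(TRUE, n_slice, n_loc)
  c2 <- matrix(TRUE, n_slice, n_loc)
  c4 <- matrix(TRUE, n_slice, n_loc)
  c5 <- matrix(TRUE, n_slice, n_loc)
  c6 <- matrix(TRUE, n_slice, n_loc)
  for (s in seq_len(n_slice)) {
    img <- volume$intensity[s, , ]
    # faintness judged on per-column peak intensity: a usable A-scan must
    # contain a bright band; the background level is uninformative
    col_peak <- apply(img, 2, max)
    c1[s, ] <- mean(col_peak) >= tau
    c2[s, ] <- col_peak >= tau
    # c4: cut-off -- faint neighbourhood or boundary at the image edge
    faint_loc <- which(!c2[s, ])
    adj <- rep(FALSE, n_loc)
    for (f in faint_loc) {
      idx <- max(1, f - thresholds$adj_px):min(n_loc, f + thresholds$adj_px)
      adj[idx] <- TRUE
    }
    adj[faint_loc] <- FALSE                      # cells 2 fails there already
    edge <- !is.na(trace$ilm_row[s, ]) &
      (trace$ilm_row[s, ] <= thresholds$adj_px |
         trace$rpe_row[s, ] >= n_row - thresholds$adj_px + 1)
    c4[s, ] <- !(adj | edge %in% TRUE)
    # c5: discontinuity in either boundary
    for (bnd in list(trace$ilm_row[s, ], trace$rpe_row[s, ])) {
      if (all(is.na(bnd))) next
      jump <- abs(diff(bnd)) > thresholds$disc_jump_px
      bad <- unique(c(which(jump), which(jump) + 1L))
      c5[s, bad] <- FALSE
    }
    # c6: rolling-window SD of thickness
    if (!all(is.na(thick[s, ]))) {
      sds <- rolling_sd(thick[s, ], 10)
      c6[s, !is.na(sds) & sds > thresholds$window_sd_px] <- FALSE
    }
  }
  c3 <- !is.na(thick) & thick >= thresholds$thin_px &
    thick <= thresholds$thick_px
  pass <- trace$valid & c1 & c2 & c3 & c4 & c5 & c6
  out_thick <- ifelse(pass, thick, NA)
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
                 pass = pass, thickness = out_thick, tau = tau),
            class = "qc_report")
}

#' Accept or reject a candidate training segmentation mask
#'
#' The acceptance rule for automatically generated training masks: the
#' per-scan mean ILM-RPE thickness must lie in [30, 80] axial px and the
#' per-scan SD must be at most 10 axial px (both bounds inclusive).
#'
#' @param mean_px per-scan mean thickness, axial px.
#' @param sd_px per-scan thickness SD, axial px (NA when fewer than two
#'   locations are available, which rejects).
#' @return Logical: accepted.
#' @export
accept_training_mask <- function(mean_px, sd_px) {
  if (is.na(mean_px) || is.na(sd_px)) return(FALSE)
  mean_px >= 30 && mean_px <= 80 && sd_px <= 10
}
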