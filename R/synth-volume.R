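#' Specification of injected B-scan artifacts
#'
#' Each component targets one of the six location-QC criteria: globally
#' faint B-scans, faint rectangular regions, boundaries cut off at the image
#' edge, single-location discontinuity spikes, and high-local-variance
#' wobble.
#'
#' @param faint_scans integer vector of B-scan (slice) indices rendered at a
#'   small fraction of nominal intensity.
#' @param faint_regions data frame (slice, loc_start, loc_end) of
#'   rectangular regions rendered faint.
#' @param cutoffs data frame (slice, loc_start, loc_end, shift): axial shift
#'   (px) pushing the bands toward/past the image edge.
#' @param spikes data frame (slice, location, size): RPE displaced by `size`
#'   axial px at a single location.
#' @param wobble data frame (slice, loc_start, loc_end, sd): boundary rows
#'   perturbed by N(0, sd) over a run of locations.
#' @param faint_factor intensity multiplier for faint scans/regions.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(faint_scans = integer(0),
                          faint_regions = NULL, cutoffs = NULL,
                          spikes = NULL, wobble = NULL,
                          faint_factor = 0.05) {
  structure(list(faint_scans = faint_scans, faint_regions = faint_regions,
                 cutoffs = cutoffs, spikes = spikes, wobble = wobble,
                 faint_factor = faint_factor),
            class = "artifact_spec")
}

#' Render a synthetic OCT volume from a thickness grid
#'
#' Draws two bright bands per B-scan -- the ILM at a configurable axial row
#' and the RPE at ILM + thickness -- on a dark background, then injects the
#' requested artifacts. Grid rows become B-scans (slices); grid columns
#' become A-scan locations. Ground-truth boundary rows and artifact
#' locations are recorded alongside the volume.
#'
#' @param grid a [thickness_grid()]; values are the ILM-RPE separation in
#'   axial px.
#' @param artifacts an [artifact_spec()].
#' @param seed integer seed for speckle noise and wobble.
#' @param n_axial image height in axial px.
#' @param ilm_row nominal ILM row.
#' @param band_intensity peak band intensity; background is 5% of this.
#' @param band_sd Gaussian half-width of each band, axial px.
#' @param noise_sd additive intensity noise SD.
#' @return List with elements `volume` ([bscan_volume()]), `truth` (ilm/rpe
#'   row matrices, artifact bookkeeping) and the spec used.
#' @export
generate_volume <- function(grid, artifacts = artifact_spec(), seed = 1,
                            n_axial = 160, ilm_row = 40,
                            band_intensity = 200, band_sd = 1.5,
                            noise_sd = 0) {
  stopifnot(inherits(grid, "thickness_grid"))
  th <- grid$values
  n_slice <- nrow(th)
  n_loc <- ncol(th)
  ilm <- matrix(ilm_row, n_slice, n_loc)
  rpe <- ilm + round(th)

  restore <- scoped_seed(seed)
  on.exit(restore(), add = TRUE)

  ok <- function(df) !is.null(df) && nrow(df) > 0
  if (ok(artifacts$cutoffs)) {
    for (i in seq_len(nrow(artifacts$cutoffs))) {
      a <- artifacts$cutoffs[i, ]
      idx <- a$loc_start:a$loc_end
      ilm[a$slice, idx] <- ilm[a$slice, idx] + a$shift
      rpe[a$slice, idx] <- rpe[a$slice, idx] + a$shift
    }
  }
  if (ok(artifacts$spikes)) {
    for (i in seq_len(nrow(artifacts$spikes))) {
      a <- artifacts$spikes[i, ]
      rpe[a$slice, a$location] <- rpe[a$slice, a$location] + a$size
    }
  }
  if (ok(artifacts$wobble)) {
    for (i in seq_len(nrow(artifacts$wobble))) {
      a <- artifacts$wobble[i, ]
      idx <- a$loc_start:a$loc_end
      # +-sd displacements with random signs: local variance is pinned at
      # ~sd while the excursion stays bounded (inside the image and the
      # tracker's refinement window)
      rpe[a$slice, idx] <- rpe[a$slice, idx] +
        sample(c(-1L, 1L), length(idx), replace = TRUE) * round(a$sd)
    }
  }
  # out-of-range rows are an input error unless deliberately cut off
  out_of_range <- any(ilm < 1 | rpe > n_axial, na.rm = TRUE)
  if (out_of_range && !ok(artifacts$cutoffs)) {
    stop("band rows outside image height")
  }

  bg <- 0.05 * band_intensity
  rows <- seq_len(n_axial)
  vol <- array(bg, dim = c(n_slice, n_axial, n_loc))
  for (s in seq_len(n_slice)) {
    for (l in seq_len(n_loc)) {
      if (is.na(th[s, l])) next
      prof <- band_intensity * (exp(-(rows - ilm[s, l])^2 / (2 * band_sd^2)) +
                                exp(-(rows - rpe[s, l])^2 / (2 * band_sd^2)))
      vol[s, , l] <- pmin(band_intensity, bg + prof)
    }
  }
  if (ok(artifacts$faint_regions)) {
    for (i in seq_len(nrow(artifacts$faint_regions))) {
      a <- artifacts$faint_regions[i, ]
      vol[a$slice, , a$loc_start:a$loc_end] <-
        vol[a$slice, , a$loc_start:a$loc_end] * artifacts$faint_factor
    }
  }
  for (s in artifacts$faint_scans) {
    vol[s, , ] <- vol[s, , ] * artifacts$faint_factor
  }
  if (noise_sd > 0) {
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim = dim(vol))
    vol[vol < 0] <- 0
  }

  list(volume = bscan_volume(vol, axial_scale = 3.5, eye = grid$eye),
       truth = list(ilm = ilm, rpe = rpe, artifacts = artifacts),
       spec = artifacts)
}
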