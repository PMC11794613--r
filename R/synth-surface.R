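#' Parameters of the synthetic macular thickness surface
#'
#' The synthetic surface mimics the canonical macular geometry: retinal
#' thickness (RT) peaks in a perifoveal ring and dips to a minimum at the
#' central foveal pit. Thickness is expressed in axial pixels (~3.5 um per
#' pixel on the emulated device); lateral geometry is parameterised in
#' micrometres so ETDRS radii remain meaningful at any grid resolution.
#'
#' Defaults give a surface of ~65 axial px (~228 um) baseline with a pit
#' minimum near 150 um, within the typical adult range.
#'
#' @param n_row,n_col grid dimensions (default 32 x 64 for desk scale).
#' @param base_thickness baseline thickness, axial px.
#' @param pit_depth depth of the foveal pit Gaussian, axial px.
#' @param pit_sigma lateral SD of the pit, um.
#' @param ring_height height of the perifoveal ring, axial px.
#' @param ring_radius radius of the ring, um.
#' @param ring_sigma radial SD of the ring, um.
#' @param eigenmodes list of per-mode lists with elements `map` (n_row x
#'   n_col grid, unit norm under grid quadrature) and `sd` (score SD).
#' @param noise_sd SD of i.i.d. pixel noise, axial px.
#' @param row_scale,col_scale physical pixel size, um per row / per column.
#'   Defaults follow a 6000 um field over a 128 x 256 grid measured at every
#'   other A-scan: 46.88 um/row, 23.44 um/col.
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(n_row = 32, n_col = 64,
                           base_thickness = 65, pit_depth = 22,
                           pit_sigma = 400, ring_height = 6,
                           ring_radius = 1800, ring_sigma = 700,
                           eigenmodes = list(), noise_sd = 1,
                           row_scale = 46.88, col_scale = 23.44) {
  stopifnot(pit_depth < base_thickness, noise_sd >= 0,
            n_row >= 2, n_col >= 4, row_scale > 0, col_scale > 0)
  p <- list(n_row = n_row, n_col = n_col, base_thickness = base_thickness,
            pit_depth = pit_depth, pit_sigma = pit_sigma,
            ring_height = ring_height, ring_radius = ring_radius,
            ring_sigma = ring_sigma, eigenmodes = eigenmodes,
            noise_sd = noise_sd, row_scale = row_scale, col_scale = col_scale)
  class(p) <- "surface_params"
  p
}

# deterministic mean surface (axial px) for a parameter set
surface_mean <- function(params) {
  r <- grid_radius(params$n_row, params$n_col, params$row_scale,
                   params$col_scale)
  params$base_thickness -
    params$pit_depth * exp(-r^2 / (2 * params$pit_sigma^2)) +
    params$ring_height * exp(-(r - params$ring_radius)^2 /
                               (2 * params$ring_sigma^2))
}

#' Generate one synthetic per-eye thickness grid
#'
#' Thickness at each pixel is the sum of the deterministic pit-plus-ring
#' geometry, the individual's eigenmode contributions and i.i.d. Gaussian
#' noise:
#' `T = base - pit*exp(-r^2/2s_f^2) + ring*exp(-(r-r0)^2/2s_r^2)
#'      + sum_k score_k * phi_k + eps`.
#'
#' @param params a [surface_params()] object.
#' @param scores numeric vector of per-mode scores (length =
#'   `length(params$eigenmodes)`).
#' @param seed integer seed for the noise draw.
#' @return A `thickness_grid` (see [thickness_grid()]), fully observed.
#' @export
generate_surface <- function(params, scores = numeric(0), seed = 1) {
  stopifnot(inherits(params, "surface_params"),
            length(scores) == length(params$eigenmodes))
  values <- surface_mean(params)
  for (k in seq_along(scores)) {
    values <- values + scores[k] * params$eigenmodes[[k]]$map
  }
  if (params$noise_sd > 0) {
    restore <- scoped_seed(seed)
    on.exit(restore(), add = TRUE)
    values <- values + matrix(stats::rnorm(length(values), 0,
                                           params$noise_sd),
                              params$n_row, params$n_col)
  }
  if (any(values <= 0)) {
    stop("surface parameters produce non-positive thickness; rejected")
  }
  thickness_grid(values, eye = "right",
                 row_scale = params$row_scale, col_scale = params$col_scale)
}

#' Construct a family of orthonormal smooth eigenmode maps
#'
#' Builds `k` smooth spatial modes (perifoveal ring, gradients, parafoveal
#' annulus, foveal disc, ...) and orthonormalises them by Gram-Schmidt
#' under the grid quadrature (relative pixel-area weights summing to one,
#' so a unit-norm mode has RMS 1 over the grid and mode scores are in
#' axial-pixel units). By default each seed shape is first projected onto
#' the span of a tensor-product spline basis, so the planted modes are
#' exactly representable by the downstream functional PCA basis.
#'
#' @param n_row,n_col grid dimensions.
#' @param k number of modes (max 8).
#' @param row_scale,col_scale physical pixel size, um.
#' @param span_k marginal dimensions of the spline span to project onto
#'   (NULL for no projection).
#' @return List of `k` unit-norm grid maps, mutually orthogonal under grid
#'   quadrature.
#' @export
make_eigenmodes <- function(n_row, n_col, k = 6,
                            row_scale = 46.88, col_scale = 23.44,
                            span_k = c(12, 12)) {
  stopifnot(k >= 1, k <= 8)
  co <- grid_coords(n_row, n_col, row_scale, col_scale)
  x <- matrix(co$col_mu, n_row, n_col, byrow = TRUE)
  y <- matrix(co$row_mu, n_row, n_col)
  r <- grid_radius(n_row, n_col, row_scale, col_scale)
  rmax <- max(r)
  seeds <- list(
    exp(-(r - 0.6 * rmax)^2 / (2 * (0.25 * rmax)^2)),   # perifoveal ring
    x / rmax,                                           # nasal-temporal tilt
    y / rmax,                                           # superior-inferior
    exp(-(r - 0.35 * rmax)^2 / (2 * (0.18 * rmax)^2)),  # parafoveal annulus
    exp(-r^2 / (2 * (0.2 * rmax)^2)),                   # foveal disc
    (x * y) / rmax^2,                                   # saddle
    cos(3 * atan2(y, x)) * (r / rmax),                  # angular harmonic
    (r / rmax)^2 - 0.5                                  # radial bowl
  )
  project <- identity
  if (!is.null(span_k)) {
    span_k <- pmin(span_k, c(n_col, n_row))   # marginal basis <= grid size
    dat <- data.frame(x = as.vector(x), y = as.vector(y))
    B <- mgcv::smoothCon(mgcv::te(x, y, k = span_k), data = dat,
                         absorb.cons = FALSE)[[1]]$X
    qrB <- qr(B)
    project <- function(s) {
      cf <- qr.coef(qrB, as.vector(s))
      cf[is.na(cf)] <- 0
      matrix(B %*% cf, n_row, n_col)
    }
  }
  w <- 1 / (n_row * n_col)      # uniform pixels: relative areas sum to 1
  modes <- list()
  for (s in seeds[seq_len(k)]) {
    v <- project(s)
    for (m in modes) v <- v - sum(v * m * w) * m
    nv <- sqrt(sum(v^2 * w))
    if (nv < 1e-10) stop("degenerate eigenmode seed")
    modes[[length(modes) + 1L]] <- v / nv
  }
  modes
}
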