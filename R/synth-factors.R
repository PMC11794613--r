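#' Canonical spatial effect maps on the pixel grid
#'
#' Returns a named effect map describing where (and how strongly, in axial
#' px per SD of the factor) a factor acts on retinal thickness. Shapes
#' follow the regions repeatedly implicated in macular analyses: the
#' parafoveal annulus, a nasal crescent, and the foveal disc.
#'
#' @param shape one of "annulus", "nasal", "fovea", "none".
#' @param n_row,n_col grid dimensions.
#' @param amplitude peak effect, axial px per SD.
#' @param row_scale,col_scale physical pixel size, um.
#' @return n_row x n_col numeric matrix (zero outside the support).
#' @export
effect_map <- function(shape = c("annulus", "nasal", "fovea", "none"),
                       n_row = 32, n_col = 64, amplitude = 1,
                       row_scale = 46.88, col_scale = 23.44) {
  shape <- match.arg(shape)
  r <- grid_radius(n_row, n_col, row_scale, col_scale)
  co <- grid_coords(n_row, n_col, row_scale, col_scale)
  x <- matrix(co$col_mu, n_row, n_col, byrow = TRUE)
  m <- switch(shape,
    none = matrix(0, n_row, n_col),
    annulus = ifelse(r >= 500 & r <= 1500, amplitude, 0),
    fovea = ifelse(r < 500, amplitude, 0),
    nasal = ifelse(x > 0.3 * max(abs(x)) & r <= 2800, amplitude, 0)
  )
  m
}

#' Generate a factor table with known spatial effects on thickness
#'
#' Continuous (metabolite-like) factors are drawn in correlated clusters
#' via a shared Gaussian cluster factor; binary (PheCode-like) factors come
#' from a thresholded latent liability at the requested prevalence; raw
#' blood counts carry configurable technical-covariate artifacts
#' (instrument offset, day effect, smooth drift in acquisition time).
#'
#' @param n number of individuals.
#' @param continuous data frame, one row per factor: `name`, `cluster`
#'   (integer; factors sharing a cluster are correlated), `within_r`
#'   (correlation with cluster factor), `shape` (see [effect_map()]),
#'   `amplitude` (axial px per SD).
#' @param binary data frame, one row per factor: `name`, `prevalence`,
#'   `shape`, `amplitude` (axial px for case vs control).
#' @param n_row,n_col grid dimensions for the effect maps.
#' @param blood logical; also simulate four raw blood counts
#'   (neutrophils, lymphocytes, monocytes, platelets) with technical
#'   covariates.
#' @param instrument_offset additive log-scale offset applied to instrument
#'   "B" measurements of the blood counts (the injected technical effect).
#' @param seed integer seed.
#' @param row_scale,col_scale physical pixel size, um.
#' @return A list of class `factor_table`: `continuous` (n x k matrix),
#'   `binary` (n x b 0/1 matrix), `blood` (data frame of raw counts +
#'   technical covariates) and `truth` (effect maps, liabilities,
#'   injected technical effects).
#' @export
generate_factors <- function(n, continuous = NULL, binary = NULL,
                             n_row = 32, n_col = 64, blood = FALSE,
                             instrument_offset = 0, seed = 1,
                             row_scale = 46.88, col_scale = 23.44) {
  restore <- scoped_seed(seed)
  on.exit(restore(), add = TRUE)
  truth <- list(effect_maps = list())
  cont <- NULL
  if (!is.null(continuous) && nrow(continuous) > 0) {
    if (is.null(continuous$within_r)) continuous$within_r <- 0.8
    clusters <- unique(continuous$cluster)
    z_cluster <- matrix(stats::rnorm(n * length(clusters)), n,
                        length(clusters), dimnames = list(NULL, clusters))
    cont <- sapply(seq_len(nrow(continuous)), function(j) {
      rho <- continuous$within_r[j]
      zc <- z_cluster[, as.character(continuous$cluster[j])]
      rho * zc + sqrt(1 - rho^2) * stats::rnorm(n)
    })
    colnames(cont) <- continuous$name
    for (j in seq_len(nrow(continuous))) {
      truth$effect_maps[[continuous$name[j]]] <-
        effect_map(continuous$shape[j], n_row, n_col,
                   continuous$amplitude[j], row_scale, col_scale)
    }
  }
  bin <- NULL
  if (!is.null(binary) && nrow(binary) > 0) {
    liab <- matrix(stats::rnorm(n * nrow(binary)), n, nrow(binary))
    bin <- sapply(seq_len(nrow(binary)), function(j) {
      as.integer(liab[, j] > stats::qnorm(1 - binary$prevalence[j]))
    })
    colnames(bin) <- binary$name
    truth$liability <- liab
    for (j in seq_len(nrow(binary))) {
      truth$effect_maps[[binary$name[j]]] <-
        effect_map(binary$shape[j], n_row, n_col, binary$amplitude[j],
                   row_scale, col_scale)
    }
  }
  blood_df <- NULL
  if (blood) {
    instrument <- sample(c("A", "B"), n, replace = TRUE)
    day <- sample(1:7, n, replace = TRUE)
    route <- sample(c("clinic", "mail"), n, replace = TRUE)
    time <- stats::runif(n, 0, 24)
    base <- list(neutrophils = 4.2, lymphocytes = 1.9, monocytes = 0.5,
                 platelets = 250)
    tech <- instrument_offset * (instrument == "B")
    blood_df <- data.frame(instrument = instrument, day = day,
                           route = route, time = time)
    for (nm in names(base)) {
      blood_df[[nm]] <- exp(log(base[[nm]]) + stats::rnorm(n, 0, 0.25) + tech)
    }
    truth$blood_technical <- tech
  }
  structure(list(continuous = cont, binary = bin, blood = blood_df,
                 truth = truth, n = n),
            class = "factor_table")
}
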