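#' Functional PCA of the pixel grid via tensor-product splines
#'
#' Each centred thickness surface is represented in a 12 x 12 tensor-product
#' spline basis; the covariance of the basis coefficients is
#' eigen-decomposed in the quadrature metric induced by the physical pixel
#' areas (Gram-matrix weighting), yielding eigen-surfaces that are
#' orthonormal under grid quadrature. The mean surface is estimated by a
#' penalized smooth of the pixel-wise means. Signs are fixed so each
#' eigenfunction's largest-magnitude loading is positive.
#'
#' @param cohort a [cohort_matrix()] (complete, individuals x pixels).
#' @param n_components number of components to retain (default 100,
#'   truncated to the basis rank with a warning when it exceeds it).
#' @param k marginal basis dimensions.
#' @return List of class `fpc_model`: `mean` (pixel vector), `efuns`
#'   (pixels x K eigenfunction matrix), `evalues`, `scores` (individuals x
#'   K), `cum_var` (cumulative fraction of total centred quadrature
#'   variance), `pixel_index`, quadrature weight `w`, and `total_var`.
#' @export
fit_fpca <- function(cohort, n_components = 100, k = c(12, 12)) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  y <- cohort$matrix
  n <- nrow(y)
  px <- cohort$pixel_index
  # quadrature weights: relative pixel areas, normalised to sum to one --
  # uniform pixels give w = 1/npix, so unit-norm eigenfunctions have RMS 1
  # over the grid and scores carry axial-pixel units
  w <- 1 / nrow(px)
  dat <- data.frame(x = px$col_mu, y = px$row_mu)

  # smoothed mean surface
  dat$z <- colMeans(y)
  mfit <- mgcv::gam(z ~ te(x, y, k = k), data = dat, method = "GCV.Cp")
  mu <- as.numeric(stats::fitted(mfit))
  yc <- sweep(y, 2, mu)

  # basis representation of centred surfaces (least squares in the basis)
  sm <- mgcv::smoothCon(mgcv::te(x, y, k = k), data = dat,
                        absorb.cons = FALSE)[[1]]
  B <- sm$X                                     # pixels x K basis
  qrB <- qr(B)
  theta <- qr.coef(qrB, t(yc))                  # K x n coefficients
  theta[is.na(theta)] <- 0

  gram <- crossprod(B) * w                      # quadrature Gram matrix
  eg <- eigen(gram, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  half <- eg$vectors[, pos] %*% (sqrt(eg$values[pos]) * t(eg$vectors[, pos]))
  ihalf <- eg$vectors[, pos] %*%
    ((1 / sqrt(eg$values[pos])) * t(eg$vectors[, pos]))

  cv <- tcrossprod(half %*% theta) / (n - 1)    # metric-weighted covariance
  ev <- eigen(cv, symmetric = TRUE)
  rank <- sum(ev$values > max(ev$values[1], 0) * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components reduced to rank %d", rank))
    n_components <- rank
  }
  lambda <- pmax(ev$values[seq_len(n_components)], 0)
  u <- ihalf %*% ev$vectors[, seq_len(n_components), drop = FALSE]
  efuns <- B %*% u                              # pixels x K, quadrature-ON
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(efuns))) {
    m <- which.max(abs(efuns[, j]))
    if (efuns[m, j] < 0) efuns[, j] <- -efuns[, j]
  }
  scores <- yc %*% efuns * w                    # quadrature inner products
  total_var <- sum(apply(yc, 2, stats::var)) * w
  model <- structure(list(
    mean = mu, efuns = efuns, evalues = lambda, scores = scores,
    cum_var = cumsum(lambda) / total_var, total_var = total_var,
    pixel_index = px, w = w, basis = list(k = k)), class = "fpc_model")
  model
}

#' @export
print.fpc_model <- function(x, ...) {
  cat(sprintf("fpc_model: %d components; cumulative variance %.1f%%\n",
              length(x$evalues), 100 * max(x$cum_var)))
  invisible(x)
}

#' Project surfaces onto fitted eigenfunctions
#'
#' Scores are quadrature inner products of the centred surfaces with the
#' model eigenfunctions.
#'
#' @param model an `fpc_model`.
#' @param cohort a [cohort_matrix()] on the same pixel set.
#' @return individuals x components score matrix.
#' @export
project_scores <- function(model, cohort) {
  stopifnot(inherits(model, "fpc_model"), inherits(cohort, "cohort_matrix"),
            ncol(cohort$matrix) == length(model$mean))
  sweep(cohort$matrix, 2, model$mean) %*% model$efuns * model$w
}

#' Pixel-wise correlation map for each component
#'
#' For every retained pixel, the Pearson correlation between the
#' component's scores and that pixel's thickness across individuals --
#' the standard display of what spatial pattern a component captures.
#'
#' @param scores individuals x components matrix.
#' @param cohort a [cohort_matrix()].
#' @return pixels x components matrix of correlations in [-1, 1].
#' @export
fpc_correlation_map <- function(scores, cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"),
            nrow(scores) == nrow(cohort$matrix))
  stats::cor(cohort$matrix, scores)
}

#' Number of components needed to reach a variance-explained target
#'
#' @param model an `fpc_model`.
#' @param target cumulative variance fraction (default 0.95).
#' @return Smallest k with cumulative variance >= target (or the number of
#'   available components if never reached).
#' @export
n_components_for <- function(model, target = 0.95) {
  k <- which(model$cum_var >= target)
  if (length(k) == 0) length(model$cum_var) else min(k)
}
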