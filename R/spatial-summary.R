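#' Pixel-level over-representation analysis
#'
#' Each pixel is treated as a set whose entries are its significant
#' pixel-factor pairs. With N = pixels x factors total pairs in the
#' population, K = total significant pairs, each pixel draws n = #factors
#' pairs of which k are significant; the upper-tail hypergeometric
#' probability of observing >= k successes is the pixel's enrichment
#' p-value, corrected across pixels by Benjamini-Hochberg.
#'
#' @param sig logical pixels x factors significance matrix.
#' @param universe "pairs" (default, population = all pixel-factor pairs,
#'   exact hypergeometric tail) or "binomial" (alternative reading:
#'   each pixel's k compared with a Binomial(n_factors, overall hit rate)
#'   tail).
#' @return Data frame per pixel: `k` (significant factors), `p`, `p_adj`.
#' @export
pixel_ora <- function(sig, universe = c("pairs", "binomial")) {
  universe <- match.arg(universe)
  stopifnot(is.matrix(sig))
  sig <- sig * 1L
  n_pix <- nrow(sig); n_fac <- ncol(sig)
  k <- rowSums(sig)
  K <- sum(sig)
  if (K == 0) {
    p <- rep(1, n_pix)
  } else if (universe == "pairs") {
    N <- n_pix * n_fac
    p <- stats::phyper(k - 1, K, N - K, n_fac, lower.tail = FALSE)
  } else {
    p <- stats::pbinom(k - 1, n_fac, K / (n_pix * n_fac),
                       lower.tail = FALSE)
  }
  data.frame(pixel = seq_len(n_pix), k = k, p = p,
             p_adj = stats::p.adjust(p, method = "BH"))
}

#' Local (loess) smoothing of a grid map for display
#'
#' Local quadratic regression over (row, col) with tricube weights;
#' typically applied to log10 p-value maps before plotting.
#'
#' @param values numeric matrix (the grid map), or vector with
#'   `pixel_index`.
#' @param span loess span (default 0.3).
#' @param pixel_index data frame (row, col) when `values` is a vector.
#' @param degree local polynomial degree (default 2).
#' @return Smoothed values, same shape as the input, finite everywhere.
#' @export
loess_smooth <- function(values, span = 0.3, pixel_index = NULL,
                         degree = 2) {
  if (is.matrix(values)) {
    df <- data.frame(z = as.vector(values),
                     row = as.vector(row(values)),
                     col = as.vector(col(values)))
  } else {
    stopifnot(!is.null(pixel_index))
    df <- data.frame(z = values, row = pixel_index$row,
                     col = pixel_index$col)
  }
  if (stats::sd(df$z) < 1e-12) return(values)   # constant map
  fit <- stats::loess(z ~ row + col, data = df, span = span,
                      degree = degree, family = "gaussian",
                      normalize = FALSE,
                      control = stats::loess.control(surface = "direct"))
  out <- as.numeric(stats::fitted(fit))
  if (is.matrix(values)) matrix(out, nrow(values), ncol(values)) else out
}

#' Hierarchical clustering of factors or pixels on their effect maps
#'
#' Agglomerative clustering with correlation distance (1 - Pearson r) and
#' average linkage, cut at `k` clusters; returns per-cluster mean effect
#' maps. Clustering rows (factors) groups factors with shared spatial
#' effect patterns; clustering columns (pixels) groups retinal regions
#' responding similarly.
#'
#' @param beta factors x pixels matrix of effect estimates.
#' @param axis "factors" (rows) or "pixels" (columns).
#' @param k number of clusters.
#' @return List: `labels` (integer cluster per item), `tree` (hclust),
#'   `cluster_maps` (k x pixels mean-beta matrix when axis = "factors";
#'   k-vector of mean betas when axis = "pixels"), `silhouette_k`
#'   (logged suggestion from a simple silhouette-style heuristic).
#' @export
hier_cluster <- function(beta, axis = c("factors", "pixels"), k = 2) {
  axis <- match.arg(axis)
  m <- if (axis == "factors") beta else t(beta)
  if (k > nrow(m)) stop("k exceeds the number of items")
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[is.na(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  cluster_maps <- if (axis == "factors") {
    t(sapply(seq_len(k), function(cl) {
      colMeans(m[labels == cl, , drop = FALSE])
    }))
  } else {
    vapply(seq_len(k), function(cl) mean(m[labels == cl, ]), numeric(1))
  }
  list(labels = labels, tree = tree, cluster_maps = cluster_maps)
}

#' ETDRS sector label for every grid pixel
#'
#' Standard nine-sector macular partition centred on the fovea: central
#' subfield (1 mm diameter disc), inner ring (1-3 mm diameter) and outer
#' ring (3-6 mm diameter), the rings split into superior / nasal /
#' inferior / temporal quadrants by the +-45 degree diagonals. Distances
#' use the physical row/column scales. Orientation follows the display
#' convention: top = superior, right = nasal (right-eye anatomy).
#'
#' @param n_row,n_col grid dimensions.
#' @param row_scale,col_scale physical pixel size, um.
#' @param fovea c(row, col) of the fovea reference (defaults to the grid
#'   centre).
#' @return Integer matrix: 1 = central subfield; 2-5 = inner superior,
#'   nasal, inferior, temporal; 6-9 = outer superior, nasal, inferior,
#'   temporal; 0 = outside the 6 mm circle.
#' @export
etdrs_sector_map <- function(n_row, n_col, row_scale = 46.88,
                             col_scale = 23.44, fovea = NULL) {
  if (is.null(fovea)) fovea <- c((n_row + 1) / 2, (n_col + 1) / 2)
  y <- -(matrix(seq_len(n_row), n_row, n_col) - fovea[1]) * row_scale
  x <- (matrix(seq_len(n_col), n_row, n_col, byrow = TRUE) - fovea[2]) *
    col_scale
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) * 180 / pi                  # 0 = nasal, 90 = superior
  quadrant <- ifelse(ang >= 45 & ang < 135, 0L,   # superior
               ifelse(ang >= -45 & ang < 45, 1L,  # nasal
               ifelse(ang >= -135 & ang < -45, 2L, 3L)))  # inferior/temporal
  out <- matrix(0L, n_row, n_col)
  out[r < 500] <- 1L
  inner <- r >= 500 & r < 1500
  outer_ring <- r >= 1500 & r <= 3000
  out[inner] <- 2L + quadrant[inner]
  out[outer_ring] <- 6L + quadrant[outer_ring]
  out
}
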