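#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic component of the pipeline draws its randomness from a
#' named child of one master seed, so individual components can be
#' regenerated independently without replaying the whole stream.
#'
#' @param master integer master seed.
#' @param name character label of the component (e.g. "genotypes").
#' @return An integer seed in [0, 2^31 - 1).
#' @export
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- sum(as.integer(charToRaw(name)) * seq_along(charToRaw(name)) * 131)
  as.integer((abs(master) * 48271 + h * 16807 + 12345) %% 2147483647)
}

#' Standardise columns to mean zero, unit variance
#'
#' @param x numeric vector or matrix.
#' @return Object of the same shape with each column centred and scaled.
#' @export
standardise <- function(x) {
  if (is.matrix(x)) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("cannot standardise a constant column")
    scale(x)[, , drop = FALSE]
  } else {
    s <- stats::sd(x)
    if (s == 0) stop("cannot standardise a constant vector")
    (x - mean(x)) / s
  }
}

#' Write a data frame as tab-separated values with a header
#' @param x data frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated file written by [write_tsv()]
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# physical coordinates (micrometres) of grid pixels relative to grid centre;
# rows run superior -> inferior, columns temporal -> nasal
grid_coords <- function(n_row, n_col, row_scale, col_scale) {
  r0 <- (n_row + 1) / 2
  c0 <- (n_col + 1) / 2
  list(
    row_mu = (seq_len(n_row) - r0) * row_scale,
    col_mu = (seq_len(n_col) - c0) * col_scale
  )
}

# distance-to-centre matrix in micrometres
grid_radius <- function(n_row, n_col, row_scale, col_scale) {
  co <- grid_coords(n_row, n_col, row_scale, col_scale)
  sqrt(outer(co$row_mu^2, co$col_mu^2, `+`))
}

# set the RNG deterministically; returns a closure restoring the prior state
scoped_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}
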