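#' Configuration for a full synthetic cohort
#'
#' Collects every knob of the generator in one object. Defaults describe
#' the emulated study population: ages 40-70 with a non-linear thickness
#' peak at 54 years, a male excess concentrated in fovea/parafovea, a
#' height effect in the parafovea and a hyperopia (positive spherical
#' equivalent) effect in the para/perifovea.
#'
#' @param n number of individuals.
#' @param params a [surface_params()] object (grid geometry + noise).
#' @param n_modes number of individual eigenmodes of variation.
#' @param mode_sd score SDs for the eigenmodes (axial px), length
#'   `n_modes`; defaults to the square roots of the eigenvalue spectrum
#'   (10, 6, 4, 2, 1, 0.5), keeping individual variation well below the
#'   22 px pit depth so the fovea stays detectable.
#' @param both_eyes_prob probability an individual has both eyes imaged;
#'   the remainder split evenly between left-only and right-only.
#' @param missing_rate MCAR per-pixel missingness rate in each eye grid.
#' @param edge_missing extra missingness rate on the outermost 2 rows/cols
#'   (non-random QC failure pattern).
#' @param age_peak age (years) of maximum thickness.
#' @param age_curv thickness loss, axial px per (decade from peak)^2.
#' @param sex_effect male minus female thickness at the foveal disc, axial
#'   px.
#' @param height_effect axial px per SD of height, parafoveal annulus.
#' @param se_effect axial px per dioptre of spherical equivalent,
#'   perifoveal ring.
#' @param block_spec genotype block specification (see
#'   [generate_genotypes()]); NULL for the default 12 blocks of 12 SNPs.
#' @param causal data frame of causal variants: `block` (block index; the
#'   middle SNP of the block is causal), `beta` (axial px per allele),
#'   `shape` (see [effect_map()]).
#' @param factors_continuous,factors_binary factor specifications passed to
#'   [generate_factors()].
#' @param blood logical; simulate raw blood counts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 300, params = surface_params(),
                          n_modes = 6,
                          mode_sd = sqrt(c(10, 6, 4, 2, 1,
                                           0.5))[seq_len(n_modes)],
                          both_eyes_prob = 0.7, missing_rate = 0.02,
                          edge_missing = 0.15,
                          age_peak = 54, age_curv = 1.5,
                          sex_effect = 2, height_effect = 0.8,
                          se_effect = 0.6,
                          block_spec = NULL, causal = NULL,
                          factors_continuous = NULL, factors_binary = NULL,
                          blood = FALSE) {
  if (is.null(block_spec)) {
    block_spec <- data.frame(n_snp = rep(12, 12), r = 0.9,
                             chrom = as.character(c(1:11, "X")))
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' Composes surfaces, eigenmode scores, covariate effects, genotype and
#' factor effects into per-eye thickness grids, together with genotypes,
#' factor tables, covariates and every ground-truth object needed to test
#' the downstream pipeline. All randomness derives from named children of
#' the single master seed, so each component is reproducible in isolation.
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return A list of class `synthetic_cohort` with elements `grids` (per
#'   individual: `$left`/`$right` [thickness_grid()] or NULL), `genotypes`,
#'   `factors`, `covariates` (data frame with age, sex, height,
#'   spherical_equivalent, device, eye_code, PC1..PC10), and `truth`
#'   (eigenmodes, scores, causal effects, factor maps, covariate maps).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$params
  nr <- p$n_row; nc <- p$n_col
  n <- config$n

  modes <- make_eigenmodes(nr, nc, config$n_modes, p$row_scale, p$col_scale)
  p$eigenmodes <- lapply(seq_along(modes), function(k) {
    list(map = modes[[k]], sd = config$mode_sd[k])
  })

  restore <- scoped_seed(child_seed(seed, "covariates"))
  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1, 0.46)                 # 1 = male
  height <- stats::rnorm(n, 168 + 11 * sex, 7)
  sph_eq <- stats::rnorm(n, -0.3, 2)
  device <- sample(1:3, n, replace = TRUE)
  u <- stats::runif(n)
  eye_code <- ifelse(u < config$both_eyes_prob, "mean",
                     ifelse(u < config$both_eyes_prob +
                              (1 - config$both_eyes_prob) / 2,
                            "left", "right"))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  restore()

  geno <- generate_genotypes(n, config$block_spec, sex = sex,
                             seed = child_seed(seed, "genotypes"))

  factors <- generate_factors(
    n, continuous = config$factors_continuous,
    binary = config$factors_binary, n_row = nr, n_col = nc,
    blood = config$blood, seed = child_seed(seed, "factors"),
    row_scale = p$row_scale, col_scale = p$col_scale)

  restore <- scoped_seed(child_seed(seed, "scores"))
  scores <- sapply(config$mode_sd, function(s) stats::rnorm(n, 0, s))
  restore()

  # covariate effect maps (axial px contributions)
  map_fovea <- effect_map("fovea", nr, nc, 1, p$row_scale, p$col_scale)
  map_annulus <- effect_map("annulus", nr, nc, 1, p$row_scale, p$col_scale)
  r <- grid_radius(nr, nc, p$row_scale, p$col_scale)
  map_peri <- ifelse(r > 1500 & r <= 3000, 1, 0)

  base <- surface_mean(p)
  height_std <- as.numeric(standardise(height))
  cov_effect <- function(i) {
    -config$age_curv * ((age[i] - config$age_peak) / 10)^2 * (base / base) +
      config$sex_effect * sex[i] * (map_fovea + 0.5 * map_annulus) +
      config$height_effect * height_std[i] * map_annulus +
      config$se_effect * sph_eq[i] * map_peri
  }

  causal_effects <- list()
  snp_effect <- matrix(0, nr * nc, 0)
  causal_snps <- integer(0)
  if (!is.null(config$causal) && nrow(config$causal) > 0) {
    for (j in seq_len(nrow(config$causal))) {
      b <- config$causal$block[j]
      snps_in <- which(geno$snp_meta$block == b)
      snp <- snps_in[ceiling(length(snps_in) / 2)]
      causal_snps <- c(causal_snps, snp)
      causal_effects[[j]] <- list(
        snp = snp, id = geno$snp_meta$id[snp], beta = config$causal$beta[j],
        map = effect_map(config$causal$shape[j], nr, nc, 1,
                         p$row_scale, p$col_scale))
    }
  }

  fac_effects <- list()
  if (!is.null(factors$continuous)) {
    for (nm in colnames(factors$continuous)) {
      fac_effects[[nm]] <- list(values = factors$continuous[, nm],
                                map = factors$truth$effect_maps[[nm]])
    }
  }
  if (!is.null(factors$binary)) {
    for (nm in colnames(factors$binary)) {
      fac_effects[[nm]] <- list(values = factors$binary[, nm],
                                map = factors$truth$effect_maps[[nm]])
    }
  }

  make_eye <- function(i, eye, eye_seed) {
    extra <- cov_effect(i)
    for (k in seq_along(modes)) extra <- extra + scores[i, k] * modes[[k]]
    for (ce in causal_effects) {
      extra <- extra + ce$beta * geno$dosages[i, ce$snp] * ce$map
    }
    for (fe in fac_effects) extra <- extra + fe$values[i] * fe$map
    restore <- scoped_seed(eye_seed)
    on.exit(restore(), add = TRUE)
    vals <- base + extra +
      matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    vals[vals <= 0] <- 0.1
    miss <- matrix(stats::runif(nr * nc) < config$missing_rate, nr, nc)
    if (config$edge_missing > 0) {
      edge <- matrix(FALSE, nr, nc)
      edge[c(1:2, nr - 1, nr), ] <- TRUE
      edge[, c(1:2, nc - 1, nc)] <- TRUE
      miss <- miss | (edge & matrix(stats::runif(nr * nc) <
                                      config$edge_missing, nr, nc))
    }
    vals[miss] <- NA
    thickness_grid(vals, eye = eye, row_scale = p$row_scale,
                   col_scale = p$col_scale,
                   id = sprintf("ind%04d_%s", i, eye))
  }

  grids <- lapply(seq_len(n), function(i) {
    out <- list(left = NULL, right = NULL)
    if (eye_code[i] %in% c("mean", "right")) {
      out$right <- make_eye(i, "right", child_seed(seed, paste0("eyeR", i)))
    }
    if (eye_code[i] %in% c("mean", "left")) {
      out$left <- make_eye(i, "left", child_seed(seed, paste0("eyeL", i)))
    }
    out
  })

  covariates <- data.frame(id = sprintf("ind%04d", seq_len(n)), age = age,
                           sex = sex, height = height,
                           spherical_equivalent = sph_eq, device = device,
                           eye_code = eye_code, stringsAsFactors = FALSE)
  covariates <- cbind(covariates, pcs)

  structure(list(
    grids = grids, genotypes = geno, factors = factors,
    covariates = covariates,
    truth = list(eigenmodes = modes, mode_sd = config$mode_sd,
                 scores = scores, causal = causal_effects,
                 causal_snps = causal_snps,
                 factor_maps = factors$truth$effect_maps,
                 base_surface = base),
    config = config, seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: n = %d, grid %d x %d, %d SNPs\n",
              x$config$n, x$config$params$n_row, x$config$params$n_col,
              ncol(x$genotypes$dosages)))
  invisible(x)
}
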