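# shared fixture builders (built in code at test time)

# covariate table with the full column contract
make_covariates <- function(n, seed = 1) {
  restore <- retinagrid:::scoped_seed(seed)
  on.exit(restore(), add = TRUE)
  covs <- data.frame(
    age = stats::runif(n, 40, 70),
    sex = stats::rbinom(n, 1, 0.5),
    height = stats::rnorm(n, 170, 8),
    spherical_equivalent = stats::rnorm(n, 0, 2),
    device = sample(1:3, n, replace = TRUE),
    eye_code = sample(c("left", "right", "mean"), n, replace = TRUE))
  for (i in 1:10) covs[[paste0("PC", i)]] <- stats::rnorm(n)
  covs
}

# small two-band B-scan volume with known boundaries
make_band_volume <- function(n_slice = 4, n_axial = 120, n_loc = 24,
                             thickness = 55, ilm_row = 30, noise_sd = 0,
                             seed = 1) {
  p <- surface_params(n_row = n_slice, n_col = n_loc, noise_sd = 0,
                      base_thickness = thickness, pit_depth = 5,
                      ring_height = 0)
  g <- generate_surface(p, seed = seed)
  generate_volume(g, seed = seed, n_axial = n_axial, ilm_row = ilm_row,
                  noise_sd = noise_sd)
}

# cohort matrix simulated from known orthonormal modes
make_mode_cohort <- function(n = 200, n_row = 16, n_col = 24, k = 3,
                             lambdas = c(8, 4, 2), noise_sd = 0.1,
                             seed = 1) {
  restore <- retinagrid:::scoped_seed(seed)
  on.exit(restore(), add = TRUE)
  modes <- make_eigenmodes(n_row, n_col, k, span_k = c(8, 8))
  M <- sapply(modes, as.vector)
  sc <- sapply(sqrt(lambdas), function(s) stats::rnorm(n, 0, s))
  Y <- matrix(55, n, n_row * n_col) + sc %*% t(M) +
    matrix(stats::rnorm(n * n_row * n_col, 0, noise_sd), n)
  px <- data.frame(row = rep(0:(n_row - 1), n_col),
                   col = rep(0:(n_col - 1), each = n_row))
  list(cohort = cohort_matrix(Y, px), modes = M, scores = sc,
       lambdas = lambdas)
}

# random GWAS instance for consolidation oracle checks: a handful of LD
# blocks, planted effects on random pixel subsets
make_gwas_instance <- function(seed, n = 500, n_blocks = 4,
                               snps_per_block = 8, npix = 15) {
  restore <- retinagrid:::scoped_seed(seed)
  on.exit(restore(), add = TRUE)
  bs <- data.frame(n_snp = rep(snps_per_block, n_blocks), r = 0.9,
                   chrom = as.character(seq_len(n_blocks)), maf = 0.3)
  geno <- generate_genotypes(n, bs, seed = seed + 1)
  Y <- matrix(stats::rnorm(n * npix), n, npix)
  n_causal <- sample(1:3, 1)
  causal_blocks <- sample(n_blocks, n_causal)
  for (b in causal_blocks) {
    snp <- (b - 1) * snps_per_block + sample(snps_per_block, 1)
    pix <- sample(npix, sample(3:8, 1))
    Y[, pix] <- Y[, pix] + stats::runif(1, 0.25, 0.5) * geno$dosages[, snp]
  }
  gw <- gwas_scan(geno, Y)
  ld <- ld_r2(geno, 5000)
  phenos <- unique(gw$table$phenotype)
  clumps <- lapply(stats::setNames(phenos, phenos), function(q) {
    clump_snps(gw$table[gw$table$phenotype == q, c("snp", "p")],
               gw$snp_meta, ld)
  })
  list(gwas = gw, clumps = clumps, meta = gw$snp_meta,
       causal_blocks = causal_blocks)
}
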