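test_that("noise-free surface matches the closed form with its minimum at the centre", {
  p <- surface_params(noise_sd = 0)
  g <- generate_surface(p, seed = 1)
  r <- retinagrid:::grid_radius(p$n_row, p$n_col, p$row_scale, p$col_scale)
  expected <- p$base_thickness -
    p$pit_depth * exp(-r^2 / (2 * p$pit_sigma^2)) +
    p$ring_height * exp(-(r - p$ring_radius)^2 / (2 * p$ring_sigma^2))
  expect_equal(g$values, expected)
  centre_vals <- g$values[16:17, 32:33]
  expect_equal(min(g$values), min(centre_vals))
})

test_that("surface generation is deterministic in the seed and rejects bad params", {
  p <- surface_params(noise_sd = 1)
  expect_identical(generate_surface(p, seed = 7)$values,
                   generate_surface(p, seed = 7)$values)
  expect_false(identical(generate_surface(p, seed = 7)$values,
                         generate_surface(p, seed = 8)$values))
  expect_error(surface_params(base_thickness = 10, pit_depth = 22),
               "pit_depth")
  # a huge negative eigenmode contribution drives thickness negative
  modes <- make_eigenmodes(32, 64, 1)
  p2 <- surface_params(noise_sd = 0,
                       eigenmodes = list(list(map = modes[[1]], sd = 1)))
  expect_error(generate_surface(p2, scores = -1e4, seed = 1), "rejected")
})

test_that("pixel noise has the requested SD (Monte Carlo)", {
  p <- surface_params(n_row = 4, n_col = 4, noise_sd = 2, pit_sigma = 200)
  draws <- vapply(1:2500, function(s) {
    generate_surface(p, seed = s)$values[2, 2]
  }, numeric(1))
  # 2500 draws at 4 pixels' worth of stability: SD within 5% of nominal
  expect_lt(abs(stats::sd(draws) - 2) / 2, 0.05)
})

test_that("eigenmode maps are orthonormal under grid quadrature", {
  modes <- make_eigenmodes(32, 64, 6)
  w <- 1 / (32 * 64)
  gram <- sapply(modes, function(a) sapply(modes, function(b) {
    sum(a * b * w)
  }))
  expect_lt(max(abs(gram - diag(6))), 1e-8)
})

test_that("genotype blocks induce the requested LD and honour chrX coding", {
  n <- 2000
  bs <- data.frame(n_snp = c(12, 12), r = c(0.9, 0),
                   chrom = c("1", "X"), maf = 0.3)
  sex <- rep(c(0L, 1L), n / 2)
  geno <- generate_genotypes(n, bs, sex = sex, seed = 11)
  expect_true(all(geno$dosages %in% 0:2))
  cm <- stats::cor(geno$dosages[, 1:12])
  mean_r2 <- mean(cm[upper.tri(cm)]^2)
  expect_gt(mean_r2, 0.7)
  expect_lt(mean_r2, 0.9)
  # r = 0 block: mean off-diagonal r^2 is ~1/(n-1)
  cm0 <- stats::cor(geno$dosages[, 13:24])
  expect_lt(mean(cm0[upper.tri(cm0)]^2), 3 / n)
  # chrX males never carry dosage 1
  xmale <- geno$dosages[sex == 1, geno$snp_meta$chrom == "X"]
  expect_true(all(xmale %in% c(0L, 2L)))
  # positions strictly increasing within chromosome
  for (ch in unique(geno$snp_meta$chrom)) {
    pos <- geno$snp_meta$pos[geno$snp_meta$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_identical(generate_genotypes(50, bs, sex = rep(0L, 50),
                                      seed = 3)$dosages,
                   generate_genotypes(50, bs, sex = rep(0L, 50),
                                      seed = 3)$dosages)
})

test_that("factor generator delivers cluster correlation, prevalence and effect support", {
  spec_c <- data.frame(name = c("m1", "m2", "m3"), cluster = c(1, 1, 2),
                       within_r = c(0.9, 0.9, 0.5),
                       shape = c("annulus", "annulus", "fovea"),
                       amplitude = c(1, 1, 0))
  spec_b <- data.frame(name = "d1", prevalence = 0.2, shape = "nasal",
                       amplitude = 0.5)
  fac <- generate_factors(2000, spec_c, spec_b, seed = 5)
  # same-cluster pair: r ~ 0.9^2 = 0.81 within +-0.05
  r12 <- stats::cor(fac$continuous[, "m1"], fac$continuous[, "m2"])
  expect_lt(abs(r12 - 0.81), 0.05)
  expect_lt(abs(stats::cor(fac$continuous[, "m1"],
                           fac$continuous[, "m3"])), 0.08)
  expect_true(all(fac$binary %in% 0:1))
  expect_lt(abs(mean(fac$binary[, "d1"]) - 0.2), 0.03)
  # annulus map nonzero exactly on the annulus
  m <- fac$truth$effect_maps[["m1"]]
  r <- retinagrid:::grid_radius(32, 64, 46.88, 23.44)
  expect_true(all((m != 0) == (r >= 500 & r <= 1500)))
  # zero-amplitude factor has an all-zero map
  expect_true(all(fac$truth$effect_maps[["m3"]] == 0))
})

test_that("cohorts are internally consistent and seed-deterministic", {
  cc <- cohort_config(n = 25)
  syn1 <- generate_cohort(cc, seed = 99)
  syn2 <- generate_cohort(cc, seed = 99)
  expect_equal(length(syn1$grids), 25)
  expect_equal(nrow(syn1$covariates), 25)
  expect_equal(nrow(syn1$genotypes$dosages), 25)
  g1 <- Filter(Negate(is.null), unlist(syn1$grids, recursive = FALSE))
  g2 <- Filter(Negate(is.null), unlist(syn2$grids, recursive = FALSE))
  expect_identical(lapply(g1, `[[`, "values"), lapply(g2, `[[`, "values"))
  expect_identical(syn1$genotypes$dosages, syn2$genotypes$dosages)
  # eye availability matches the covariate eye code
  for (i in seq_len(25)) {
    ec <- syn1$covariates$eye_code[i]
    expect_equal(!is.null(syn1$grids[[i]]$left), ec %in% c("mean", "left"))
    expect_equal(!is.null(syn1$grids[[i]]$right), ec %in% c("mean", "right"))
  }
})

test_that("with all effects off, a null factor shows no association (permutation-level)", {
  cc <- cohort_config(n = 80, age_curv = 0, sex_effect = 0,
                      height_effect = 0, se_effect = 0, missing_rate = 0,
                      edge_missing = 0, mode_sd = rep(0, 6))
  syn <- generate_cohort(cc, seed = 13)
  # exchangeable thickness: correlate a random factor with mean thickness
  mt <- vapply(syn$grids, function(g) {
    gg <- if (!is.null(g$right)) g$right else g$left
    mean(gg$values, na.rm = TRUE)
  }, numeric(1))
  restore <- retinagrid:::scoped_seed(17)
  on.exit(restore(), add = TRUE)
  pvals <- vapply(1:200, function(i) {
    stats::cor.test(mt, stats::rnorm(80))$p.value
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated FPC score covariance matches the requested spectrum", {
  cc <- cohort_config(n = 1000)
  syn <- generate_cohort(cc, seed = 21)
  emp <- apply(syn$truth$scores, 2, stats::var)
  expect_true(all(abs(emp - cc$mode_sd^2) / cc$mode_sd^2 < 0.10))
})

test_that("volume rendering places bands at the requested rows and records artifacts", {
  vol <- make_band_volume(noise_sd = 0)
  # band centres: intensity at the truth rows is the profile maximum
  for (s in 1:4) for (l in c(1, 12, 24)) {
    prof <- vol$volume$intensity[s, , l]
    peaks <- which(prof == max(prof))
    expect_true(vol$truth$ilm[s, l] %in% peaks)
    expect_true(vol$truth$rpe[s, l] %in% peaks)
  }
  # faint scan artifact by construction
  art <- artifact_spec(faint_scans = 2)
  va <- generate_volume(generate_surface(surface_params(
    n_row = 4, n_col = 24, noise_sd = 0), seed = 1), art, seed = 1)
  expect_lt(mean(va$volume$intensity[2, , ]),
            0.2 * mean(va$volume$intensity[1, , ]))
  expect_error(generate_volume(generate_surface(surface_params(
    n_row = 4, n_col = 24, noise_sd = 0), seed = 1), seed = 1,
    n_axial = 40), "image height")
})

test_that("a +40 px spike yields the arithmetically expected rolling-window SD", {
  # 10-location window with a single 40 px outlier: SD = sqrt(40^2 / 10)
  trace <- rep(50, 24); trace[12] <- 90
  sds <- retinagrid:::rolling_sd(trace, 10)
  expect_equal(max(sds), sqrt(40^2 / 10), tolerance = 1e-10)
  expect_lt(max(sds), 20)   # a lone spike is a criterion-5, not -6, event
})
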