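test_that("the association scan matches joint OLS and recovers planted SNP effects", {
  covs <- make_covariates(2000, seed = 1)
  geno <- generate_genotypes(2000, data.frame(n_snp = 10, r = 0.5,
                                              maf = 0.3), seed = 2)
  restore <- retinagrid:::scoped_seed(3)
  on.exit(restore(), add = TRUE)
  Y <- matrix(stats::rnorm(2000 * 20), 2000, 20)
  Y[, 1] <- Y[, 1] + 0.4 * geno$dosages[, 4]
  des <- design_spec(stats::rnorm(2000), covs)
  gw <- gwas_scan(geno, Y, des)
  # planted effect within 2 SE
  expect_lt(abs(gw$beta[4, 1] - 0.4), 2 * gw$se[4, 1])
  # residualisation path equals the direct multiple regression
  X <- cbind(des$X[, colnames(des$X) != "factor"],
             g = geno$dosages[des$keep, 7])
  f <- stats::lm.fit(X, Y[des$keep, 5])
  bj <- f$coefficients[["g"]]
  rdf <- length(f$residuals) - ncol(X)
  sj <- sqrt(sum(f$residuals^2) / rdf * chol2inv(qr.R(qr(X)))[ncol(X),
                                                             ncol(X)])
  expect_lt(abs(gw$beta[7, 5] - bj), 1e-10)
  expect_lt(abs(gw$se[7, 5] - sj), 1e-10)
  # null SNP p-values uniform
  null_p <- as.vector(gw$p[-4, -1])
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)
  # monomorphic SNPs are skipped, not errored
  geno2 <- geno
  geno2$dosages[, 2] <- 1L
  gw2 <- gwas_scan(geno2, Y[, 1:2])
  expect_true("rs2" %in% gw2$skipped)
  expect_false("rs2" %in% gw2$table$snp)
})

test_that("LD r-squared has unit diagonal semantics and block structure", {
  geno <- generate_genotypes(1500, data.frame(n_snp = c(8, 8), r = c(0.9, 0.9),
                                              chrom = c("1", "2"),
                                              maf = 0.3), seed = 4)
  ld <- ld_r2(geno, 5000)
  # duplicated column: r2 = 1
  geno$dosages[, 2] <- geno$dosages[, 1]
  ld_dup <- ld_r2(geno, 5000)
  pair <- ld_dup[ld_dup$snp_a == "rs1" & ld_dup$snp_b == "rs2", ]
  expect_equal(pair$r2, 1)
  # no cross-chromosome pairs are reported at all
  meta <- geno$snp_meta
  chr_of <- stats::setNames(meta$chrom, meta$id)
  expect_true(all(chr_of[ld$snp_a] == chr_of[ld$snp_b]))
})

test_that("clumping honours the p, r2 and distance criteria with multi-membership", {
  meta <- data.frame(chrom = "1", pos = c(1e6, 2e6, 3e6, 5.0015e9, 9e9),
                     id = paste0("s", 1:5))
  assoc <- data.frame(snp = meta$id, p = c(1e-9, 1e-6, 1e-9, 1e-6, 0.5))
  ld <- data.frame(snp_a = c("s1", "s1", "s2", "s3", "s1"),
                   snp_b = c("s2", "s3", "s3", "s4", "s5"),
                   r2 = c(0.5, 0.4, 0.6, 0.9, 0.9))
  cl <- clump_snps(assoc, meta, ld)
  expect_equal(length(cl), 2)            # two index SNPs (s1, s3)
  m1 <- cl[[which(vapply(cl, `[[`, "", "index") == "s1")]]$members
  m3 <- cl[[which(vapply(cl, `[[`, "", "index") == "s3")]]$members
  expect_setequal(m1, c("s1", "s2", "s3"))
  expect_setequal(m3, c("s3", "s1", "s2"))     # shared members allowed
  # s4 sits beyond the 5000 kb window of s3 (distance > 5,000,000 kb here)
  expect_false("s4" %in% m3)
  # s5 fails the p < 5e-5 member criterion despite high r2
  expect_false("s5" %in% m1)
  # an isolated significant SNP forms a singleton clump
  assoc2 <- data.frame(snp = "s1", p = 1e-9)
  cl2 <- clump_snps(assoc2, meta[1, ], ld[0, ])
  expect_equal(cl2[[1]]$members, "s1")
})

test_that("member distance is inclusive at the window and exclusive beyond it", {
  meta <- data.frame(chrom = "1", pos = c(1, 1 + 5000e3, 1 + 5001e3),
                     id = c("a", "b", "c"))
  assoc <- data.frame(snp = meta$id, p = c(1e-9, 1e-6, 1e-6))
  ld <- data.frame(snp_a = c("a", "a"), snp_b = c("b", "c"), r2 = 0.9)
  cl <- clump_snps(assoc, meta, ld)
  expect_true("b" %in% cl[[1]]$members)    # exactly 5,000 kb away
  expect_false("c" %in% cl[[1]]$members)   # 5,001 kb away
})

test_that("loci consolidation handles canonical cases deterministically", {
  # single SNP-pixel signal: one locus with that SNP and pixel
  meta <- data.frame(chrom = "1", pos = 1e6, id = "s1")
  tab <- data.frame(snp = "s1", phenotype = "px1", p = 1e-10)
  cl <- list(px1 = list(list(index = "s1", members = "s1")))
  loci <- consolidate_loci(tab, cl, meta, min_snps = 1)
  expect_equal(length(loci), 1)
  expect_equal(loci[[1]]$sentinel, "s1")
  expect_equal(loci[[1]]$top_phenotype, "px1")
  expect_equal(loci[[1]]$n_snps, 1)

  # a 20-SNP LD block significant over a 3x3 pixel patch: one locus
  geno <- generate_genotypes(1200, data.frame(n_snp = 20, r = 0.95,
                                              maf = 0.3), seed = 5)
  restore <- retinagrid:::scoped_seed(6)
  on.exit(restore(), add = TRUE)
  Y <- matrix(stats::rnorm(1200 * 9), 1200, 9)
  Y <- Y + 0.45 * geno$dosages[, 10]
  gw <- gwas_scan(geno, Y)
  ld <- ld_r2(geno, 5000)
  phenos <- unique(gw$table$phenotype)
  clumps <- lapply(stats::setNames(phenos, phenos), function(q) {
    clump_snps(gw$table[gw$table$phenotype == q, c("snp", "p")],
               gw$snp_meta, ld)
  })
  loci2 <- consolidate_loci(gw, clumps, gw$snp_meta)
  expect_equal(length(loci2), 1)
  expect_equal(sort(loci2[[1]]$phenotypes), sort(phenos))
  expect_gte(loci2[[1]]$n_snps, 5)

  # record order must not matter
  gw_shuf <- gw
  gw_shuf$table <- gw$table[sample(nrow(gw$table)), ]
  loci3 <- consolidate_loci(gw_shuf, clumps, gw$snp_meta)
  expect_identical(locus_canon(loci2), locus_canon(loci3))
})

test_that("consolidation agrees with an independent coding of the printed loop", {
  for (seed in 1:8) {
    inst <- make_gwas_instance(seed, n = 500, n_blocks = 5,
                               snps_per_block = 8, npix = 18)
    mine <- consolidate_loci(inst$gwas, inst$clumps, inst$meta,
                             min_snps = 1)
    theirs <- oracle_consolidate(inst$gwas$table, inst$clumps, inst$meta,
                                 min_snps = 1)
    expect_identical(locus_canon(mine), locus_canon(theirs))
    # every genome-wide-significant pair is consumed by the loop
    sig <- inst$gwas$table[inst$gwas$table$p < 5e-8, ]
    if (nrow(sig) > 0 && length(mine) > 0) {
      loc_snps <- unlist(lapply(mine, function(l) c(l$sentinel,
                                                    l$supporting)))
      # each significant SNP is allocated to (at least) one locus or was
      # removed through its clump in step 4
      expect_true(all(sig$snp %in% c(loc_snps, unlist(lapply(
        unlist(inst$clumps, recursive = FALSE), `[[`, "members")))))
    }
  }
})

test_that("the under-5-SNP filter and arm threshold gate reported loci", {
  geno <- generate_genotypes(900, data.frame(n_snp = 8, r = 0.95,
                                             maf = 0.3), seed = 10)
  restore <- retinagrid:::scoped_seed(11)
  on.exit(restore(), add = TRUE)
  y <- matrix(stats::rnorm(900) + 0.5 * geno$dosages[, 4], ncol = 1)
  gw <- gwas_scan(geno, y)
  ld <- ld_r2(geno, 5000)
  cl <- list(px1 = clump_snps(gw$table[, c("snp", "p")], gw$snp_meta, ld))
  base <- consolidate_loci(gw, cl, gw$snp_meta, min_snps = 1)
  expect_equal(length(base), 1)
  expect_gte(base[[1]]$n_snps, 5)
  # a min-SNP requirement above the block size removes the locus
  expect_equal(length(consolidate_loci(gw, cl, gw$snp_meta,
                                       min_snps = 50)), 0)
  # an unreachable arm threshold removes it too
  expect_equal(length(consolidate_loci(gw, cl, gw$snp_meta, min_snps = 1,
                                       p_report = 1e-300)), 0)
})

test_that("secondary signals appear exactly when a second independent causal SNP exists", {
  # moderately correlated block: both causal SNPs share a clump
  geno <- generate_genotypes(2500, data.frame(n_snp = 12, r = 0.35,
                                              maf = 0.3), seed = 7)
  restore <- retinagrid:::scoped_seed(8)
  on.exit(restore(), add = TRUE)
  y1 <- matrix(stats::rnorm(2500) + 0.45 * geno$dosages[, 3] +
                 0.45 * geno$dosages[, 9], ncol = 1)
  gw <- gwas_scan(geno, y1)
  ld <- ld_r2(geno, 5000)
  cl <- list(px1 = clump_snps(gw$table[, c("snp", "p")], gw$snp_meta, ld))
  loci <- consolidate_loci(gw, cl, gw$snp_meta, min_snps = 1)
  expect_equal(length(loci), 1)
  sec <- detect_secondary(loci[[1]], geno, y1, threshold = 5e-8)
  other <- setdiff(c("rs3", "rs9"), loci[[1]]$sentinel)
  expect_true(other %in% sec)

  # single causal SNP: no secondary
  y2 <- matrix(stats::rnorm(2500) + 0.5 * geno$dosages[, 3], ncol = 1)
  gw2 <- gwas_scan(geno, y2)
  cl2 <- list(px1 = clump_snps(gw2$table[, c("snp", "p")], gw2$snp_meta,
                               ld))
  loci2 <- consolidate_loci(gw2, cl2, gw2$snp_meta, min_snps = 1)
  sec2 <- detect_secondary(loci2[[1]], geno, y2, threshold = 5e-8)
  expect_equal(length(sec2), 0)
})

test_that("cross-stratum concordance reaches the analytic extremes", {
  restore <- retinagrid:::scoped_seed(9)
  on.exit(restore(), add = TRUE)
  eff <- matrix(stats::rnorm(5 * 100), 5, 100)
  cc <- cross_stratum_concordance(eff, eff, top_a = eff[, 1],
                                  top_b = eff[, 1])
  expect_equal(cc$per_sentinel, rep(1, 5))
  expect_equal(cc$top_pearson, 1)
  neg <- cross_stratum_concordance(eff, -eff)
  expect_equal(neg$per_sentinel, rep(-1, 5))
  # independent strata: small rank correlations
  meds <- replicate(100, {
    stats::median(abs(cross_stratum_concordance(
      matrix(stats::rnorm(300), 3), matrix(stats::rnorm(300),
                                           3))$per_sentinel))
  })
  expect_lt(stats::median(meds), 0.1)
})

test_that("the gene evidence score is the plain sum of its ten indicators", {
  expect_equal(evidence_score(rep(FALSE, 10)), 0L)
  expect_equal(evidence_score(rep(TRUE, 10)), 10L)
  flags <- rep(FALSE, 10)
  flags[c(1, 4, 9)] <- TRUE    # positional, retina eQTL, mouse eye
  expect_equal(evidence_score(flags), 3L)
  expect_error(evidence_score(rep(TRUE, 9)))
})
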