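#' Per-SNP additive association scan over all phenotypes
#'
#' Covariates are regressed out of both the phenotype matrix and the
#' dosage matrix once (shared QR); the per-(SNP, phenotype) slope, SE and
#' p-value are then computed from the residualised vectors, which is
#' algebraically identical to the joint multiple regression for each pair
#' (Frisch-Waugh-Lovell). Hemizygous chrX males must already be coded
#' \{0, 2\}. Monomorphic SNPs are skipped.
#'
#' @param genotypes a `genotype_matrix` (see [generate_genotypes()]).
#' @param outcomes a [cohort_matrix()], or a plain individuals x
#'   phenotypes matrix (e.g. FPC scores).
#' @param design a [design_spec()] built on the same individuals (its
#'   factor column is ignored; covariates only), or NULL for
#'   intercept-only adjustment.
#' @param extra_covariate optional numeric vector appended to the
#'   covariates (used for conditional analyses on a sentinel dosage).
#' @return List of class `gwas_grid`: long-format data frame `table`
#'   (snp, phenotype, beta, se, p), matrices `beta`/`se`/`p` (SNPs x
#'   phenotypes), `snp_meta`, `df`, `skipped` (monomorphic SNP ids).
#' @export
gwas_scan <- function(genotypes, outcomes, design = NULL,
                      extra_covariate = NULL) {
  y <- if (inherits(outcomes, "cohort_matrix")) outcomes$matrix
       else as.matrix(outcomes)
  g <- genotypes$dosages
  stopifnot(nrow(g) == nrow(y))
  if (is.null(colnames(y))) colnames(y) <- paste0("px", seq_len(ncol(y)))
  if (!is.null(design)) {
    keep <- design$keep
    X <- design$X[, setdiff(colnames(design$X), "factor"), drop = FALSE]
    y <- y[keep, , drop = FALSE]
    g <- g[keep, , drop = FALSE]
  } else {
    X <- matrix(1, nrow(y), 1)
  }
  if (!is.null(extra_covariate)) {
    X <- cbind(X, extra = extra_covariate)
  }
  mono <- apply(g, 2, function(col) length(unique(col)) == 1)
  skipped <- colnames(g)[mono]
  qrX <- qr(X)
  yr <- y - X %*% qr.coef(qrX, y)
  gr <- g - X %*% qr.coef(qrX, g)
  gr[, mono] <- NA
  n <- nrow(y)
  df <- n - ncol(X) - 1L
  gg <- colSums(gr^2)
  yy <- colSums(yr^2)
  bnum <- crossprod(gr, yr)                      # SNPs x phenotypes
  beta <- bnum / gg
  rss <- matrix(yy, nrow(beta), ncol(beta), byrow = TRUE) - beta^2 * gg
  rss[rss < 0] <- 0
  se <- sqrt(rss / (df * gg))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  dimnames(beta) <- dimnames(se) <- dimnames(p) <-
    list(colnames(g), colnames(y))
  pheno_names <- colnames(y)
  if (is.null(pheno_names)) pheno_names <- paste0("px", seq_len(ncol(y)))
  tab <- data.frame(
    snp = rep(rownames(beta), times = ncol(beta)),
    phenotype = rep(pheno_names, each = nrow(beta)),
    beta = as.vector(beta), se = as.vector(se), p = as.vector(p),
    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$beta), , drop = FALSE]
  structure(list(table = tab, beta = beta, se = se, p = p,
                 snp_meta = genotypes$snp_meta, df = df, skipped = skipped),
            class = "gwas_grid")
}

#' Pairwise dosage r-squared within a distance window
#'
#' @param genotypes a `genotype_matrix`.
#' @param window_kb maximum distance between pair members, kb.
#' @return Data frame (snp_a, snp_b, r2) for all within-chromosome pairs
#'   inside the window (a < b by position).
#' @export
ld_r2 <- function(genotypes, window_kb = 5000) {
  meta <- genotypes$snp_meta
  dos <- genotypes$dosages
  out <- list()
  for (chrom in unique(meta$chrom)) {
    idx <- which(meta$chrom == chrom)
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE]))
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    dist_ok <- abs(meta$pos[idx[pairs[, 1]]] - meta$pos[idx[pairs[, 2]]]) <=
      window_kb * 1000
    pairs <- pairs[dist_ok, , drop = FALSE]
    if (nrow(pairs) == 0) next
    out[[chrom]] <- data.frame(
      snp_a = meta$id[idx[pairs[, 1]]], snp_b = meta$id[idx[pairs[, 2]]],
      r2 = cm[pairs]^2, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res)) res <- data.frame(snp_a = character(0),
                                      snp_b = character(0), r2 = numeric(0))
  res
}

# symmetric lookup table of r2 between named SNPs
.r2_lookup <- function(ld) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b) if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
  for (i in seq_len(nrow(ld))) {
    assign(key(ld$snp_a[i], ld$snp_b[i]), ld$r2[i], envir = env)
  }
  function(a, b) {
    if (a == b) return(1)
    v <- mget(key(a, b), envir = env, ifnotfound = list(0))[[1]]
    v
  }
}

#' LD clumping of one phenotype's association results
#'
#' Every SNP with p < `p_index` becomes an index SNP; its clump contains
#' all SNPs with p < `p_member`, r2 > `r2_min` with the index, and within
#' `window_kb` of it. There is no greedy removal: a SNP may belong to
#' several clumps.
#'
#' @param assoc data frame (snp, p) for one phenotype.
#' @param snp_meta SNP metadata (id, chrom, pos).
#' @param ld pairwise r2 table from [ld_r2()].
#' @param p_index,p_member index / member p-value thresholds.
#' @param r2_min exclusive r2 lower bound for membership.
#' @param window_kb distance window, kb (inclusive).
#' @return List of clumps: each has `index`, `members` (character, always
#'   including the index).
#' @export
clump_snps <- function(assoc, snp_meta, ld, p_index = 5e-8,
                       p_member = 5e-5, r2_min = 0.001, window_kb = 5000) {
  look <- .r2_lookup(ld)
  pos <- stats::setNames(snp_meta$pos, snp_meta$id)
  chrom <- stats::setNames(snp_meta$chrom, snp_meta$id)
  idx_snps <- assoc$snp[assoc$p < p_index]
  cand <- assoc[assoc$p < p_member, , drop = FALSE]
  lapply(idx_snps, function(s) {
    same <- cand$snp[chrom[cand$snp] == chrom[s] &
                       abs(pos[cand$snp] - pos[s]) <= window_kb * 1000]
    members <- same[vapply(same, function(m) look(s, m) > r2_min,
                           logical(1))]
    list(index = s, members = unique(c(s, setdiff(members, s))))
  })
}

#' Iterative consolidation of clumped associations into loci
#'
#' Implements the iterative allocation loop over the extracted
#' associations: while any (SNP, phenotype) pair remains with
#' p < `p_iter`, take the most significant pair (ties broken by
#' (p, chrom, pos, phenotype) lexicographic order). If the SNP indexes a
#' clump for that phenotype, a new locus is created with that SNP as
#' sentinel and the phenotype as top phenotype; the clump members become
#' supporting SNPs; every phenotype with p < `p_support` for the sentinel
#' or any supporting SNP is allocated to the locus; and all (locus SNP,
#' allocated phenotype) pairs are removed from the list. Otherwise the SNP
#' must be a clump member whose index has already founded a locus (a hard
#' error flags upstream inconsistency if not), and the clump's remaining
#' pairs for that phenotype are removed. Afterwards loci with fewer than
#' `min_snps` assigned SNPs are dropped, and only loci whose sentinel
#' meets `p_report` (the analysis arm's Bonferroni threshold) are
#' reported.
#'
#' @param gwas a `gwas_grid` (or a long data frame snp/phenotype/p).
#' @param clumps named list: per phenotype, the [clump_snps()] result.
#' @param snp_meta SNP metadata (id, chrom, pos).
#' @param p_iter iteration threshold (default 5e-8).
#' @param p_support support/allocation threshold (default 5e-5).
#' @param min_snps minimum SNPs per reported locus (default 5).
#' @param p_report sentinel reporting threshold (arm Bonferroni; default
#'   `p_iter`, i.e. no extra filter).
#' @return Data-frame-free list of loci; each locus has `sentinel`,
#'   `top_phenotype`, `sentinel_p`, `supporting` (character),
#'   `phenotypes` (character), `n_snps`.
#' @export
consolidate_loci <- function(gwas, clumps, snp_meta, p_iter = 5e-8,
                             p_support = 5e-5, min_snps = 5,
                             p_report = p_iter) {
  tab <- if (inherits(gwas, "gwas_grid")) gwas$table else gwas
  stopifnot(all(c("snp", "phenotype", "p") %in% names(tab)))
  pos <- stats::setNames(snp_meta$pos, snp_meta$id)
  chrom <- stats::setNames(snp_meta$chrom, snp_meta$id)
  live <- tab[tab$p < p_support, , drop = FALSE]   # only these matter
  ord <- order(live$p, chrom[live$snp], pos[live$snp], live$phenotype)
  live <- live[ord, , drop = FALSE]
  key <- paste(live$snp, live$phenotype, sep = "\r")
  alive <- rep(TRUE, nrow(live))
  loci <- list()
  sentinel_of <- character(0)                      # snp -> locus index
  repeat {
    cand <- which(alive & live$p < p_iter)
    if (length(cand) == 0) break
    i <- cand[1]
    s <- live$snp[i]; q <- live$phenotype[i]
    cl <- clumps[[q]]
    idx_match <- which(vapply(cl, function(x) x$index == s, logical(1)))
    if (length(idx_match) >= 1) {
      # clump members already satisfy p < p_support for this phenotype
      members <- union(s, unique(unlist(lapply(idx_match,
                                               function(j) cl[[j]]$members))))
      loc_phenos <- unique(live$phenotype[alive & live$snp %in% members])
      loci[[length(loci) + 1L]] <- list(
        sentinel = s, top_phenotype = q, sentinel_p = live$p[i],
        supporting = setdiff(members, s), phenotypes = loc_phenos,
        n_snps = length(members))
      sentinel_of[s] <- length(loci)
      drop <- alive & live$snp %in% members & live$phenotype %in% loc_phenos
      alive[drop] <- FALSE
    } else {
      # non-index SNP: find the clump(s) containing it for this phenotype
      holding <- Filter(function(x) s %in% x$members, cl)
      if (length(holding) == 0) {
        stop(sprintf(
          "inconsistent clump bookkeeping: %s (%s) is neither index nor member",
          s, q))
      }
      assigned <- Filter(function(x) x$index %in% names(sentinel_of),
                         holding)
      if (length(assigned) == 0) {
        stop(sprintf(
          "inconsistent clump bookkeeping: no clump index for %s (%s) has a locus",
          s, q))
      }
      members <- unique(unlist(lapply(assigned, function(x) x$members)))
      drop <- alive & live$phenotype == q & live$snp %in% members
      alive[drop] <- FALSE
    }
  }
  keep <- vapply(loci, function(l) {
    l$n_snps >= min_snps && l$sentinel_p < p_report
  }, logical(1))
  loci[keep]
}

#' Conditional secondary-signal detection for one locus
#'
#' Re-runs the association scan for the locus's top phenotype with the
#' sentinel SNP's dosage added to the covariates; any locus SNP whose
#' conditional p-value meets the arm threshold is reported as a secondary
#' signal. Candidates nearly collinear with the sentinel (r2 > 0.99) are
#' skipped.
#'
#' @param locus one element of the [consolidate_loci()] result.
#' @param genotypes a `genotype_matrix`.
#' @param outcomes phenotype matrix / [cohort_matrix()] used in the scan.
#' @param design the covariate [design_spec()] (or NULL).
#' @param threshold arm-specific Bonferroni threshold for secondary
#'   signals.
#' @return Character vector of secondary SNP ids (possibly empty).
#' @export
detect_secondary <- function(locus, genotypes, outcomes, design = NULL,
                             threshold = 5e-8) {
  snps <- setdiff(c(locus$sentinel, locus$supporting), locus$sentinel)
  if (length(snps) == 0) return(character(0))
  sel <- match(c(locus$sentinel, snps), genotypes$snp_meta$id)
  sentinel_dos <- genotypes$dosages[, sel[1]]
  if (!is.null(design)) sentinel_dos <- sentinel_dos[design$keep]
  sub <- list(dosages = genotypes$dosages[, sel[-1], drop = FALSE],
              snp_meta = genotypes$snp_meta[sel[-1], , drop = FALSE],
              blocks = NULL, sex = NULL)
  class(sub) <- "genotype_matrix"
  y <- if (inherits(outcomes, "cohort_matrix")) outcomes$matrix
       else as.matrix(outcomes)
  if (is.null(colnames(y))) colnames(y) <- paste0("px", seq_len(ncol(y)))
  y1 <- y[, locus$top_phenotype, drop = FALSE]
  # drop near-collinear candidates
  dos_check <- if (!is.null(design)) {
    sub$dosages[design$keep, , drop = FALSE]
  } else sub$dosages
  r2 <- suppressWarnings(stats::cor(dos_check, sentinel_dos))^2
  ok <- is.na(r2) | r2 <= 0.99
  if (!any(ok)) return(character(0))
  sub$dosages <- sub$dosages[, ok, drop = FALSE]
  sub$snp_meta <- sub$snp_meta[ok, , drop = FALSE]
  scan <- gwas_scan(sub, y1, design, extra_covariate = sentinel_dos)
  hits <- scan$table$snp[scan$table$p < threshold]
  hits
}

#' Cross-stratum concordance of per-pixel SNP effects
#'
#' For each sentinel, the Spearman rank correlation of its per-pixel betas
#' between two strata (e.g. ancestry groups); plus the Pearson
#' correlation of the sentinels' top-phenotype betas across strata.
#'
#' @param effects_a,effects_b SNPs x pixels beta matrices on matched
#'   dimensions (rows = sentinels).
#' @param top_a,top_b optional vectors of top-phenotype betas per sentinel.
#' @return List: `per_sentinel` (Spearman r per row), `top_pearson`
#'   (Pearson r of top betas, NA when not supplied).
#' @export
cross_stratum_concordance <- function(effects_a, effects_b,
                                      top_a = NULL, top_b = NULL) {
  stopifnot(all(dim(effects_a) == dim(effects_b)))
  per <- vapply(seq_len(nrow(effects_a)), function(i) {
    suppressWarnings(stats::cor(effects_a[i, ], effects_b[i, ],
                                method = "spearman"))
  }, numeric(1))
  top <- if (!is.null(top_a) && !is.null(top_b)) {
    stats::cor(top_a, top_b)
  } else NA_real_
  list(per_sentinel = per, top_pearson = top)
}

#' Candidate-gene evidence score
#'
#' Sum of ten binary lines of evidence for a gene at a locus: positional
#' mapping; exonic candidate SNP; candidate SNP with CADD >= 20; retina
#' eQTL; blood eQTL; brain eQTL; brain chromatin interaction; retina
#' chromatin interaction; mouse eye-abnormality phenotype; retinal OMIM
#' phenotype.
#'
#' @param flags logical vector of length 10.
#' @return Integer in 0..10.
#' @export
evidence_score <- function(flags) {
  stopifnot(length(flags) == 10, is.logical(flags) | all(flags %in% 0:1))
  as.integer(sum(flags))
}

#' Flatten a locus list to a reporting table
#'
#' @param loci result of [consolidate_loci()].
#' @param secondary optional named list: per sentinel, character vector of
#'   secondary SNPs.
#' @return Data frame with columns sentinel, top_phenotype, sentinel_p,
#'   n_snps, n_phenotypes, supporting, snp_secondary (semicolon-joined).
#' @export
loci_table <- function(loci, secondary = NULL) {
  if (length(loci) == 0) {
    return(data.frame(sentinel = character(0), top_phenotype = character(0),
                      sentinel_p = numeric(0), n_snps = integer(0),
                      n_phenotypes = integer(0), supporting = character(0),
                      snp_secondary = character(0)))
  }
  do.call(rbind, lapply(loci, function(l) {
    sec <- if (!is.null(secondary) && l$sentinel %in% names(secondary)) {
      paste(secondary[[l$sentinel]], collapse = ";")
    } else ""
    data.frame(sentinel = l$sentinel, top_phenotype = l$top_phenotype,
               sentinel_p = l$sentinel_p, n_snps = l$n_snps,
               n_phenotypes = length(l$phenotypes),
               supporting = paste(l$supporting, collapse = ";"),
               snp_secondary = sec, stringsAsFactors = FALSE)
  }))
}
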