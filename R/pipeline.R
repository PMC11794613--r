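#' Pipeline configuration
#'
#' Collects thresholds and settings used across stages. Bonferroni
#' divisors are derived from the pixel/FPC counts actually in use.
#'
#' @param cohort a [cohort_config()] describing the synthetic inputs.
#' @param genome_wide_p genome-wide significance threshold (5e-8).
#' @param support_p clump/support threshold (5e-5).
#' @param r2_min clump membership r2 lower bound.
#' @param window_kb clump distance window, kb.
#' @param min_snps minimum SNPs per reported locus.
#' @param fpc_target cumulative variance target selecting the number of
#'   FPCs.
#' @param assoc_alpha BH significance level for pixel-wise factor
#'   associations.
#' @param fpc_alpha BH significance level for FPC associations.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            genome_wide_p = 5e-8, support_p = 5e-5,
                            r2_min = 0.001, window_kb = 5000,
                            min_snps = 5, fpc_target = 0.95,
                            assoc_alpha = 0.05, fpc_alpha = 0.01) {
  stopifnot(genome_wide_p > 0, support_p > 0, r2_min > 0, window_kb > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Bonferroni-corrected reporting threshold for one analysis arm
#'
#' Divides the genome-wide threshold by the number of phenotypes tested in
#' that arm (pixels or FPCs), e.g. 5e-8 / 29041 for the full-resolution
#' pixel grid and 5e-8 / 6 for six FPCs.
#'
#' @param n_phenotypes number of parallel GWAS in the arm.
#' @param genome_wide_p base threshold (default 5e-8).
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(n_phenotypes, genome_wide_p = 5e-8) {
  stopifnot(n_phenotypes >= 1)
  genome_wide_p / n_phenotypes
}

#' Run the full synthetic pipeline end to end
#'
#' synth -> align/trim/impute -> phenotype assembly -> FPCA -> GWAS ->
#' clumping -> loci consolidation. Factor association stages are exposed
#' through their own functions and run here only when the cohort carries
#' factors. All randomness flows from the master seed.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed.
#' @return List: `cohort_data` (the synthetic inputs), `cohort`
#'   ([cohort_matrix()]), `fpca`, `scores`, `gwas_px`, `loci_px`,
#'   `gwas_fpc`, `loci_fpc`, `thresholds`, and per-factor association
#'   results in `assoc` when factors exist.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- generate_cohort(config$cohort, seed)

  aligned <- lapply(syn$grids, function(g) {
    list(left = if (!is.null(g$left)) align_scan(g$left) else NULL,
         right = if (!is.null(g$right)) align_scan(g$right) else NULL)
  })
  all_grids <- unlist(lapply(aligned, function(g) {
    Filter(Negate(is.null), g)
  }), recursive = FALSE)
  trim <- trim_pixel_grid(all_grids)
  imputed <- lapply(aligned, function(g) {
    list(left = if (!is.null(g$left)) impute_scan(g$left) else NULL,
         right = if (!is.null(g$right)) impute_scan(g$right) else NULL)
  })
  asm <- assemble_phenotypes(imputed, trim$keep, ids = syn$covariates$id)
  cohort <- asm$cohort
  keep_ind <- match(rownames(cohort$matrix), syn$covariates$id)
  covs <- syn$covariates[keep_ind, , drop = FALSE]
  covs$eye_code <- cohort$eye_code
  geno <- syn$genotypes
  geno$dosages <- geno$dosages[keep_ind, , drop = FALSE]

  model <- fit_fpca(cohort, n_components = min(100, nrow(cohort$matrix) - 1))
  n_fpc <- n_components_for(model, config$fpc_target)
  scores <- model$scores[, seq_len(n_fpc), drop = FALSE]
  colnames(scores) <- paste0("FPC", seq_len(n_fpc))

  des <- design_spec(stats::rnorm(nrow(covs)), covs)   # covariates only
  gwas_px <- gwas_scan(geno, cohort, des)
  gwas_fpc <- gwas_scan(geno, scores, des)
  ld <- ld_r2(geno, config$window_kb)

  consolidate_arm <- function(gw, n_phen) {
    phenos <- unique(gw$table$phenotype)
    clumps <- lapply(stats::setNames(phenos, phenos), function(q) {
      clump_snps(gw$table[gw$table$phenotype == q, c("snp", "p")],
                 gw$snp_meta, ld, config$genome_wide_p, config$support_p,
                 config$r2_min, config$window_kb)
    })
    consolidate_loci(gw, clumps, gw$snp_meta, config$genome_wide_p,
                     config$support_p, config$min_snps,
                     p_report = bonferroni_threshold(n_phen,
                                                     config$genome_wide_p))
  }
  loci_px <- consolidate_arm(gwas_px, ncol(cohort$matrix))
  loci_fpc <- consolidate_arm(gwas_fpc, n_fpc)

  assoc <- list()
  fac <- syn$factors
  if (!is.null(fac$continuous)) {
    for (nm in colnames(fac$continuous)) {
      d <- design_spec(fac$continuous[keep_ind, nm], covs)
      assoc[[nm]] <- moderate_variances(fit_mass_linear(cohort, d))
    }
  }

  list(cohort_data = syn, cohort = cohort, trim = trim, covariates = covs,
       fpca = model, n_fpc = n_fpc, scores = scores,
       gwas_px = gwas_px, gwas_fpc = gwas_fpc,
       loci_px = loci_px, loci_fpc = loci_fpc, assoc = assoc,
       thresholds = list(
         pixel = bonferroni_threshold(ncol(cohort$matrix),
                                      config$genome_wide_p),
         fpc = bonferroni_threshold(n_fpc, config$genome_wide_p)),
       removed = asm$removed)
}

#' Serialise a cohort matrix to TSV + JSON sidecar
#'
#' @param cohort a [cohort_matrix()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(cohort$matrix)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(cohort$matrix)))
  m <- as.data.frame(cohort$matrix)
  m <- cbind(data.frame(id = ids, eye_code = cohort$eye_code), m)
  write_tsv(m, file.path(dir, "matrix.tsv"))
  write_tsv(cohort$pixel_index, file.path(dir, "pixel_index.tsv"))
  jsonlite::write_json(list(row_scale = cohort$row_scale,
                            col_scale = cohort$col_scale),
                       file.path(dir, "geometry.json"), auto_unbox = TRUE)
}

#' Read a cohort matrix written by [write_cohort()]
#' @param dir directory.
#' @return A [cohort_matrix()].
#' @export
read_cohort <- function(dir) {
  m <- read_tsv(file.path(dir, "matrix.tsv"))
  px <- read_tsv(file.path(dir, "pixel_index.tsv"))
  geo <- jsonlite::read_json(file.path(dir, "geometry.json"))
  mat <- as.matrix(m[, -(1:2), drop = FALSE])
  rownames(mat) <- m$id
  colnames(mat) <- NULL
  cohort_matrix(mat, px, m$eye_code, geo$row_scale, geo$col_scale)
}
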