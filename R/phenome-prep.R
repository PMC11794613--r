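#' Clean a raw blood trait with technical-effect adjustment
#'
#' The trait is log- (counts) or logit- (proportions/ratios in (0,1))
#' transformed; an additive technical model (cubic smooth in acquisition
#' time plus categorical instrument, acquisition route and day effects) is
#' fitted on the central measurements (within 3.5 MAD of the median); all
#' values are adjusted by the predicted technical effect; and outliers
#' beyond 6 MAD of the adjusted trait's median are excluded.
#'
#' @param values raw trait values.
#' @param technical data frame with columns `time` (numeric),
#'   `instrument`, `route`, `day` (categorical).
#' @param transform "log", "logit" or "none".
#' @return List of class `cleaned_factor`: `values` (adjusted, NA for
#'   excluded), `transform`, `excluded` (indices with reason),
#'   `technical_fit` (the fitted model).
#' @export
clean_blood_trait <- function(values, technical,
                              transform = c("log", "logit", "none")) {
  transform <- match.arg(transform)
  stopifnot(nrow(technical) == length(values),
            all(c("time", "instrument", "route", "day") %in%
                  names(technical)))
  x <- switch(transform,
    log = { stopifnot(all(values > 0, na.rm = TRUE)); log(values) },
    logit = {
      v <- pmin(pmax(values, 1e-6), 1 - 1e-6)
      log(v / (1 - v))
    },
    none = values)
  med <- stats::median(x, na.rm = TRUE)
  mad <- stats::mad(x, na.rm = TRUE)
  if (mad == 0) {
    warning("degenerate MAD = 0; skipping centrality restriction")
    central <- !is.na(x)
  } else {
    central <- !is.na(x) & abs(x - med) < 3.5 * mad
  }
  if (sum(central) < 50) stop("fewer than 50 central observations")
  df <- data.frame(x = x, time = technical$time,
                   instrument = factor(technical$instrument),
                   route = factor(technical$route),
                   day = factor(technical$day))
  form <- x ~ s(time, k = 8)
  for (v in c("instrument", "route", "day")) {
    if (nlevels(df[[v]]) > 1) {
      form <- stats::update.formula(form, paste("~ . +", v))
    }
  }
  fit <- mgcv::gam(form, data = df[central, ])
  tech_pred <- as.numeric(stats::predict(fit, newdata = df))
  adj <- x - (tech_pred - mean(tech_pred, na.rm = TRUE))
  med2 <- stats::median(adj, na.rm = TRUE)
  mad2 <- stats::mad(adj, na.rm = TRUE)
  out_mask <- !is.na(adj) & mad2 > 0 & abs(adj - med2) > 6 * mad2
  excluded <- data.frame(index = which(out_mask),
                         reason = rep("outlier_6mad", sum(out_mask)))
  adj[out_mask] <- NA
  structure(list(values = adj, transform = transform, excluded = excluded,
                 technical_fit = fit), class = "cleaned_factor")
}

#' Systemic inflammation indices from blood counts
#'
#' NLR = neutrophils/lymphocytes; PLR = platelets/lymphocytes;
#' LMR = lymphocytes/monocytes; SII = neutrophils x platelets /
#' lymphocytes.
#'
#' @param neutrophils,lymphocytes,monocytes,platelets positive counts.
#' @return Data frame with columns nlr, plr, lmr, sii (NA with a reason
#'   attribute where a denominator is zero or missing).
#' @export
inflammation_indices <- function(neutrophils, lymphocytes, monocytes,
                                 platelets) {
  n <- length(neutrophils)
  stopifnot(length(lymphocytes) == n, length(monocytes) == n,
            length(platelets) == n)
  safe_div <- function(a, b) ifelse(!is.na(b) & b > 0, a / b, NA_real_)
  data.frame(
    nlr = safe_div(neutrophils, lymphocytes),
    plr = safe_div(platelets, lymphocytes),
    lmr = safe_div(lymphocytes, monocytes),
    sii = safe_div(neutrophils * platelets, lymphocytes))
}

#' Prepare a metabolite matrix: transform, impute, recompute ratios
#'
#' Non-derived metabolites are square-root transformed for symmetry.
#' Missing values are filled by a simple chained conditional-mean imputer:
#' starting from marginal means, each incomplete metabolite is repeatedly
#' regressed on the others and its missing entries replaced by fitted
#' values; the procedure is run `repeats` times from noise-perturbed
#' starts (seeded) and the results averaged. Configured derived ratios are
#' recomputed from the back-transformed components and then square-root
#' transformed.
#'
#' @param mat individuals x metabolites matrix of non-negative raw values.
#' @param ratios optional named list: each element `c(num, den)` of column
#'   names defining a derived ratio to (re)compute.
#' @param repeats number of averaged imputation repeats.
#' @param sweeps chained-regression sweeps per repeat.
#' @param seed integer seed.
#' @return List of class `metabolite_set`: `values` (sqrt scale, complete),
#'   `imputed_mask`, `transform` = "sqrt".
#' @export
prepare_metabolites <- function(mat, ratios = NULL, repeats = 5,
                                sweeps = 3, seed = 1) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("negative metabolite values")
  x <- sqrt(mat)
  miss <- is.na(x)
  if (any(miss)) {
    restore <- scoped_seed(seed)
    on.exit(restore(), add = TRUE)
    acc <- 0
    for (rep_i in seq_len(repeats)) {
      xi <- x
      for (j in seq_len(ncol(xi))) {
        mj <- mean(xi[, j], na.rm = TRUE)
        sj <- stats::sd(xi[, j], na.rm = TRUE)
        xi[miss[, j], j] <- mj + stats::rnorm(sum(miss[, j]), 0,
                                              if (is.na(sj)) 0 else sj)
      }
      for (sw in seq_len(sweeps)) {
        for (j in which(colSums(miss) > 0)) {
          others <- xi[, -j, drop = FALSE]
          fit <- stats::lm.fit(cbind(1, others), xi[, j])
          pred <- cbind(1, others) %*% fit$coefficients
          xi[miss[, j], j] <- pred[miss[, j]]
        }
      }
      acc <- acc + xi
    }
    x <- acc / repeats
  }
  if (!is.null(ratios)) {
    raw <- x^2                                   # back to raw scale
    for (nm in names(ratios)) {
      pr <- ratios[[nm]]
      x <- cbind(x, sqrt(raw[, pr[1]] / raw[, pr[2]]))
      colnames(x)[ncol(x)] <- nm
    }
  }
  structure(list(values = x, imputed_mask = miss, transform = "sqrt"),
            class = "metabolite_set")
}

#' Definition of a genetic (risk) score
#'
#' @param trait trait name.
#' @param snps data frame: `chrom`, `pos`, `effect_allele`, `weight`.
#' @param type "trait", "metabolic" or "internal"; metabolic scores
#'   require at least three SNPs.
#' @return List of class `score_definition`.
#' @export
score_definition <- function(trait, snps, type = c("trait", "metabolic",
                                                   "internal")) {
  type <- match.arg(type)
  stopifnot(all(c("chrom", "pos", "effect_allele", "weight") %in%
                  names(snps)), all(is.finite(snps$weight)))
  if (type == "metabolic" && nrow(snps) < 3) {
    stop("metabolic scores require at least 3 SNPs")
  }
  structure(list(trait = trait, snps = snps, type = type),
            class = "score_definition")
}

#' Build a weighted allele-dosage genetic score
#'
#' `score_i = sum_k weight_k * dosage_i(effect allele k)`. SNPs are
#' matched by (chrom, pos); when the effect allele is the reference
#' allele the dosage is flipped (2 - d). Unmatched SNPs are dropped with a
#' warning; a metabolic score with fewer than three matched SNPs is
#' rejected.
#'
#' @param defn a [score_definition()].
#' @param genotypes a `genotype_matrix`.
#' @return Numeric per-individual score with attribute `n_matched`.
#' @export
build_genetic_score <- function(defn, genotypes) {
  stopifnot(inherits(defn, "score_definition"))
  meta <- genotypes$snp_meta
  score <- numeric(nrow(genotypes$dosages))
  matched <- 0L
  for (k in seq_len(nrow(defn$snps))) {
    s <- defn$snps[k, ]
    j <- which(meta$chrom == as.character(s$chrom) & meta$pos == s$pos)
    if (length(j) == 0) {
      warning(sprintf("score SNP %s:%d not found; dropped",
                      as.character(s$chrom), s$pos))
      next
    }
    j <- j[1]
    d <- genotypes$dosages[, j]
    if (s$effect_allele == meta$alt[j]) {
      # effect allele is ALT: dosage counts it directly
    } else if (s$effect_allele == meta$ref[j]) {
      d <- 2 - d
    } else {
      warning(sprintf("allele mismatch for %s:%d; dropped",
                      as.character(s$chrom), s$pos))
      next
    }
    score <- score + s$weight * d
    matched <- matched + 1L
  }
  if (defn$type == "metabolic" && matched < 3) {
    stop("metabolic score with fewer than 3 matched SNPs rejected")
  }
  attr(score, "n_matched") <- matched
  score
}

#' Map ICD diagnosis records to binary PheCodes
#'
#' @param icd_records data frame with columns `individual`, `icd`.
#' @param phecode_map data frame with columns `icd`, `phecode`,
#'   `category`.
#' @param individuals character vector fixing the row order (defaults to
#'   the individuals present in the records).
#' @return List: `matrix` (individuals x phecodes, 0/1), `unmapped`
#'   (ICD codes absent from the map), `categories` (phecode -> category).
#' @export
map_phecodes <- function(icd_records, phecode_map, individuals = NULL) {
  stopifnot(all(c("individual", "icd") %in% names(icd_records)),
            all(c("icd", "phecode") %in% names(phecode_map)))
  if (is.null(individuals)) {
    individuals <- unique(icd_records$individual)
  }
  phecodes <- sort(unique(phecode_map$phecode))
  m <- matrix(0L, length(individuals), length(phecodes),
              dimnames = list(individuals, as.character(phecodes)))
  merged <- merge(icd_records, phecode_map, by = "icd")
  for (i in seq_len(nrow(merged))) {
    ind <- as.character(merged$individual[i])
    if (ind %in% individuals) {
      m[ind, as.character(merged$phecode[i])] <- 1L
    }
  }
  unmapped <- setdiff(unique(icd_records$icd), unique(phecode_map$icd))
  cats <- if ("category" %in% names(phecode_map)) {
    unique(phecode_map[, c("phecode", "category")])
  } else NULL
  list(matrix = m, unmapped = unmapped, categories = cats)
}
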