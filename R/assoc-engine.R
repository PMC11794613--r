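#' Build the design specification for factor-thickness association
#'
#' The factor of interest and all quantitative covariates are standardised
#' to mean 0, variance 1 (which also defuses the age/age-squared
#' collinearity); device and eye code enter as categorical. Rows with
#' missing values in any design column are dropped and counted.
#'
#' @param factor numeric (or 0/1) vector, the factor of interest.
#' @param covariates data frame with columns age, sex, height,
#'   spherical_equivalent, device, eye_code and PC1..PC10; extra columns
#'   named in `extra` are appended as standardised covariates.
#' @param extra character vector of additional covariate columns (e.g.
#'   "bmi", "smoking").
#' @param interaction logical; add a factor x age interaction term.
#' @param standardise_binary logical; standardise binary factors too
#'   (default TRUE, making betas comparable across factors).
#' @return List of class `design_spec`: `X` (model matrix with the factor
#'   in column "factor"), `keep` (logical complete-case mask),
#'   `n_dropped`.
#' @export
design_spec <- function(factor, covariates, extra = character(0),
                        interaction = FALSE, standardise_binary = TRUE) {
  need <- c("age", "sex", "height", "spherical_equivalent", "device",
            "eye_code", paste0("PC", 1:10))
  stopifnot(all(need %in% names(covariates)),
            length(factor) == nrow(covariates))
  df <- covariates[, c(need, extra), drop = FALSE]
  df$.factor <- factor
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  std <- function(x) as.numeric(standardise(as.numeric(x)))
  is_binary <- all(df$.factor %in% c(0, 1))
  fac <- if (!is_binary || standardise_binary) std(df$.factor) else df$.factor
  age <- std(df$age)
  cols <- list(
    "(Intercept)" = rep(1, nrow(df)),
    factor = fac,
    sex = as.numeric(df$sex),
    age = age,
    age2 = std(df$age^2),
    height = std(df$height),
    spherical_equivalent = std(df$spherical_equivalent))
  dev <- factor(df$device)
  if (nlevels(dev) > 1) {
    dm <- stats::model.matrix(~dev)[, -1, drop = FALSE]
    colnames(dm) <- paste0("device", levels(dev)[-1])
    cols <- c(cols, as.list(as.data.frame(dm)))
  }
  eye <- factor(df$eye_code)
  if (nlevels(eye) > 1) {
    em <- stats::model.matrix(~eye)[, -1, drop = FALSE]
    colnames(em) <- paste0("eye", levels(eye)[-1])
    cols <- c(cols, as.list(as.data.frame(em)))
  }
  for (pc in paste0("PC", 1:10)) cols[[pc]] <- std(df[[pc]])
  for (e in extra) cols[[e]] <- std(df[[e]])
  if (interaction) {
    if (stats::sd(df$age) == 0) stop("age is constant; no interaction term")
    cols[["factor:age"]] <- fac * age
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, keep = keep, n_dropped = sum(!keep),
                 interaction = interaction),
            class = "design_spec")
}

#' Mass pixel-wise ordinary least squares
#'
#' Fits the same linear model to every pixel (column of the outcome
#' matrix) using one shared QR decomposition of the design, and extracts
#' the coefficient of interest with its standard error, residual degrees
#' of freedom and residual variance.
#'
#' @param cohort a [cohort_matrix()], or a plain individuals x outcomes
#'   numeric matrix.
#' @param design a [design_spec()].
#' @param coef name of the design column to report (default "factor").
#' @return List of class `mass_fit`: vectors `beta`, `se`, `sigma2`,
#'   scalar `df`, plus `t_ord` and two-sided `p_ord` from the ordinary
#'   t-statistic, `coef`, and `stdev_unscaled` (SE / residual SD).
#' @export
fit_mass_linear <- function(cohort, design, coef = "factor") {
  y <- if (inherits(cohort, "cohort_matrix")) cohort$matrix else cohort
  stopifnot(inherits(design, "design_spec"), coef %in% colnames(design$X))
  y <- y[design$keep, , drop = FALSE]
  X <- design$X
  stopifnot(nrow(y) == nrow(X))
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df < 1) stop("not enough residual degrees of freedom")
  qrX <- qr(X)
  coefs <- qr.coef(qrX, y)                       # p x pixels
  res <- y - X %*% coefs
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match(coef, colnames(X))
  unscaled <- sqrt(xtx_inv[j, j])
  beta <- coefs[j, ]
  se <- unscaled * sqrt(sigma2)
  t_ord <- beta / se
  structure(list(beta = beta, se = se, sigma2 = sigma2, df = df,
                 t_ord = t_ord,
                 p_ord = 2 * stats::pt(-abs(t_ord), df),
                 stdev_unscaled = unscaled, coef = coef),
            class = "mass_fit")
}

# solve trigamma(x) = y by Newton iteration on 1/x scale
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of pixel-wise residual variances
#'
#' Borrows information across pixels: residual variances are modelled as
#' draws from a scaled inverse-chi-square prior `s0^2 * d0 / chisq(d0)`,
#' whose hyperparameters are estimated by matching the first two moments
#' of log s^2 (digamma/trigamma equations). Each pixel's variance is
#' shrunk to `(d0 s0^2 + d s^2) / (d0 + d)` and the t-statistic recomputed
#' with `d + d0` degrees of freedom.
#'
#' @param fit a `mass_fit`.
#' @param d0 optional fixed prior df (estimated when NULL; `d0 = 0`
#'   reproduces the ordinary t exactly; `d0 = Inf` pools fully).
#' @return The fit, augmented with `d0`, `s0_2`, `s2_shrunk`, `t_mod`,
#'   `p_mod` and `df_total`, class `moderated_fit`.
#' @export
moderate_variances <- function(fit, d0 = NULL) {
  stopifnot(inherits(fit, "mass_fit"))
  s2 <- fit$sigma2
  d <- fit$df
  if (length(s2) < 10 && is.null(d0)) {
    stop("need >= 10 pixels to estimate the variance prior")
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  if (is.null(d0) && stats::var(z) < 1e-14) {
    # exactly constant variances: nothing to estimate, shrinkage a no-op
    # (limma convention: infinite prior df, so p-values go normal)
    out <- c(fit, list(d0 = Inf, s0_2 = mean(s2), s2_shrunk = s2,
                       t_mod = fit$t_ord,
                       p_mod = 2 * stats::pnorm(-abs(fit$t_ord)),
                       df_total = Inf))
    class(out) <- c("moderated_fit", "mass_fit")
    return(out)
  }
  if (is.null(d0)) {
    evar <- stats::var(e) - trigamma(d / 2)
    if (evar <= 0) {
      warning("no excess dispersion in log-variances; pooling fully")
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(evar)
    }
  }
  if (is.infinite(d0)) {
    s0_2 <- exp(mean(e))
    s2_shrunk <- rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s0_2 <- NA_real_
    s2_shrunk <- s2
  } else {
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_shrunk <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  df_total <- d + d0
  t_mod <- fit$beta / (fit$stdev_unscaled * sqrt(s2_shrunk))
  p_mod <- 2 * stats::pt(-abs(t_mod), df_total)
  out <- c(fit, list(d0 = d0, s0_2 = s0_2, s2_shrunk = s2_shrunk,
                     t_mod = t_mod, p_mod = p_mod, df_total = df_total))
  class(out) <- c("moderated_fit", "mass_fit")
  out
}

#' Multiple-testing adjustment over the pixel-factor grid
#'
#' Three schemes are supported for a pixels x factors matrix of p-values:
#' joint Bonferroni over all tests, joint Benjamini-Hochberg over all
#' tests (the default reporting scheme), and Benjamini-Hochberg across
#' pixels separately within each factor.
#'
#' @param p numeric vector or pixels x factors matrix of p-values.
#' @param scheme one of "bonferroni_global", "bh_global",
#'   "bh_within_factor".
#' @return Adjusted p-values, same shape as `p`.
#' @export
adjust_pvalues <- function(p, scheme = c("bh_global", "bonferroni_global",
                                         "bh_within_factor")) {
  scheme <- match.arg(scheme)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (scheme == "bh_within_factor") {
    if (is.null(dim(p))) stop("bh_within_factor needs a pixels x factors matrix")
    apply(p, 2, stats::p.adjust, method = "BH")
  } else if (scheme == "bh_global") {
    out <- stats::p.adjust(p, method = "BH")
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  } else {
    out <- stats::p.adjust(p, method = "bonferroni")
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
}

#' Scalar summary measures for one factor
#'
#' The four standard per-factor summaries: (i) number of significantly
#' associated pixels, (ii) mean beta over significant pixels (NA when
#' none), (iii) mean beta over all pixels, (iv) median -log10 p over all
#' pixels.
#'
#' @param fit a `moderated_fit`.
#' @param alpha significance level applied to `adjusted_p`.
#' @param adjusted_p adjusted p-values for this factor's pixels (defaults
#'   to BH across its own pixels).
#' @return Named list: `n_sig`, `mean_beta_sig`, `mean_beta_all`,
#'   `median_log10p`.
#' @export
summarize_factor <- function(fit, alpha = 0.05, adjusted_p = NULL) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (is.null(adjusted_p)) {
    adjusted_p <- stats::p.adjust(fit$p_mod, method = "BH")
  }
  sig <- adjusted_p < alpha
  list(n_sig = sum(sig),
       mean_beta_sig = if (any(sig)) mean(fit$beta[sig]) else NA_real_,
       mean_beta_all = mean(fit$beta),
       median_log10p = stats::median(-log10(pmax(fit$p_mod,
                                                 .Machine$double.xmin))))
}

#' Factor x age interaction scan
#'
#' Refits the mass model with main effects plus a factor-by-age
#' interaction, and reports, over pixels whose interaction term is
#' significant, the proportion whose interaction sign agrees with the
#' main-effect sign (an age-amplification summary).
#'
#' @param cohort a [cohort_matrix()] or outcome matrix.
#' @param factor factor values per individual.
#' @param covariates covariate data frame (see [design_spec()]).
#' @param alpha BH significance level for the interaction term.
#' @return List: `main` and `interaction` `moderated_fit`s,
#'   `sign_agreement` (proportion, NA if no significant interaction),
#'   `n_sig_interaction`.
#' @export
interaction_scan <- function(cohort, factor, covariates, alpha = 0.05) {
  des_int <- design_spec(factor, covariates, interaction = TRUE)
  fit_main <- moderate_variances(
    fit_mass_linear(cohort, des_int, coef = "factor"))
  fit_int <- moderate_variances(
    fit_mass_linear(cohort, des_int, coef = "factor:age"))
  padj <- stats::p.adjust(fit_int$p_mod, method = "BH")
  sig <- padj < alpha
  agree <- if (any(sig)) {
    mean(sign(fit_int$beta[sig]) == sign(fit_main$beta[sig]))
  } else NA_real_
  list(main = fit_main, interaction = fit_int, sign_agreement = agree,
       n_sig_interaction = sum(sig))
}

#' Associate factors with FPC scores
#'
#' Runs the same mass-regression engine with FPC scores as the outcomes.
#' Because each component already summarises a grid-wide pattern, a more
#' lenient 1% FDR (BH) defines significance.
#'
#' @param scores individuals x components FPC score matrix.
#' @param factor factor values per individual.
#' @param covariates covariate data frame.
#' @param alpha BH threshold (default 0.01).
#' @return List: `fit` (`moderated_fit` over components), `adjusted_p`,
#'   `significant` logical per component.
#' @export
associate_fpcs <- function(scores, factor, covariates, alpha = 0.01) {
  des <- design_spec(factor, covariates)
  raw <- fit_mass_linear(as.matrix(scores), des)
  # moderation needs many parallel outcomes; with a handful of components
  # the ordinary t is reported (d0 = 0)
  fit <- if (ncol(as.matrix(scores)) >= 10) moderate_variances(raw)
         else moderate_variances(raw, d0 = 0)
  padj <- stats::p.adjust(fit$p_mod, method = "BH")
  list(fit = fit, adjusted_p = padj, significant = padj < alpha)
}

#' Correlation between two pixel-wise effect maps
#'
#' @param map_a,map_b numeric vectors of per-pixel betas.
#' @param mode pixel set: "all", "a_significant" (pixels significant for
#'   map a), "both_significant".
#' @param sig_a,sig_b logical significance masks (required by the
#'   restricted modes).
#' @param method "pearson" or "spearman" (rank variant for cross-ancestry
#'   comparison).
#' @return Pearson or Spearman correlation over the selected pixels.
#' @export
compare_effect_maps <- function(map_a, map_b,
                                mode = c("all", "a_significant",
                                         "both_significant"),
                                sig_a = NULL, sig_b = NULL,
                                method = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(length(map_a) == length(map_b))
  sel <- switch(mode,
    all = rep(TRUE, length(map_a)),
    a_significant = { stopifnot(!is.null(sig_a)); sig_a },
    both_significant = {
      stopifnot(!is.null(sig_a), !is.null(sig_b)); sig_a & sig_b
    })
  if (sum(sel) < 3) return(NA_real_)
  stats::cor(map_a[sel], map_b[sel], method = method)
}
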