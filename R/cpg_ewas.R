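#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment over the tested (non-missing) p-values: sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in
#' input order. `NA` p-values stay `NA` and do not count toward `m`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return q-values in input order.
#' @export
adjust_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

# design matrix for methylation models: intercept + age + male covariates
ewas_design <- function(pheno,
                        covariates = c("male_bmi", "male_smoking",
                                       "male_infertile")) {
  stopifnot("male_age" %in% names(pheno))
  miss <- setdiff(covariates, names(pheno))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, male_age = pheno$male_age)
  for (cv in covariates) X <- cbind(X, as.numeric(pheno[[cv]]))
  colnames(X) <- c("(Intercept)", "male_age", covariates)
  X
}

#' Per-CpG linear model of methylation on male age
#'
#' Ordinary least squares of a single probe's M-values on male age plus
#' male covariates; the p-value comes from the t-statistic of the age
#' coefficient with residual degrees of freedom.
#'
#' @param y numeric response (M-values, one per subject).
#' @param age male age in years.
#' @param covariates optional data.frame/matrix of additional covariates.
#' @return list with `effect` (per-year age slope), `se`, `p`, `df`. A
#'   rank-deficient or zero-variance fit returns `NA` values rather than
#'   being dropped.
#' @export
fit_cpg <- function(y, age, covariates = NULL) {
  X <- cbind(1, age)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("too few subjects for the model")
  if (var(y) == 0 || qr(X)$rank < p)
    return(list(effect = NA_real_, se = NA_real_, p = NA_real_, df = n - p))
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- n - p
  xtxinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(xtxinv[2, 2] * rss / df)
  eff <- unname(fit$coefficients[2])
  tval <- eff / se
  list(effect = eff, se = se, p = 2 * pt(-abs(tval), df), df = df)
}

# vectorized OLS over all probes sharing one design; returns effect, se, p
ols_scan <- function(Y, X) {
  # Y: probes x subjects; X: subjects x p
  n <- ncol(Y); p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) stop("design matrix is rank deficient")
  coefs <- qr.coef(qrx, t(Y))                 # p x probes
  res <- t(Y) - X %*% coefs                   # n x probes
  rss <- colSums(res^2)
  df <- n - p
  xtxinv <- chol2inv(qr.R(qrx))
  se <- sqrt(xtxinv[2, 2] * rss / df)
  eff <- coefs[2, ]
  tval <- eff / se
  pv <- 2 * pt(-abs(tval), df)
  zerovar <- rowSums((Y - rowMeans(Y))^2) == 0
  eff[zerovar] <- NA; se[zerovar] <- NA; pv[zerovar] <- NA
  data.frame(effect = eff, se = se, p = pv)
}

#' Epigenome-wide association scan of methylation on male age
#'
#' Fits, for every probe, two OLS models sharing one design matrix:
#' inference (p-values) from the M-value model, effect sizes from a
#' beta-value refit reported as percent methylation change per 5 years of
#' age. Multiplicity is controlled by Benjamini-Hochberg q-values and a
#' Bonferroni flag across all tested probes.
#'
#' @param ds a `MethylomeDataset` (already filtered).
#' @param pheno data.frame with one row per subject in dataset column order;
#'   must contain `male_age` and the model covariates.
#' @param covariates male covariate column names (default BMI, smoking,
#'   infertility; methylation models do not adjust for female age).
#' @param alpha significance level for the Bonferroni flag (default 0.05).
#' @return data.frame, one row per probe: `probe_id`, `chrom`, `pos`,
#'   `effect_M` (M-units/year), `effect_per_5yr_beta` (percent/5 years),
#'   `p`, `q`, `bonf_sig`.
#' @export
run_ewas <- function(ds, pheno,
                     covariates = c("male_bmi", "male_smoking",
                                    "male_infertile"),
                     alpha = 0.05) {
  stopifnot(nrow(pheno) == length(ds$subject_ids))
  X <- ewas_design(pheno, covariates)
  M <- m_values(ds)
  fit_m <- ols_scan(M, X)
  fit_b <- ols_scan(ds$beta, X)
  q <- adjust_bh(fit_m$p)
  m_tested <- sum(!is.na(fit_m$p))
  bonf <- !is.na(fit_m$p) & fit_m$p < alpha / m_tested
  data.frame(probe_id = ds$manifest$probe_id, chrom = ds$manifest$chrom,
             pos = ds$manifest$pos,
             effect_M = fit_m$effect,
             effect_per_5yr_beta = 5 * fit_b$effect * 100,
             p = fit_m$p, q = q, bonf_sig = bonf,
             stringsAsFactors = FALSE)
}

#' Write an EWAS result table to CSV
#' @param ewas result of [run_ewas()].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_ewas_csv <- function(ewas, path) {
  write.csv(ewas, path, row.names = FALSE)
  invisible(path)
}
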