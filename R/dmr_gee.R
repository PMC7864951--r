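#' Identity-link GEE with exchangeable working correlation
#'
#' Marginal linear regression for clustered observations: iterates weighted
#' least squares under the current exchangeable working correlation, then
#' moment re-estimation of the correlation from Pearson residuals, until the
#' maximum coefficient change falls below `tol` (or `max_iter` sweeps).
#' Variance is the cluster-robust sandwich estimator; p-values use the
#' normal approximation. With single-observation clusters the estimate and
#' sandwich SE collapse to OLS with HC0.
#'
#' @param y numeric response (stacked long data).
#' @param X design matrix (rows aligned with `y`), including intercept.
#' @param cluster cluster identifier per row (e.g. subject id).
#' @param tol convergence tolerance on coefficients (default 1e-6).
#' @param max_iter maximum iterations (default 50).
#' @param rho optional fixed working correlation; when supplied (e.g. `0`
#'   for working independence) it is not re-estimated.
#' @param small_sample apply the Mancl-DeRouen-style inflation
#'   `n_clusters / (n_clusters - p)` to the sandwich variance.
#' @return list with `coefficients`, `robust_se`, `p`, `rho`, `converged`,
#'   `n_clusters`, `rho_clipped`.
#' @export
fit_gee_exchangeable <- function(y, X, cluster, tol = 1e-6, max_iter = 50,
                                 rho = NULL, small_sample = FALSE) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(cluster) == length(y))
  cluster <- as.integer(factor(cluster))
  K <- max(cluster)
  p <- ncol(X)
  msize <- tabulate(cluster, K)               # cluster sizes, by cluster id
  fixed_rho <- !is.null(rho)
  rho_cur <- if (fixed_rho) rho else 0
  beta <- qr.coef(qr(X), y)  # OLS start
  if (anyNA(beta)) stop("design matrix is rank deficient")
  max_m <- max(msize)
  rho_lo <- if (max_m > 1) -1 / (max_m - 1) + 1e-6 else -0.99
  clipped <- FALSE
  converged <- FALSE

  # exchangeable R^{-1} = a*I + b*J with size-dependent a, b; all per-cluster
  # quadratic forms reduce to rowsum() aggregates grouped by cluster size
  ab <- function(m, r) {
    if (m == 1) return(c(a = 1, b = 0))
    c(a = 1 / (1 - r),
      b = -r / ((1 - r) * (1 + (m - 1) * r)))
  }
  S <- rowsum(X, cluster)                     # K x p cluster column sums
  sizes <- sort(unique(msize))
  size_of <- msize                            # per-cluster size lookup

  Av_parts <- function(r, e = NULL) {
    # returns list(A, v or B) using current correlation r
    A <- matrix(0, p, p)
    v <- numeric(p)
    B <- matrix(0, p, p)
    sy <- rowsum(y, cluster)
    if (!is.null(e)) {
      Xe <- rowsum(X * e, cluster)            # K x p of Xi' e_i
      se <- rowsum(e, cluster)
    }
    for (m in sizes) {
      kk <- which(size_of == m)
      rows <- cluster %in% kk
      coefs <- ab(m, r)
      Xm <- X[rows, , drop = FALSE]
      A <- A + coefs["a"] * crossprod(Xm) +
        coefs["b"] * crossprod(S[kk, , drop = FALSE])
      if (is.null(e)) {
        v <- v + coefs["a"] * crossprod(Xm, y[rows]) +
          coefs["b"] * crossprod(S[kk, , drop = FALSE], sy[kk])
      } else {
        U <- coefs["a"] * Xe[kk, , drop = FALSE] +
          coefs["b"] * drop(se)[kk] * S[kk, , drop = FALSE]
        B <- B + crossprod(U)
      }
    }
    list(A = A, v = v, B = B)
  }

  for (it in seq_len(max_iter)) {
    parts <- Av_parts(rho_cur)
    beta_new <- drop(solve(parts$A, parts$v))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    e <- y - drop(X %*% beta)
    phi <- sum(e^2) / (length(y) - p)
    if (!fixed_rho) {
      se_cl <- drop(rowsum(e, cluster))
      e2_cl <- drop(rowsum(e^2, cluster))
      num <- sum((se_cl^2 - e2_cl) / 2)
      npairs <- sum(msize * (msize - 1) / 2)
      rho_new <- if (npairs > p) (num / (npairs - p)) / phi
      else if (npairs > 0) (num / npairs) / phi else 0
      if (rho_new <= rho_lo || rho_new >= 0.99) {
        clipped <- TRUE
        rho_new <- min(max(rho_new, rho_lo), 0.99)
      }
      rho_cur <- rho_new
    }
    if (delta < tol) { converged <- TRUE; break }
  }

  # final pass so the reported coefficients solve the estimating equations
  # exactly at the reported working correlation
  parts <- Av_parts(rho_cur)
  beta <- drop(solve(parts$A, parts$v))

  # sandwich variance (scale parameter cancels)
  e <- y - drop(X %*% beta)
  parts <- Av_parts(rho_cur, e = e)
  Ainv <- solve(parts$A)
  V <- Ainv %*% parts$B %*% Ainv
  if (small_sample) V <- V * K / max(K - p, 1)
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  list(coefficients = setNames(beta, colnames(X)),
       robust_se = setNames(se, colnames(X)),
       p = setNames(2 * pnorm(-abs(z)), colnames(X)),
       rho = if (max_m > 1) rho_cur else NA_real_,
       converged = converged, n_clusters = K, rho_clipped = clipped)
}

#' GEE fit for one methylation region
#'
#' Stacks the region's probes into long form (one row per subject x probe)
#' and regresses methylation on male age plus male covariates with subjects
#' as clusters under an exchangeable working correlation.
#'
#' @param values probes x subjects matrix of methylation values for the
#'   region's member probes (M-values or beta-values).
#' @param pheno data.frame with one row per subject (dataset column order).
#' @param covariates male covariate column names.
#' @inheritParams fit_gee_exchangeable
#' @return list as from [fit_gee_exchangeable()], with `effect`, `se`, `p`
#'   for the age coefficient pulled out.
#' @export
fit_region_gee <- function(values, pheno,
                           covariates = c("male_bmi", "male_smoking",
                                          "male_infertile"),
                           rho = NULL, small_sample = FALSE) {
  values <- as.matrix(values)
  m <- nrow(values); n <- ncol(values)
  stopifnot(nrow(pheno) == n)
  X1 <- ewas_design(pheno, covariates)
  y <- as.vector(values)                      # probe-major within subject
  X <- X1[rep(seq_len(n), each = m), , drop = FALSE]
  cluster <- rep(seq_len(n), each = m)
  fit <- fit_gee_exchangeable(y, X, cluster, rho = rho,
                              small_sample = small_sample)
  fit$effect <- unname(fit$coefficients["male_age"])
  fit$se <- unname(fit$robust_se["male_age"])
  fit$p_age <- unname(fit$p["male_age"])
  fit
}

#' Region-level differential methylation scan (GEE)
#'
#' One GEE fit per region: inference (p) from the M-value response and the
#' reported effect from a beta-value refit, expressed as percent methylation
#' change per 5 years of male age. BH q-values and Bonferroni flags are
#' computed across converged regions; regions that fail to converge carry NA
#' p-values and do not count toward the BH denominator.
#'
#' @param regions a `MethylRegionSet` from [find_clusters()].
#' @param ds the `MethylomeDataset` the regions were derived from.
#' @param pheno subject phenotype data.frame (dataset column order).
#' @param covariates male covariate column names.
#' @param alpha Bonferroni significance level (default 0.05).
#' @param small_sample passed to [fit_gee_exchangeable()].
#' @return data.frame: `region_id`, `chrom`, `start`, `end`, `n_probes`,
#'   `effect_per_5yr_beta`, `robust_se`, `p`, `q`, `bonf_sig`, `direction`
#'   ("hyper"/"hypo"), `converged`.
#' @export
run_dmr <- function(regions, ds, pheno,
                    covariates = c("male_bmi", "male_smoking",
                                   "male_infertile"),
                    alpha = 0.05, small_sample = FALSE) {
  M <- m_values(ds)
  idx_of <- setNames(seq_len(nrow(ds$manifest)), ds$manifest$probe_id)
  nr <- nrow(regions)
  eff <- se <- pv <- rep(NA_real_, nr)
  conv <- rep(FALSE, nr)
  for (i in seq_len(nr)) {
    pid <- idx_of[regions$probe_ids[[i]]]
    res <- tryCatch({
      fm <- fit_region_gee(M[pid, , drop = FALSE], pheno, covariates,
                           small_sample = small_sample)
      fb <- fit_region_gee(ds$beta[pid, , drop = FALSE], pheno, covariates,
                           small_sample = small_sample)
      list(p = fm$p_age, eff = fb$effect * 5 * 100,
           se = fb$se * 5 * 100, conv = fm$converged && fb$converged)
    }, error = function(e) NULL)
    if (!is.null(res) && res$conv) {
      pv[i] <- res$p; eff[i] <- res$eff; se[i] <- res$se; conv[i] <- TRUE
    }
  }
  q <- adjust_bh(pv)
  m_tested <- sum(!is.na(pv))
  bonf <- !is.na(pv) & pv < alpha / max(m_tested, 1)
  data.frame(region_id = regions$region_id, chrom = regions$chrom,
             start = regions$start, end = regions$end,
             n_probes = regions$n_probes,
             effect_per_5yr_beta = eff, robust_se = se, p = pv, q = q,
             bonf_sig = bonf,
             direction = ifelse(is.na(eff), NA_character_,
                                ifelse(eff >= 0, "hyper", "hypo")),
             converged = conv, stringsAsFactors = FALSE)
}

#' Write a DMR result table to CSV
#' @param dmr result of [run_dmr()].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_dmr_csv <- function(dmr, path) {
  write.csv(dmr, path, row.names = FALSE)
  invisible(path)
}
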