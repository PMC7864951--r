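#' Weighted logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression with frequency weights, fit by
#' iteratively reweighted least squares with step-halving (so the weighted
#' log-likelihood never decreases across iterations). Convergence is
#' declared when every component of the score vector is below `tol` in
#' absolute value. Used with per-couple success proportions as `y` and
#' oocyte counts as `w`, this reproduces the fit on the oocyte-expanded
#' data exactly.
#'
#' @param y responses in \[0, 1\] (binary or per-couple proportions).
#' @param X design matrix including intercept.
#' @param w positive frequency weights (default 1).
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return list: `coefficients`, `se` (inverse-information), `vcov`,
#'   `loglik_trace`, `converged`, `n_iter`.
#' @export
logistic_irls <- function(y, X, w = rep(1, length(y)), tol = 1e-8,
                          max_iter = 100) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(w) == length(y))
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  if (any(w <= 0)) stop("weights must be positive")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (all(y == 1) || all(y == 0))
    stop("complete separation: outcome is constant at ", y[1])
  p <- ncol(X)
  beta <- numeric(p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(w * (y * eta - log1p(exp(eta))))
  }
  ll_cur <- ll(beta)
  trace <- ll_cur
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, w * (y - mu)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    Winfo <- w * mu * (1 - mu)
    info <- crossprod(X, X * Winfo)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the log-likelihood non-decreasing
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- ll(cand)
      if (ll_new >= ll_cur - 1e-12 || lam < 1e-10) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    ll_cur <- ll_new
    trace <- c(trace, ll_cur)
  }
  eta <- drop(X %*% beta)
  # diverging linear predictors with perfectly predicted outcomes = separation
  # (the score can vanish numerically in that regime, so test unconditionally)
  if (max(abs(eta)) > 25) {
    j <- which.max(abs(beta[-1])) + 1L
    stop("complete separation detected (covariate: ",
         colnames(X)[j] %||% j, ")")
  }
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations")
  mu <- plogis(eta)
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  V <- solve(info)
  se <- sqrt(diag(V))
  list(coefficients = setNames(drop(beta), colnames(X)),
       se = setNames(se, colnames(X)), vcov = V,
       loglik_trace = trace, converged = converged, n_iter = it)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

outcome_design <- function(couples,
                           covariates = c("male_bmi", "male_smoking",
                                          "male_infertile", "female_age")) {
  X <- cbind(`(Intercept)` = 1, male_age = couples$male_age)
  for (cv in covariates) X <- cbind(X, as.numeric(couples[[cv]]))
  colnames(X) <- c("(Intercept)", "male_age", covariates)
  X
}

make_outcome_fit <- function(fit, outcome, weighted, conf = 0.95) {
  zc <- qnorm(1 - (1 - conf) / 2)
  b <- fit$coefficients["male_age"]
  se <- fit$se["male_age"]
  structure(list(outcome = outcome,
                 or = unname(exp(b)),
                 ci = unname(exp(c(b - zc * se, b + zc * se))),
                 p = unname(2 * pnorm(-abs(b / se))),
                 coefficients = fit$coefficients, se = fit$se,
                 weighted = weighted,
                 loglik_trace = fit$loglik_trace,
                 converged = fit$converged),
            class = "OutcomeFit")
}

#' @export
print.OutcomeFit <- function(x, ...) {
  cat(sprintf("%s: OR per year of male age = %.3f (95%% CI %.3f, %.3f)%s\n",
              x$outcome, x$or, x$ci[1], x$ci[2],
              if (x$weighted) " [oocyte-weighted]" else ""))
  invisible(x)
}

#' Oocyte-weighted logistic model of a proportion outcome
#'
#' Models a per-couple success proportion against male age (adjusting for
#' male BMI, smoking, infertility and female age) with the couple's oocyte
#' count as a frequency weight, so each couple contributes one observation
#' per oocyte.
#'
#' @param y per-couple success proportions in \[0, 1\].
#' @param w oocyte counts (positive).
#' @param couples couple data.frame (provides age + covariates).
#' @param covariates adjustment covariate names (outcome models include
#'   female age).
#' @param outcome label for the fit.
#' @return an `OutcomeFit`: odds ratio per 1 year of male age with Wald 95%
#'   CI, full coefficient vector with SEs.
#' @export
fit_weighted_logistic <- function(y, w, couples,
                                  covariates = c("male_bmi", "male_smoking",
                                                 "male_infertile",
                                                 "female_age"),
                                  outcome = "outcome") {
  X <- outcome_design(couples, covariates)
  fit <- logistic_irls(y, X, w)
  make_outcome_fit(fit, outcome, weighted = TRUE)
}

#' Unweighted logistic model of live birth
#'
#' Live birth is a single event per couple, so no oocyte weights are used.
#'
#' @param live_birth 0/1 outcomes.
#' @inheritParams fit_weighted_logistic
#' @return an `OutcomeFit`.
#' @export
fit_livebirth_logistic <- function(live_birth, couples,
                                   covariates = c("male_bmi", "male_smoking",
                                                  "male_infertile",
                                                  "female_age")) {
  X <- outcome_design(couples, covariates)
  fit <- logistic_irls(live_birth, X)
  make_outcome_fit(fit, "live_birth", weighted = FALSE)
}

#' Validate a couple-level phenotype table
#' @param couples data.frame of couple records.
#' @return invisibly, `couples`; errors name the violated constraint.
#' @export
validate_couples <- function(couples) {
  need <- c("couple_id", "male_age", "male_bmi", "male_smoking",
            "male_infertile", "female_age", "n_oocytes", "n_fertilized",
            "n_day3_hq", "n_day5_hq", "n_day5_tq", "live_birth")
  miss <- setdiff(need, names(couples))
  if (length(miss)) stop("missing couple columns: ", paste(miss, collapse = ", "))
  if (any(couples$n_oocytes < 1)) stop("n_oocytes must be >= 1")
  if (any(couples$n_fertilized > couples$n_oocytes))
    stop("n_fertilized exceeds n_oocytes")
  for (cc in c("n_day3_hq", "n_day5_hq", "n_day5_tq"))
    if (any(couples[[cc]] > couples$n_fertilized))
      stop(cc, " exceeds n_fertilized")
  ages <- c(couples$male_age, couples$female_age)
  if (any(ages < 18 | ages > 60)) stop("ages outside plausible bounds [18, 60]")
  invisible(couples)
}

#' Couple-level models of all ART outcomes against male age
#'
#' Fits oocyte-weighted logistic regressions for fertilization and the
#' day-3/day-5 embryo-quality proportions (counts over oocytes retrieved),
#' and an unweighted logistic model for live birth, each adjusted for male
#' BMI, smoking, infertility and female age. Optionally refits within
#' infertility strata (strata under `min_stratum` couples are skipped with a
#' warning).
#'
#' @param couples validated couple table (see [validate_couples()]).
#' @param stratify_infertility also fit per infertility stratum.
#' @param min_stratum minimum couples per stratum (default 10).
#' @return data.frame, one row per outcome (x stratum): `outcome`,
#'   `stratum`, `or`, `ci_lo`, `ci_hi`, `p` (Wald, for the age coefficient),
#'   `n`. An outcome missing for all couples yields an NA row.
#' @export
run_art_outcomes <- function(couples, stratify_infertility = FALSE,
                             min_stratum = 10) {
  validate_couples(couples)
  specs <- list(
    fertilization = function(d) list(y = d$n_fertilized / d$n_oocytes, w = d$n_oocytes),
    day3_hq = function(d) list(y = d$n_day3_hq / d$n_oocytes, w = d$n_oocytes),
    day5_hq = function(d) list(y = d$n_day5_hq / d$n_oocytes, w = d$n_oocytes),
    day5_tq = function(d) list(y = d$n_day5_tq / d$n_oocytes, w = d$n_oocytes),
    live_birth = function(d) list(y = d$live_birth, w = NULL))
  fit_one <- function(d, stratum) {
    rows <- lapply(names(specs), function(nm) {
      yw <- specs[[nm]](d)
      row <- data.frame(outcome = nm, stratum = stratum, or = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        n = nrow(d), stringsAsFactors = FALSE)
      if (all(is.na(yw$y))) return(row)
      fit <- tryCatch({
        if (is.null(yw$w)) fit_livebirth_logistic(yw$y, d)
        else fit_weighted_logistic(yw$y, yw$w, d, outcome = nm)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        row$or <- fit$or; row$ci_lo <- fit$ci[1]; row$ci_hi <- fit$ci[2]
        row$p <- fit$p
      }
      row
    })
    do.call(rbind, rows)
  }
  out <- fit_one(couples, "all")
  if (stratify_infertility) {
    for (s in sort(unique(couples$male_infertile))) {
      d <- couples[couples$male_infertile == s, , drop = FALSE]
      if (nrow(d) < min_stratum) {
        warning("infertility stratum ", s, " has < ", min_stratum,
                " couples; skipped")
        next
      }
      # the stratifying covariate drops out of the stratified design
      d2 <- d; d2$male_infertile <- NULL
      fit_strat <- lapply(names(specs), function(nm) {
        yw <- specs[[nm]](d)
        row <- data.frame(outcome = nm, stratum = paste0("infertile=", s),
                          or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          p = NA_real_, n = nrow(d), stringsAsFactors = FALSE)
        fit <- tryCatch({
          covs <- c("male_bmi", "male_smoking", "female_age")
          if (is.null(yw$w))
            make_outcome_fit(logistic_irls(yw$y, outcome_design(d, covs)),
                             nm, FALSE)
          else
            make_outcome_fit(logistic_irls(yw$y, outcome_design(d, covs),
                                           yw$w), nm, TRUE)
        }, error = function(e) NULL)
        if (!is.null(fit)) {
          row$or <- fit$or; row$ci_lo <- fit$ci[1]; row$ci_hi <- fit$ci[2]
          row$p <- fit$p
        }
        row
      })
      out <- rbind(out, do.call(rbind, fit_strat))
    }
  }
  out
}

#' Read a couple phenotype CSV
#' @param path CSV with the CoupleRecord schema.
#' @return validated data.frame.
#' @export
read_couples <- function(path) {
  validate_couples(read.csv(path, stringsAsFactors = FALSE))
}
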