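test_that("GEE with singleton clusters collapses to OLS with HC0", {
  set.seed(20)
  n <- 40
  X <- cbind(1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- 1 + 0.5 * X[, 2] - 0.2 * X[, 3] + rnorm(n)
  gee <- fit_gee_exchangeable(y, X, cluster = seq_len(n))
  ref <- ols_hc0(y, X)
  expect_equal(unname(gee$coefficients), unname(ref$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(gee$robust_se), unname(ref$se), tolerance = 1e-8)
  expect_true(is.na(gee$rho))
})

test_that("working independence reproduces pooled OLS coefficients", {
  set.seed(21)
  n_cl <- 30; m <- 4
  cl <- rep(seq_len(n_cl), each = m)
  X <- cbind(1, x = rnorm(n_cl * m))
  y <- 2 + 0.3 * X[, 2] + rnorm(n_cl)[cl] + rnorm(n_cl * m)
  gee <- fit_gee_exchangeable(y, X, cl, rho = 0)
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(gee$coefficients), unname(ols), tolerance = 1e-10)
  expect_equal(gee$rho, 0)
})

test_that("the moment estimator recovers the exchangeable correlation", {
  set.seed(22)
  n_cl <- 400; m <- 5; rho <- 0.5
  cl <- rep(seq_len(n_cl), each = m)
  u <- rnorm(n_cl)[cl]
  y <- 1 + sqrt(rho) * u + sqrt(1 - rho) * rnorm(n_cl * m)
  gee <- fit_gee_exchangeable(y, cbind(rep(1, n_cl * m)), cl)
  expect_true(gee$converged)
  expect_equal(gee$rho, rho, tolerance = 0.08)
})

test_that("GEE coefficients solve the estimating equations exactly", {
  set.seed(23)
  n_cl <- 25; m <- 3
  cl <- rep(seq_len(n_cl), each = m)
  X <- cbind(1, age = runif(n_cl, 25, 45)[cl], z = rnorm(n_cl * m))
  y <- 0.5 + 0.02 * X[, 2] + rnorm(n_cl)[cl] + rnorm(n_cl * m)
  gee <- fit_gee_exchangeable(y, X, cl, tol = 1e-12, max_iter = 200)
  # residual score under the working correlation must vanish:
  # sum_i X_i' R^{-1}(rho) e_i = 0
  r <- gee$rho
  a <- 1 / (1 - r); b <- -r / ((1 - r) * (1 + (m - 1) * r))
  e <- y - drop(X %*% gee$coefficients)
  score <- numeric(ncol(X))
  for (i in seq_len(n_cl)) {
    rows <- which(cl == i)
    Rinv <- a * diag(m) + b * matrix(1, m, m)
    score <- score + crossprod(X[rows, , drop = FALSE], Rinv %*% e[rows])
  }
  expect_lt(max(abs(score)), 1e-6)
})

test_that("sandwich intervals attain near-nominal coverage", {
  set.seed(24)
  n_cl <- 60; m <- 3; b_true <- 0.05
  reps <- 250
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    age <- runif(n_cl, 25, 45)
    cl <- rep(seq_len(n_cl), each = m)
    y <- b_true * age[cl] + 0.7 * rnorm(n_cl)[cl] + rnorm(n_cl * m)
    X <- cbind(1, age = age[cl])
    gee <- fit_gee_exchangeable(y, X, cl)
    ci <- gee$coefficients["age"] +
      c(-1, 1) * qnorm(0.975) * gee$robust_se["age"]
    covered[r] <- ci[1] <= b_true && b_true <= ci[2]
  }
  # robust sandwich at 60 clusters is mildly anti-conservative; allow a
  # Monte-Carlo band around the expected ~0.93-0.95
  expect_gte(mean(covered), 0.87)
  expect_lte(mean(covered), 0.99)
})

test_that("region stacking aligns probes, subjects and clusters", {
  ds <- make_dataset(n_probes = 6, n_subj = 20, n_chrom = 1, seed = 25)
  pheno <- make_couples(20, seed = 25)
  vals <- m_values(ds)[1:3, ]
  fit <- fit_region_gee(vals, pheno)
  # manual long-form construction: subject blocks of m probes
  X1 <- spermage:::ewas_design(pheno)
  y <- as.vector(vals)
  X <- X1[rep(seq_len(20), each = 3), ]
  ref <- fit_gee_exchangeable(y, X, rep(seq_len(20), each = 3))
  expect_equal(fit$effect, unname(ref$coefficients["male_age"]),
               tolerance = 1e-12)
  expect_equal(fit$se, unname(ref$robust_se["male_age"]), tolerance = 1e-12)
})

test_that("the DMR scan reports effects per 5 years with directions", {
  set.seed(26)
  n <- 40
  pheno <- make_couples(n, seed = 26)
  age <- pheno$male_age
  # two clusters: one hypermethylating with age, one flat
  mk_probe <- function(slope) plogis(qlogis(0.4) + slope * (age - 33) +
                                       rnorm(n, 0, 0.05))
  beta <- rbind(mk_probe(0.08), mk_probe(0.08), mk_probe(0.08),
                mk_probe(0), mk_probe(0))
  man <- data.frame(probe_id = sprintf("p%d", 1:5), chrom = "chr01",
                    pos = c(100L, 200L, 300L, 5000L, 5100L))
  dimnames(beta) <- list(man$probe_id, pheno$couple_id)
  ds <- methylome_dataset(man, beta)
  regions <- find_clusters(ds, corr_threshold = 0.2)
  dmr <- run_dmr(regions, ds, pheno)
  expect_equal(nrow(dmr), nrow(regions))
  expect_true(all(dmr$converged))
  hot <- which(dmr$start == 100)
  expect_equal(dmr$direction[hot], "hyper")
  expect_lt(dmr$p[hot], 0.001)
  expect_equal(dmr$q, adjust_bh(dmr$p))
  # beta-scale effect reported as percent per 5 years: positive and sane
  expect_gt(dmr$effect_per_5yr_beta[hot], 0)
  expect_lt(abs(dmr$effect_per_5yr_beta[hot]), 100)
})

test_that("rank-deficient GEE designs are rejected", {
  n <- 20
  X <- cbind(1, x = rnorm(n), xdup = 0)
  X[, 3] <- X[, 2]
  expect_error(fit_gee_exchangeable(rnorm(n), X, seq_len(n)),
               "rank deficient")
})
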