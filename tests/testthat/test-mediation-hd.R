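test_that("univariate MCP solutions match grid minimization", {
  cases <- list(c(z = 2, lam = 1, gamma = 3, want = 1.5),
                c(z = 4, lam = 1, gamma = 3, want = 4),      # |z| > gamma*lam
                c(z = 0.8, lam = 1, gamma = 3, want = 0),    # lam >= |z|
                c(z = -2, lam = 1, gamma = 3, want = -1.5),
                c(z = 1.3, lam = 0.5, gamma = 2.5, want = NA))
  for (cs in cases) {
    pr <- univariate_problem(cs["z"])
    fit <- mcp_fit(pr$X, pr$y, lambda = cs[["lam"]], gamma = cs[["gamma"]],
                   tol = 1e-10)
    got <- unname(fit$beta["v"])
    grid <- seq(cs["z"] - 2, cs["z"] + 2, by = 1e-6)
    want <- grid[which.min(mcp_objective(grid, cs["z"], cs[["lam"]],
                                         cs[["gamma"]]))]
    expect_equal(got, want, tolerance = 2e-6)
    if (!is.na(cs["want"])) expect_equal(got, unname(cs["want"]),
                                         tolerance = 1e-6)
  }
})

test_that("MCP keeps forced covariates and selects true support", {
  set.seed(50)
  n <- 200; K <- 30
  X <- matrix(rnorm(n * (K + 2)), n, K + 2)
  colnames(X) <- c(sprintf("c%02d", seq_len(K)), "covA", "covB")
  y <- 1.5 * X[, "c03"] - 1.2 * X[, "c17"] + 0.05 * X[, "covA"] + rnorm(n)
  fit <- mcp_fit(X, y, penalty_factor = c(rep(1, K), 0, 0))
  expect_setequal(fit$support, c("c03", "c17"))
  # forced covariates are never reported as selected support but stay in
  expect_false(any(c("covA", "covB") %in% fit$support))
  expect_true(all(is.finite(fit$beta[c("covA", "covB")])))
  # the selected model minimizes BIC on the path
  expect_equal(fit$lambda, fit$lambda_path[which.min(fit$bic)])
})

test_that("MCP solutions satisfy the coordinate-wise stationary condition", {
  set.seed(51)
  n <- 120; K <- 10
  X <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("v", 1:K)))
  w <- runif(n, 0.5, 3)
  y <- X[, 1] - 0.7 * X[, 4] + rnorm(n)
  fit <- mcp_fit(X, y, weights = w, nlambda = 20, tol = 1e-9,
                 max_iter = 2000)
  # verify on the standardized problem at the selected lambda
  W <- sum(w)
  xbar <- colSums(X * w) / W; sx <- sqrt(colSums(w * sweep(X, 2, xbar)^2) / W)
  Xs <- sweep(sweep(X, 2, xbar), 2, sx, "/")
  ybar <- sum(w * y) / W; yc <- y - ybar
  sel <- which(fit$lambda_path == fit$lambda)
  b <- fit$beta_path[, sel]
  r <- yc - Xs %*% b
  for (j in seq_len(K)) {
    zj <- sum(w * Xs[, j] * r) / W + b[j]
    lam <- fit$lambda
    bj_opt <- if (abs(zj) > 3 * lam) zj
    else sign(zj) * max(abs(zj) - lam, 0) / (1 - 1 / 3)
    expect_equal(unname(b[j]), unname(bj_opt), tolerance = 1e-6)
  }
})

test_that("SIS ranking equals brute-force marginal correlation ranking", {
  set.seed(52)
  n <- 80; K <- 40
  X <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, sprintf("m%02d", 1:K)))
  y <- X[, 5] + 0.5 * X[, 20] + rnorm(n)
  w <- runif(n, 0.5, 2)
  got <- sis_rank(X, y, d = K, weights = w)
  wc <- function(x) {
    ww <- w / sum(w)
    xm <- sum(ww * x); ym <- sum(ww * y)
    sum(ww * (x - xm) * (y - ym)) /
      sqrt(sum(ww * (x - xm)^2) * sum(ww * (y - ym)^2))
  }
  stat <- abs(apply(X, 2, wc))
  want <- colnames(X)[order(-stat, colnames(X))]
  expect_equal(got, want)
  expect_equal(got[1], "m05")
  # d = K is the identity set; zero-variance columns rank last
  X2 <- cbind(X, const = 1)
  expect_equal(sis_rank(X2, y, d = K + 1)[K + 1], "const")
  # a candidate equal to the response ranks first
  X3 <- cbind(X, exact = y)
  expect_equal(sis_rank(X3, y, d = 3)[1], "exact")
})

test_that("stage-1 screening applies BH across candidate fits", {
  set.seed(53)
  sc <- make_mediation_scenario(100, alpha_k = c(0.05, 0.04),
                                beta_k = c(1.5, -1.5), b_direct = -0.01,
                                seed = 53)
  cand <- cbind(sc$mediators, null1 = rnorm(100), null2 = rnorm(100))
  s1 <- stage1_screen(cand, sc$y, sc$couples, sc$w)
  expect_equal(s1$region_id, colnames(cand))
  expect_equal(s1$q, adjust_bh(s1$p))
  expect_true(all(s1$kept == (!is.na(s1$q) & s1$q < 0.05)))
  expect_true(all(s1$kept[1:2]))              # strong planted paths survive
  # per-candidate p matches a direct single-mediator fit
  X <- cbind(spermage:::mediation_design(sc$couples), mediator = cand[, 1])
  f <- logistic_irls(sc$y, X, sc$w)
  z <- f$coefficients["mediator"] / f$se["mediator"]
  expect_equal(s1$p[1], unname(2 * pnorm(-abs(z))), tolerance = 1e-10)
})

test_that("mediation decomposition NIE + NDE = c * theta_total is exact", {
  for (s in 1:5) {
    sc <- make_mediation_scenario(150, alpha_k = c(0.04, -0.03),
                                  beta_k = c(0.9, 0.8), b_direct = -0.02,
                                  seed = s)
    res <- estimate_mediation(sc$mediators, sc$y, sc$couples, sc$w,
                              bootstrap_B = 0)
    expect_equal(res$nie_log + res$nde_log, res$c * res$theta_tot,
                 tolerance = 1e-12)
    expect_equal(res$proportion, res$nie_log / (res$c * res$theta_tot),
                 tolerance = 1e-12)
    expect_equal(res$nie_or, exp(res$nie_log), tolerance = 1e-12)
  }
})

test_that("mediator rescaling leaves NIE and proportion invariant", {
  sc <- make_mediation_scenario(150, alpha_k = c(0.05, 0.03),
                                beta_k = c(1, -1), b_direct = -0.02, seed = 7)
  r1 <- estimate_mediation(sc$mediators, sc$y, sc$couples, sc$w,
                           bootstrap_B = 0)
  r2 <- estimate_mediation(sweep(sc$mediators, 2, c(10, 0.1), "*"),
                           sc$y, sc$couples, sc$w, bootstrap_B = 0)
  expect_equal(r1$nie_log, r2$nie_log, tolerance = 1e-6)
  expect_equal(r1$proportion, r2$proportion, tolerance = 1e-6)
  # alpha and beta change individually but their products are preserved
  expect_equal(unname(r1$alpha_beta), unname(r2$alpha_beta),
               tolerance = 1e-6)
})

test_that("mediator alpha paths equal covariate-adjusted linear fits", {
  sc <- make_mediation_scenario(120, alpha_k = 0.05, beta_k = 1,
                                b_direct = 0, seed = 8)
  res <- estimate_mediation(sc$mediators, sc$y, sc$couples, sc$w,
                            bootstrap_B = 0)
  ref <- lm(sc$mediators[, 1] ~ male_age + female_age + male_bmi +
              male_smoking + male_infertile, data = sc$couples)
  expect_equal(unname(res$alpha[1]), unname(coef(ref)["male_age"]),
               tolerance = 1e-10)
})

test_that("bootstrap intervals are reproducible from the seed", {
  sc <- make_mediation_scenario(80, alpha_k = c(0.05, 0.04),
                                beta_k = c(1, 1), b_direct = -0.02, seed = 9)
  r1 <- estimate_mediation(sc$mediators, sc$y, sc$couples, sc$w,
                           bootstrap_B = 50, seed = 123)
  r2 <- estimate_mediation(sc$mediators, sc$y, sc$couples, sc$w,
                           bootstrap_B = 50, seed = 123)
  r3 <- estimate_mediation(sc$mediators, sc$y, sc$couples, sc$w,
                           bootstrap_B = 50, seed = 124)
  expect_identical(r1$nie_or_ci, r2$nie_or_ci)
  expect_false(identical(r1$nie_or_ci, r3$nie_or_ci))
  expect_true(r1$nie_or_ci[1] <= r1$nie_or_ci[2])
})

test_that("stability selection frequencies behave as advertised", {
  set.seed(54)
  sc <- make_mediation_scenario(80, alpha_k = c(0.06, 0.05),
                                beta_k = c(2, -2), b_direct = -0.01,
                                seed = 10, noise_sd = 1)
  cand <- cbind(sc$mediators,
                matrix(rnorm(80 * 10), 80, 10,
                       dimnames = list(NULL, sprintf("null%02d", 1:10))))
  st <- loo_stability_select(cand, sc$y, sc$couples, sc$w)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_equal(st$selected, st$frequency >= 0.20)
  expect_true(all(c("med01", "med02") %in% st$region_id[st$selected]))
  # result is deterministic (seedless)
  st2 <- loo_stability_select(cand, sc$y, sc$couples, sc$w)
  expect_identical(st, st2)
  # lowering the threshold can only grow the selected set
  lo <- loo_stability_select(cand, sc$y, sc$couples, sc$w,
                             freq_threshold = 0.05)
  expect_true(all(st$region_id[st$selected] %in% lo$region_id[lo$selected]))
})

test_that("region mediators are TSS-restricted mean M-values", {
  ds <- make_dataset(n_probes = 8, n_subj = 10, n_chrom = 1, seed = 55,
                     spacing = 300)
  regions <- find_clusters(ds, corr_threshold = 0.01)
  dmr_set <- data.frame(region_id = regions$region_id)
  gene_map <- data.frame(region_id = regions$region_id,
                         gene_id = c("gA", rep(NA, nrow(regions) - 1)),
                         stringsAsFactors = FALSE)
  med <- summarize_region_mediators(dmr_set, regions, ds, gene_map)
  expect_equal(ncol(med), 1)
  expect_equal(attr(med, "n_excluded"), nrow(regions) - 1)
  expect_equal(unname(attr(med, "gene")), "gA")
  pid <- regions$probe_ids[[1]]
  expect_equal(unname(med[, 1]),
               unname(colMeans(m_values(ds)[pid, , drop = FALSE])),
               tolerance = 1e-12)
})

test_that("gamma must exceed one and empty mediator sets error", {
  pr <- univariate_problem(2)
  expect_error(mcp_fit(pr$X, pr$y, gamma = 1), "gamma")
  expect_error(estimate_mediation(matrix(numeric(0), 10, 0), rep(0.5, 10),
                                  make_couples(10)), "at least one")
})
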