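# Shared builders for small synthetic inputs used across the test files.

# a position-sorted MethylomeDataset with uniform random betas
make_dataset <- function(n_probes = 40, n_subj = 20, n_chrom = 2, seed = 1,
                         spacing = 400, beta = NULL) {
  set.seed(seed)
  chrom <- sort(rep_len(sprintf("chr%02d", seq_len(n_chrom)), n_probes))
  pos <- unlist(lapply(split(seq_along(chrom), chrom), function(ix)
    seq(1000L, by = spacing, length.out = length(ix))), use.names = FALSE)
  man <- data.frame(probe_id = sprintf("cg%05d", seq_len(n_probes)),
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  if (is.null(beta))
    beta <- matrix(runif(n_probes * n_subj, 0.05, 0.95), n_probes, n_subj)
  dimnames(beta) <- list(man$probe_id, sprintf("S%03d", seq_len(n_subj)))
  methylome_dataset(man, beta)
}

# a valid couple table; b_age plants a fertilization log-odds per year
make_couples <- function(n, seed = 1, b_age = 0) {
  set.seed(seed)
  male_age <- runif(n, 24, 48)
  female_age <- pmin(pmax(male_age + rnorm(n, -2, 2), 20), 50)
  n_oo <- pmax(rnbinom(n, size = 4.664, mu = 15.1), 1)
  p <- plogis(0.4 + b_age * (male_age - 33))
  n_fert <- rbinom(n, n_oo, p)
  data.frame(couple_id = sprintf("C%04d", seq_len(n)),
             male_age = male_age,
             male_bmi = pmin(pmax(rnorm(n, 27, 3), 18), 44),
             male_smoking = rbinom(n, 1, 0.2),
             male_infertile = rbinom(n, 1, 0.3),
             female_age = female_age,
             n_oocytes = n_oo, n_fertilized = n_fert,
             n_day3_hq = rbinom(n, n_fert, 0.5),
             n_day5_hq = rbinom(n, n_fert, 0.15),
             n_day5_tq = rbinom(n, n_fert, 0.3),
             live_birth = rbinom(n, 1, 0.35),
             stringsAsFactors = FALSE)
}

# textbook BH step-up, written independently of adjust_bh
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher exact p by full hypergeometric enumeration for the table
# matrix(c(a, b, c, d), 2, byrow = TRUE) with rows = groups, cols = feature
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, N - r1, c1)
  obs <- dhyper(a, r1, N - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# HC0 sandwich standard errors for OLS
ols_hc0 <- function(y, X) {
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  e <- y - drop(X %*% beta)
  V <- XtXi %*% crossprod(X * e) %*% XtXi
  list(coefficients = beta, se = sqrt(diag(V)))
}

# naive A-clustering reimplementation using stats::cor in a plain loop
naive_clusters <- function(man, M, max_gap, thr, linkage, method) {
  res <- list()
  for (ch in unique(man$chrom)) {
    idx <- which(man$chrom == ch)
    if (length(idx) < 2) next
    cur <- idx[1]
    for (k in idx[-1]) {
      prev <- cur[length(cur)]
      join <- (man$pos[k] - man$pos[prev]) <= max_gap
      if (join) {
        cc <- if (linkage == "single")
          suppressWarnings(cor(M[k, ], M[prev, ], method = method))
        else mean(vapply(cur, function(i)
          suppressWarnings(cor(M[k, ], M[i, ], method = method)), 0))
        join <- !is.na(cc) && cc >= thr
      }
      if (join) cur <- c(cur, k)
      else {
        if (length(cur) >= 2) res[[length(res) + 1]] <- man$probe_id[cur]
        cur <- k
      }
    }
    if (length(cur) >= 2) res[[length(res) + 1]] <- man$probe_id[cur]
  }
  res
}

# direct mediator-scenario builder mirroring the generator's outcome model:
# mediators on the natural-logit scale, binomial fertilization out of oocytes
make_mediation_scenario <- function(n, alpha_k, beta_k, b_direct,
                                    noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  K <- length(alpha_k)
  couples <- make_couples(n, seed = seed + 1)
  ac <- couples$male_age - 33
  M <- sapply(seq_len(K), function(k) alpha_k[k] * ac + rnorm(n, 0, noise_sd))
  colnames(M) <- sprintf("med%02d", seq_len(K))
  lp <- 0.4 + b_direct * ac + drop(M %*% beta_k)
  couples$n_fertilized <- rbinom(n, couples$n_oocytes, plogis(lp))
  list(mediators = M, couples = couples,
       y = couples$n_fertilized / couples$n_oocytes,
       w = couples$n_oocytes)
}

# univariate MCP objective for grid/reference minimization
mcp_objective <- function(b, z, lam, gamma) {
  pen <- ifelse(abs(b) <= gamma * lam,
                lam * abs(b) - b^2 / (2 * gamma),
                gamma * lam^2 / 2)
  0.5 * (b - z)^2 + pen
}

# a standardized single-column problem whose OLS estimate is exactly z
univariate_problem <- function(z, n = 50) {
  x <- scale(seq_len(n))[, 1]
  x <- x / sqrt(mean(x^2))                 # weighted norm 1 under unit weights
  list(X = matrix(x, ncol = 1, dimnames = list(NULL, "v")), y = z * x)
}
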