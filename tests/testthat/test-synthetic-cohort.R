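small_cfg <- function(...) {
  simulation_config(n_couples = 40, n_probes = 600, n_chromosomes = 3,
                    n_age_cpgs = 20, n_age_regions = 15, ...)
}

test_that("the generator is deterministic in its seed", {
  a <- simulate_cohort(small_cfg(seed = 7))
  b <- simulate_cohort(small_cfg(seed = 7))
  c <- simulate_cohort(small_cfg(seed = 8))
  expect_identical(a$dataset$beta, b$dataset$beta)
  expect_identical(a$couples, b$couples)
  expect_identical(unclass(a$truth), unclass(b$truth))
  expect_false(identical(a$dataset$beta, c$dataset$beta))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_cohort(small_cfg(seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("simulated cohorts satisfy the schema constraints", {
  sim <- simulate_cohort(small_cfg(seed = 2))
  expect_s3_class(sim$dataset, "MethylomeDataset")
  expect_equal(nrow(sim$dataset$beta), 600)
  expect_equal(ncol(sim$dataset$beta), 40)
  expect_true(all(sim$dataset$beta > 0 & sim$dataset$beta < 1))
  expect_silent(validate_couples(sim$couples))
  expect_true(all(sim$couples$male_age >= 21 & sim$couples$male_age <= 45))
  # stage counts nest: day-3/5 embryos come from fertilized oocytes
  expect_true(all(sim$couples$n_day3_hq <= sim$couples$n_fertilized))
  expect_true(all(sim$couples$live_birth %in% 0:1))
})

test_that("planted mediator regions carry their configured age slope", {
  cfg <- simulation_config(n_couples = 400, n_probes = 1500,
                           n_chromosomes = 3, n_age_cpgs = 30,
                           n_age_regions = 20, seed = 5)
  sim <- simulate_cohort(cfg)
  L <- qlogis(sim$dataset$beta)          # exact inverse of the generator map
  reg <- sim$truth$probe_region[sim$dataset$manifest$probe_id]
  for (k in seq_along(sim$truth$mediator_region_ids)) {
    rid <- sim$truth$mediator_region_ids[k]
    lbar <- colMeans(L[reg == rid, , drop = FALSE])
    slope <- coef(lm(lbar ~ sim$couples$male_age))[2]
    expect_lt(abs(unname(slope) - cfg$alpha_k[k]), 0.01)
  }
})

test_that("planted per-CpG drifts have the configured direction", {
  sim <- simulate_cohort(small_cfg(seed = 4))
  eff <- sim$truth$planted_cpg_effect_per_5yr
  expect_equal(length(eff), 20)
  expect_true(all(abs(eff) >= 0.2 & abs(eff) <= 11.7))
  L <- qlogis(sim$dataset$beta)
  # empirical logit slope sign matches the planted sign for large drifts
  big <- which(abs(eff) > 4)
  for (i in big) {
    pid <- sim$truth$planted_cpg_ids[i]
    slope <- coef(lm(L[pid, ] ~ sim$couples$male_age))[2]
    expect_equal(unname(sign(slope)), sign(eff[i]))
  }
})

test_that("true estimands follow from the planted paths", {
  cfg <- small_cfg(seed = 1)
  sim <- simulate_cohort(cfg)
  est <- true_estimands(sim$truth)
  expect_equal(est$true_NIE_OR, exp(sum(cfg$alpha_k * cfg$beta_k)))
  expect_equal(est$true_proportion, cfg$mediation_proportion_target,
               tolerance = 1e-12)
  # a zero total effect leaves the proportion undefined
  cfg0 <- small_cfg(seed = 1, b_age_total = 0)
  tr0 <- simulate_cohort(cfg0)$truth
  expect_warning(est0 <- true_estimands(tr0), "total effect is zero")
  expect_true(is.na(est0$true_proportion))
})

test_that("the default configuration encodes the study conditions", {
  cfg <- simulation_config()
  expect_equal(cfg$b_age_total, log(0.92))
  expect_equal(cfg$mediation_proportion_target, 0.64)
  expect_equal(cfg$b_age_livebirth, log(0.80))
  expect_equal(sum(cfg$alpha_k * cfg$beta_k), 0.64 * log(0.92))
  expect_equal(cfg$b_age_direct, 0.36 * log(0.92))
  expect_equal(cfg$n_couples, 100)
  expect_equal(cfg$n_probes, 20000)
})

test_that("configuration validation rejects inconsistent parameters", {
  expect_error(simulation_config(frac_hyper = 1.2), "proportions")
  expect_error(simulation_config(n_true_mediators = 3,
                                 alpha_k = c(0.1, 0.2), beta_k = c(1, 2, 3)),
               "length")
  expect_error(simulation_config(n_true_mediators = 5, n_age_regions = 4),
               "must not exceed")
  expect_error(simulation_config(effect_per_5yr_range = c(-1, 5)),
               "positive")
  expect_error(
    simulate_cohort(simulation_config(
      n_probes = 100, n_chromosomes = 1, n_age_regions = 50,
      n_age_cpgs = 0, n_true_mediators = 0)),
    "not enough multi-probe regions")
})

test_that("layout respects region sizes, gaps and position order", {
  cfg <- small_cfg(seed = 1)
  lay <- spermage:::build_layout(cfg)
  expect_equal(nrow(lay), cfg$n_probes)
  for (ch in unique(lay$chrom))
    expect_false(is.unsorted(lay$pos[lay$chrom == ch], strictly = TRUE))
  # intra-region spacing equals the configured gap
  sizes <- table(lay$region)
  expect_true(all(sizes %in% c(1L, 2L, 3L, 4L, 5L)))
  bad <- simulation_config(region_layout = list(c(3L, 0L, 100L)))
  expect_error(spermage:::build_layout(bad), "intra-region gap")
})

test_that("stage seeds are deterministic, distinct and within integer range", {
  s <- vapply(1:50, function(k) spermage:::stage_seed(123, k), integer(1))
  expect_equal(s, vapply(1:50, function(k) spermage:::stage_seed(123, k),
                         integer(1)))
  expect_equal(length(unique(s)), 50)
  expect_true(all(s >= 0 & s < 2^31))
})

test_that("cohorts round-trip through the on-disk representation", {
  sim <- simulate_cohort(small_cfg(seed = 6))
  dir <- tempfile("cohort_")
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  ds2 <- methylome_dataset(read_manifest(paths["manifest"]),
                           read_beta_matrix(paths["beta"]))
  expect_equal(ds2$beta, sim$dataset$beta, tolerance = 1e-10)
  cp2 <- read_couples(paths["phenotypes"])
  expect_equal(cp2$n_fertilized, sim$couples$n_fertilized)
  truth2 <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth2$nie_log, sim$truth$nie_log, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
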