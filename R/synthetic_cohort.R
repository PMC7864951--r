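#' Simulation configuration for a synthetic ART methylation cohort
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults emulate the
#' study population the pipeline is designed for: 21-45 year old male
#' partners of couples in IVF treatment, sperm 450K-style beta values with a
#' bimodal baseline, a predominantly hypermethylating per-CpG age signal
#' (91% hyper, per-5-year drift 0.2-11.7%), a mixed region-level signal
#' (57% hyper), negative-binomial oocyte yields (mean 15.1, SD 8.0), a
#' fertilization odds ratio of 0.92 per year of male age of which 64% is
#' transmitted through mediator regions, and a live-birth odds ratio of 0.80.
#'
#' Age effects are planted on the natural-logit methylation scale and sized
#' so that the configured percent-methylation drift per 5 years holds at the
#' cohort-mean baseline of each probe. Within a region, probes share a
#' subject-level latent factor giving correlation `within_region_rho`.
#'
#' @param n_couples number of couples.
#' @param n_probes total probes laid out across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param region_layout list of integer triplets `c(size, gap, inter_gap)`:
#'   probes per region, spacing between adjacent probes (bp), and gap to the
#'   next region (bp). Cycled until `n_probes` are placed.
#' @param age_range male age range (years), sampled uniformly.
#' @param n_age_cpgs number of individually planted age-associated CpGs
#'   (placed on singleton regions).
#' @param effect_per_5yr_range percent-methylation drift per 5 years for
#'   planted CpGs, `c(low, high)`.
#' @param frac_hyper fraction of planted CpGs drifting upward.
#' @param n_age_regions number of planted age-associated multi-probe regions
#'   (includes the mediator regions).
#' @param region_effect_per_5yr_range drift range for planted regions.
#' @param frac_hyper_regions fraction of planted regions drifting upward.
#' @param n_true_mediators number of mediator regions (subset of planted
#'   regions) carrying an indirect age-to-fertilization path.
#' @param alpha_k age-to-methylation slopes of the mediators (natural-logit
#'   units per year); length `n_true_mediators`.
#' @param beta_k methylation-to-outcome slopes (log-odds per natural-logit
#'   unit); default chosen so the true mediation proportion is
#'   `mediation_proportion_target`.
#' @param b_age_total total fertilization log-odds per year of male age
#'   (default `log(0.92)`).
#' @param mediation_proportion_target fraction of `b_age_total` routed
#'   through the mediators (default 0.64); the remainder is the direct path.
#' @param b_age_direct direct fertilization log-odds per year; default
#'   `(1 - mediation_proportion_target) * b_age_total`.
#' @param b_age_other named log-odds per year for day-3/day-5 embryo-quality
#'   outcomes.
#' @param b_age_livebirth live-birth log-odds per year (default `log(0.80)`).
#' @param outcome_intercepts named logits of baseline outcome rates.
#' @param b_covariates named outcome effects of female age (per year, both
#'   centered), BMI (per kg/m^2), smoking and male infertility.
#' @param oocyte_mean,oocyte_dispersion negative-binomial mean and size for
#'   oocyte counts (truncated at >= 1).
#' @param smoking_prev,infertility_prev covariate prevalences.
#' @param bmi_mean,bmi_sd male BMI distribution.
#' @param female_age_sd SD of (female age - male age) coupling noise.
#' @param noise_sd subject-level methylation noise SD (natural-logit units).
#' @param within_region_rho within-region correlation of probe noise.
#' @param baseline_mix named list: `weight_low`, `low`, `high`,
#'   `region_sd`, `probe_sd` for the bimodal baseline (natural-logit units).
#' @param seed integer seed fixing every draw.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(
    n_couples = 100,
    n_probes = 20000,
    n_chromosomes = 10,
    region_layout = list(c(1L, 0L, 2000L), c(3L, 150L, 2500L),
                         c(2L, 400L, 2500L), c(5L, 120L, 2500L),
                         c(4L, 200L, 2500L)),
    age_range = c(21, 45),
    n_age_cpgs = 150,
    effect_per_5yr_range = c(0.2, 11.7),
    frac_hyper = 0.91,
    n_age_regions = 60,
    region_effect_per_5yr_range = c(1, 8),
    frac_hyper_regions = 0.57,
    n_true_mediators = 4,
    alpha_k = NULL,
    beta_k = NULL,
    b_age_total = log(0.92),
    mediation_proportion_target = 0.64,
    b_age_direct = NULL,
    b_age_other = c(day3_hq = log(0.94), day5_hq = log(0.85),
                    day5_tq = log(0.93)),
    b_age_livebirth = log(0.80),
    outcome_intercepts = c(fertilization = qlogis(0.60), day3_hq = qlogis(0.57),
                           day5_hq = qlogis(0.10), day5_tq = qlogis(0.30),
                           live_birth = qlogis(0.32)),
    b_covariates = c(female_age = -0.02, bmi = 0, smoking = -0.10,
                     infertile = -0.20),
    oocyte_mean = 15.1,
    oocyte_dispersion = 4.664,
    smoking_prev = 0.085,
    infertility_prev = 0.234,
    bmi_mean = 28, bmi_sd = 4.5,
    female_age_sd = 3,
    noise_sd = 0.15,
    within_region_rho = 0.6,
    baseline_mix = list(weight_low = 0.45, low = qlogis(0.05),
                        high = qlogis(0.95), region_sd = 0.3,
                        probe_sd = 0.15),
    seed = 1L) {

  if (is.null(b_age_direct))
    b_age_direct <- (1 - mediation_proportion_target) * b_age_total
  nie_target <- mediation_proportion_target * b_age_total
  if (n_true_mediators > 0) {
    if (is.null(alpha_k)) {
      mags <- seq(0.030, 0.040, length.out = n_true_mediators)
      sgn <- rep(1, n_true_mediators)
      if (n_true_mediators >= 3) sgn[3] <- -1
      alpha_k <- mags * sgn
    }
    if (is.null(beta_k)) beta_k <- (nie_target / n_true_mediators) / alpha_k
  } else {
    alpha_k <- numeric(0); beta_k <- numeric(0)
  }
  cfg <- list(
    n_couples = as.integer(n_couples), n_probes = as.integer(n_probes),
    n_chromosomes = as.integer(n_chromosomes), region_layout = region_layout,
    age_range = age_range, n_age_cpgs = as.integer(n_age_cpgs),
    effect_per_5yr_range = effect_per_5yr_range, frac_hyper = frac_hyper,
    n_age_regions = as.integer(n_age_regions),
    region_effect_per_5yr_range = region_effect_per_5yr_range,
    frac_hyper_regions = frac_hyper_regions,
    n_true_mediators = as.integer(n_true_mediators),
    alpha_k = alpha_k, beta_k = beta_k,
    b_age_total = b_age_total,
    mediation_proportion_target = mediation_proportion_target,
    b_age_direct = b_age_direct, b_age_other = b_age_other,
    b_age_livebirth = b_age_livebirth,
    outcome_intercepts = outcome_intercepts, b_covariates = b_covariates,
    oocyte_mean = oocyte_mean, oocyte_dispersion = oocyte_dispersion,
    smoking_prev = smoking_prev, infertility_prev = infertility_prev,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, female_age_sd = female_age_sd,
    noise_sd = noise_sd, within_region_rho = within_region_rho,
    baseline_mix = baseline_mix, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  props <- c(cfg$frac_hyper, cfg$frac_hyper_regions, cfg$smoking_prev,
             cfg$infertility_prev, cfg$within_region_rho,
             cfg$baseline_mix$weight_low)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (any(cfg$effect_per_5yr_range <= 0) ||
      any(cfg$region_effect_per_5yr_range <= 0))
    stop("effect ranges must be positive")
  sizes <- vapply(cfg$region_layout, `[`, numeric(1), 1)
  if (any(sizes < 1)) stop("region sizes must be >= 1")
  if (length(cfg$alpha_k) != cfg$n_true_mediators ||
      length(cfg$beta_k) != cfg$n_true_mediators)
    stop("alpha_k/beta_k length must equal n_true_mediators")
  if (cfg$n_true_mediators > cfg$n_age_regions)
    stop("n_true_mediators must not exceed n_age_regions")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

#' Read a simulation config from a YAML key-value file
#'
#' Keys mirror the arguments of [simulation_config()]; unspecified keys keep
#' their defaults.
#' @param path YAML file.
#' @return a `SimulationConfig`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}

# deterministic per-stage substream seed
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483647L)
}

# probe layout: cycle region_layout entries across chromosomes
build_layout <- function(cfg) {
  per_chrom <- ceiling(cfg$n_probes / cfg$n_chromosomes)
  rows <- vector("list", cfg$n_chromosomes)
  region_counter <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    n_left <- min(per_chrom, cfg$n_probes - (ch - 1L) * per_chrom)
    if (n_left <= 0) break
    pos <- 1000L
    li <- 1L
    chrom_pos <- integer(0); chrom_reg <- integer(0)
    while (n_left > 0) {
      lay <- cfg$region_layout[[(li - 1L) %% length(cfg$region_layout) + 1L]]
      size <- min(as.integer(lay[1]), n_left)
      gap <- as.integer(lay[2]); inter <- as.integer(lay[3])
      region_counter <- region_counter + 1L
      if (size > 1 && gap < 1) stop("intra-region gap must be >= 1 bp")
      p <- pos + cumsum(c(0L, rep(gap, size - 1L)))
      chrom_pos <- c(chrom_pos, p)
      chrom_reg <- c(chrom_reg, rep(region_counter, size))
      pos <- p[length(p)] + inter
      if (pos > 2.5e8) stop("infeasible layout: probes exceed chromosome capacity")
      n_left <- n_left - size
      li <- li + 1L
    }
    rows[[ch]] <- data.frame(chrom = sprintf("chr%d", ch), pos = chrom_pos,
                             region = chrom_reg)
  }
  lay <- do.call(rbind, rows)
  lay$probe_id <- sprintf("cg%07d", seq_len(nrow(lay)))
  lay
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates a `MethylomeDataset`, a couple-level phenotype table and a
#' `SyntheticTruth` record. Methylation is generated on the natural-logit
#' scale as probe baseline + planted age slope + correlated noise, then
#' mapped through the logistic function so betas are strictly inside (0, 1).
#' Fertilized counts are binomial out of oocytes with a logistic success
#' probability whose linear predictor carries the direct age path and the
#' mediator paths; live birth is Bernoulli with its own age effect.
#'
#' @param config a `SimulationConfig`.
#' @return list with elements `dataset` (`MethylomeDataset`), `couples`
#'   (data.frame, one row per couple), `truth` (`SyntheticTruth`).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  # --- layout ---------------------------------------------------------------
  lay <- build_layout(config)
  n_probes <- nrow(lay)
  n <- config$n_couples
  reg_sizes <- table(lay$region)
  multi_regions <- as.integer(names(reg_sizes)[reg_sizes >= 2])
  single_probes <- which(lay$region %in% as.integer(names(reg_sizes)[reg_sizes == 1]))

  # --- phenotypes -----------------------------------------------------------
  set.seed(stage_seed(config$seed, 1L))
  age_center <- mean(config$age_range)
  male_age <- runif(n, config$age_range[1], config$age_range[2])
  female_age <- pmin(pmax(male_age + rnorm(n, 0, config$female_age_sd), 18), 50)
  bmi <- pmin(pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 17), 45)
  smoking <- rbinom(n, 1, config$smoking_prev)
  infertile <- rbinom(n, 1, config$infertility_prev)
  n_oocytes <- rnbinom(n, size = config$oocyte_dispersion, mu = config$oocyte_mean)
  while (any(n_oocytes < 1))      # truncate at >= 1
    n_oocytes[n_oocytes < 1] <- rnbinom(sum(n_oocytes < 1),
                                        size = config$oocyte_dispersion,
                                        mu = config$oocyte_mean)
  ac <- male_age - age_center

  # --- plant effects --------------------------------------------------------
  set.seed(stage_seed(config$seed, 2L))
  if (config$n_age_regions > length(multi_regions))
    stop("not enough multi-probe regions to plant")
  planted_regions <- sort(sample(multi_regions, config$n_age_regions))
  mediator_regions <- if (config$n_true_mediators > 0)
    sort(sample(planted_regions, config$n_true_mediators)) else integer(0)
  if (config$n_age_cpgs > length(single_probes))
    stop("not enough singleton probes to plant individual CpGs")
  planted_cpg_idx <- sort(sample(single_probes, config$n_age_cpgs))

  base <- numeric(n_probes)
  regs <- sort(unique(lay$region))
  comp_low <- rbinom(length(regs), 1, config$baseline_mix$weight_low) == 1
  base_reg <- ifelse(comp_low, config$baseline_mix$low, config$baseline_mix$high) +
    rnorm(length(regs), 0, config$baseline_mix$region_sd)
  names(base_reg) <- regs
  # planted loci get mid-range baselines where drift is identifiable
  mid <- function(k) runif(k, qlogis(0.25), qlogis(0.75))
  base_reg[as.character(planted_regions)] <- mid(length(planted_regions))
  base <- base_reg[as.character(lay$region)] +
    rnorm(n_probes, 0, config$baseline_mix$probe_sd)
  base[planted_cpg_idx] <- mid(length(planted_cpg_idx))

  slope <- numeric(n_probes)                       # natural-logit per year
  # individually planted CpGs
  pct_cpg <- runif(config$n_age_cpgs, config$effect_per_5yr_range[1],
                   config$effect_per_5yr_range[2])
  sgn_cpg <- ifelse(runif(config$n_age_cpgs) < config$frac_hyper, 1, -1)
  b0 <- plogis(base[planted_cpg_idx])
  slope[planted_cpg_idx] <- sgn_cpg * (pct_cpg / 100 / 5) / (b0 * (1 - b0))
  # planted regions (non-mediator): uniform drift, mixed direction
  nonmed <- setdiff(planted_regions, mediator_regions)
  pct_reg <- runif(length(nonmed), config$region_effect_per_5yr_range[1],
                   config$region_effect_per_5yr_range[2])
  sgn_reg <- ifelse(runif(length(nonmed)) < config$frac_hyper_regions, 1, -1)
  for (i in seq_along(nonmed)) {
    idx <- which(lay$region == nonmed[i])
    bp <- plogis(base[idx])
    slope[idx] <- sgn_reg[i] * (pct_reg[i] / 100 / 5) / (bp * (1 - bp))
  }
  # mediator regions: slope = alpha_k exactly (natural-logit per year)
  for (k in seq_along(mediator_regions)) {
    slope[lay$region == mediator_regions[k]] <- config$alpha_k[k]
  }

  # --- methylation matrix ---------------------------------------------------
  set.seed(stage_seed(config$seed, 3L))
  rho <- config$within_region_rho
  u <- matrix(rnorm(length(regs) * n), length(regs), n,
              dimnames = list(regs, NULL))
  e <- matrix(rnorm(n_probes * n), n_probes, n)
  noise <- config$noise_sd *
    (sqrt(rho) * u[as.character(lay$region), , drop = FALSE] +
       sqrt(1 - rho) * e)
  L <- base + outer(slope, ac) + noise        # probes x subjects, natural logit
  beta <- plogis(L)
  subject_ids <- sprintf("S%03d", seq_len(n))
  colnames(beta) <- subject_ids
  rownames(beta) <- lay$probe_id
  manifest <- data.frame(probe_id = lay$probe_id, chrom = lay$chrom,
                         pos = lay$pos, region = lay$region,
                         stringsAsFactors = FALSE)
  ds <- methylome_dataset(manifest[c("probe_id", "chrom", "pos")], beta,
                          subject_ids)

  # --- outcomes -------------------------------------------------------------
  set.seed(stage_seed(config$seed, 4L))
  cov_lp <- config$b_covariates["female_age"] * (female_age - age_center) +
    config$b_covariates["bmi"] * (bmi - config$bmi_mean) +
    config$b_covariates["smoking"] * smoking +
    config$b_covariates["infertile"] * infertile
  med_lp <- rep(0, n)
  if (length(mediator_regions)) {
    for (k in seq_along(mediator_regions)) {
      idx <- which(lay$region == mediator_regions[k])
      lbar <- colMeans(L[idx, , drop = FALSE])
      med_lp <- med_lp + config$beta_k[k] * (lbar - mean(base[idx]))
    }
  }
  oi <- config$outcome_intercepts
  p_fert <- plogis(oi["fertilization"] + config$b_age_direct * ac +
                     med_lp + cov_lp)
  n_fert <- rbinom(n, n_oocytes, p_fert)
  draw_stage <- function(nm) {
    p <- plogis(oi[nm] + config$b_age_other[nm] * ac + cov_lp)
    rbinom(n, n_fert, p)
  }
  n_day3 <- draw_stage("day3_hq")
  n_day5hq <- draw_stage("day5_hq")
  n_day5tq <- draw_stage("day5_tq")
  live <- rbinom(n, 1, plogis(oi["live_birth"] + config$b_age_livebirth * ac +
                                cov_lp))
  couples <- data.frame(
    couple_id = subject_ids, male_age = male_age, male_bmi = bmi,
    male_smoking = smoking, male_infertile = infertile,
    female_age = female_age, n_oocytes = n_oocytes, n_fertilized = n_fert,
    n_day3_hq = n_day3, n_day5_hq = n_day5hq, n_day5_tq = n_day5tq,
    live_birth = live, stringsAsFactors = FALSE)

  nie_log <- sum(config$alpha_k * config$beta_k)
  te_log <- nie_log + config$b_age_direct
  truth <- structure(list(
    planted_cpg_ids = lay$probe_id[planted_cpg_idx],
    planted_cpg_effect_per_5yr = sgn_cpg * pct_cpg,
    planted_region_ids = planted_regions,
    planted_region_effect_per_5yr = {
      eff <- setNames(rep(NA_real_, length(planted_regions)),
                      planted_regions)
      eff[as.character(nonmed)] <- sgn_reg * pct_reg
      for (k in seq_along(mediator_regions)) {
        idx <- which(lay$region == mediator_regions[k])
        bp <- plogis(mean(base[idx]))
        eff[as.character(mediator_regions[k])] <-
          config$alpha_k[k] * 5 * bp * (1 - bp) * 100
      }
      eff
    },
    mediator_region_ids = mediator_regions,
    alpha_k = config$alpha_k, beta_k = config$beta_k,
    b_age_direct = config$b_age_direct,
    nie_log = nie_log, te_log = te_log,
    proportion = if (abs(te_log) > 1e-12) nie_log / te_log else NA_real_,
    probe_region = setNames(lay$region, lay$probe_id),
    age_center = age_center), class = "SyntheticTruth")

  list(dataset = ds, couples = couples, truth = truth)
}

#' True mediation estimands implied by planted parameters
#'
#' The true natural indirect effect per year of age is
#' `sum(alpha_k * beta_k)` on the log-odds scale, and the true mediation
#' proportion is `NIE / (NIE + direct)`.
#'
#' @param truth a `SyntheticTruth`.
#' @param age_variance reserved; the point estimands do not depend on the
#'   age distribution.
#' @return list with `true_NIE_OR` and `true_proportion` (NA with a warning
#'   when the total effect is zero).
#' @export
true_estimands <- function(truth, age_variance = NULL) {
  nie <- sum(truth$alpha_k * truth$beta_k)
  denom <- nie + truth$b_age_direct
  prop <- if (abs(denom) < 1e-12) {
    warning("total effect is zero: mediation proportion undefined")
    NA_real_
  } else nie / denom
  list(true_NIE_OR = exp(nie), true_proportion = prop)
}

#' Write a simulated cohort to disk
#'
#' Writes the probe manifest (TSV), beta matrix (TSV), phenotype table (CSV)
#' and ground truth (JSON) into a directory.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             beta = file.path(dir, "beta.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.json"))
  write_methylome(cohort$dataset, paths["manifest"], paths["beta"])
  write.csv(cohort$couples, paths["phenotypes"], row.names = FALSE)
  tr <- unclass(cohort$truth)
  tr$probe_region <- NULL
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
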