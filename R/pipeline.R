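#' Pipeline configuration
#'
#' Either a simulation block (a `SimulationConfig`) or paths to real inputs
#' (manifest, beta matrix, phenotypes, optional tracks/TSS/exclusion lists)
#' must be supplied.
#'
#' @param simulation a `SimulationConfig`, or NULL when real inputs are
#'   given.
#' @param paths named list of input file paths (`manifest`, `beta`,
#'   `phenotypes`, optional `tss`, `tracks` (named BED paths),
#'   `exclusion_lists` (named text files)).
#' @param q_threshold FDR threshold (default 0.05).
#' @param max_gap A-clustering gap (bp, default 1000).
#' @param corr_threshold A-clustering correlation threshold (default 0.5).
#' @param tss_window gene-assignment window (bp, default 1500).
#' @param freq_threshold LOO stability threshold (default 0.20).
#' @param k_subject_groups groups for subject clustering (default 4).
#' @param bootstrap_B mediation bootstrap replicates (default 200).
#' @param run_mediation run the mediation stages (default TRUE).
#' @param seed pipeline seed.
#' @param outdir output directory.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            paths = NULL,
                            q_threshold = 0.05, max_gap = 1000,
                            corr_threshold = 0.5, tss_window = 1500,
                            freq_threshold = 0.20, k_subject_groups = 4,
                            bootstrap_B = 200, run_mediation = TRUE,
                            seed = 1L, outdir = tempfile("spermage_run_")) {
  if (is.null(simulation) && is.null(paths))
    stop("either a simulation block or input paths must be provided")
  stopifnot(q_threshold > 0, q_threshold < 1, max_gap > 0,
            corr_threshold > 0, corr_threshold < 1, tss_window >= 0,
            freq_threshold >= 0, freq_threshold <= 1)
  structure(list(simulation = simulation, paths = paths,
                 q_threshold = q_threshold, max_gap = max_gap,
                 corr_threshold = corr_threshold, tss_window = tss_window,
                 freq_threshold = freq_threshold,
                 k_subject_groups = k_subject_groups,
                 bootstrap_B = bootstrap_B, run_mediation = run_mediation,
                 seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

#' Hierarchical clustering of subjects on significant CpGs
#'
#' Agglomerative clustering (Euclidean distance on beta values, Ward
#' linkage) of subjects over the significant CpG set, cut into `k` groups,
#' with per-group mean age and outcome rates.
#'
#' @param sig_betas CpGs x subjects beta matrix (significant CpGs only).
#' @param couples couple table aligned with the columns.
#' @param k number of groups (default 4).
#' @return list: `groups` (named integer vector per subject), `summary`
#'   (data.frame of group size, mean age, live-birth and fertilization
#'   rates).
#' @export
cluster_subjects <- function(sig_betas, couples, k = 4) {
  if (nrow(sig_betas) < 2) stop("need at least 2 significant CpGs")
  if (ncol(sig_betas) < k) stop("need at least k subjects")
  hc <- hclust(dist(t(sig_betas)), method = "ward.D2")
  groups <- cutree(hc, k = k)
  summ <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sel <- groups == g
    data.frame(group = g, n = sum(sel),
               mean_age = mean(couples$male_age[sel]),
               live_birth_rate = mean(couples$live_birth[sel]),
               fertilization_rate = mean(couples$n_fertilized[sel] /
                                           couples$n_oocytes[sel]))
  }))
  list(groups = groups, summary = summ)
}

log_stage <- function(report, stage, t0, ...) {
  counts <- list(...)
  report$stages[[stage]] <- c(list(wall_seconds =
                                     round(as.numeric(Sys.time()) - t0, 2)),
                              counts)
  message(sprintf("[%s] %s", stage,
                  paste(names(counts), unlist(counts), sep = "=",
                        collapse = " ")))
  report
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, QC, probe filtering, the per-CpG EWAS, adjacent
#' -site clustering, GEE region tests, annotation and enrichment (when
#' tracks are available), ART outcome models, subject clustering, and the
#' mediation analyses for fertilization and live birth. All outputs are
#' written under `config$outdir`; a `RunReport` records per-stage counts,
#' timings and the output inventory. Any stage failure halts with a
#' stage-tagged error.
#'
#' @param config a `PipelineConfig`.
#' @return list of class `RunReport`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config[setdiff(names(config),
                                             c("simulation", "paths"))],
                 seed = config$seed, stages = list(), warnings = character(0),
                 files = character(0))
  out_file <- function(name) {
    path <- file.path(config$outdir, name)
    report$files <<- c(report$files, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate or load ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  truth <- NULL
  tracks <- NULL
  tss <- NULL
  exclusion_lists <- list()
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config$seed, 10L)
    cohort <- run_stage("simulate", simulate_cohort(sim_cfg))
    ds <- cohort$dataset; couples <- cohort$couples; truth <- cohort$truth
    write_cohort(cohort, file.path(config$outdir, "cohort"))
    # synthetic annotation: TSS near mediator/planted regions + CpG context
    synth <- synthetic_annotation(ds, truth, seed = stage_seed(config$seed, 11L))
    tracks <- synth$tracks; tss <- synth$tss
  } else {
    ds <- run_stage("load", {
      man <- read_manifest(config$paths$manifest)
      beta <- read_beta_matrix(config$paths$beta)
      methylome_dataset(man, beta)
    })
    couples <- run_stage("load", read_couples(config$paths$phenotypes))
    if (!is.null(config$paths$tss)) tss <- read_tss_table(config$paths$tss)
    if (!is.null(config$paths$tracks))
      tracks <- lapply(config$paths$tracks, read_bed_track)
    if (!is.null(config$paths$exclusion_lists))
      exclusion_lists <- lapply(config$paths$exclusion_lists,
                                read_exclusion_list)
  }
  report <- log_stage(report, "input", t0, probes = nrow(ds$beta),
                      couples = nrow(couples))

  # --- filtering -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  n_before <- nrow(ds$beta)
  if (length(exclusion_lists)) {
    ds <- run_stage("filter", apply_probe_filters(ds, exclusion_lists))
  }
  report <- log_stage(report, "filter", t0, probes_in = n_before,
                      probes_out = nrow(ds$beta),
                      excluded = n_before - nrow(ds$beta))

  # --- EWAS ------------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ewas <- run_stage("ewas", run_ewas(ds, couples))
  write_ewas_csv(ewas, out_file("ewas.csv"))
  sig_cpg <- !is.na(ewas$q) & ewas$q < config$q_threshold
  report <- log_stage(report, "ewas", t0, tested = sum(!is.na(ewas$p)),
                      fdr_significant = sum(sig_cpg),
                      bonferroni = sum(ewas$bonf_sig, na.rm = TRUE))

  # --- clustering / regions --------------------------------------------------
  t0 <- as.numeric(Sys.time())
  regions <- run_stage("regions",
                       find_clusters(ds, max_gap = config$max_gap,
                                     corr_threshold = config$corr_threshold))
  write_regions_bed(regions, out_file("regions.bed"),
                    out_file("region_probes.tsv"))
  report <- log_stage(report, "regions", t0, regions = nrow(regions),
                      clustered_probes = sum(regions$n_probes))

  # --- DMRs ------------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dmr <- run_stage("dmr", run_dmr(regions, ds, couples))
  write_dmr_csv(dmr, out_file("dmr.csv"))
  dmr_sig <- !is.na(dmr$q) & dmr$q < config$q_threshold
  report <- log_stage(report, "dmr", t0, tested = sum(!is.na(dmr$p)),
                      fdr_significant = sum(dmr_sig),
                      pct_hyper = if (any(dmr_sig))
                        round(100 * mean(dmr$direction[dmr_sig] == "hyper"), 1)
                      else NA)

  # --- annotation / enrichment ----------------------------------------------
  gene_map <- NULL
  t0 <- as.numeric(Sys.time())
  if (!is.null(tss)) {
    gene_map <- run_stage("annotate",
                          assign_nearest_gene(regions, tss,
                                              window = config$tss_window))
    export_gene_list(gene_map, dmr$region_id[dmr_sig],
                     out_file("dmr_genes.txt"))
  }
  if (!is.null(tracks) && any(dmr_sig)) {
    membership <- run_stage("annotate", annotate_features(regions, tracks))
    enr <- run_stage("annotate", enrichment_scan(dmr_sig, membership))
    write.csv(enr, out_file("enrichment.csv"), row.names = FALSE)
    dirs <- direction_summary(dmr[dmr_sig, , drop = FALSE],
                              membership[as.character(dmr$region_id), ,
                                         drop = FALSE])
    write.csv(dirs, out_file("dmr_direction_by_feature.csv"),
              row.names = FALSE)
  }
  report <- log_stage(report, "annotate", t0,
                      gene_assigned = if (is.null(gene_map)) 0
                      else sum(!is.na(gene_map$gene_id)))

  # --- ART outcomes ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  outcomes <- run_stage("outcomes",
                        run_art_outcomes(couples,
                                         stratify_infertility = TRUE))
  write.csv(outcomes, out_file("art_outcomes.csv"), row.names = FALSE)
  report <- log_stage(report, "outcomes", t0, fits = nrow(outcomes))

  # --- subject clustering ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (sum(sig_cpg) >= 2) {
    cl <- run_stage("cluster_subjects",
                    cluster_subjects(ds$beta[sig_cpg, , drop = FALSE],
                                     couples, k = config$k_subject_groups))
    write.csv(cl$summary, out_file("subject_groups.csv"), row.names = FALSE)
    report <- log_stage(report, "cluster_subjects", t0,
                        groups = config$k_subject_groups)
  } else {
    report$warnings <- c(report$warnings,
                         "fewer than 2 significant CpGs; subject clustering skipped")
    report <- log_stage(report, "cluster_subjects", t0, groups = 0)
  }

  # --- mediation -------------------------------------------------------------
  mediation <- list()
  if (config$run_mediation && !is.null(gene_map)) {
    for (oc in c("fertilization", "live_birth")) {
      t0 <- as.numeric(Sys.time())
      run <- run_stage(paste0("mediation_", oc),
                       run_mediation(oc, dmr[dmr_sig, , drop = FALSE],
                                     regions, ds, gene_map, couples,
                                     freq_threshold = config$freq_threshold,
                                     bootstrap_B = config$bootstrap_B,
                                     seed = stage_seed(config$seed, 20L)))
      mediation[[oc]] <- run
      write_mediation_report(run,
                             out_file(paste0("mediation_", oc, ".json")),
                             out_file(paste0("mediation_", oc, "_edges.csv")))
      report <- log_stage(report, paste0("mediation_", oc), t0,
                          stage1 = run$stage_sizes["stage1"] %||% 0,
                          selected = length(run$selected))
    }
  } else if (config$run_mediation) {
    report$warnings <- c(report$warnings,
                         "no TSS table available; mediation skipped")
  } else {
    report$warnings <- c(report$warnings, "mediation disabled by config")
  }

  report$results <- list(ewas = ewas, regions = regions, dmr = dmr,
                         outcomes = outcomes, gene_map = gene_map,
                         mediation = mediation, truth = truth,
                         couples = couples)
  report_json <- report[c("parameters", "seed", "stages", "warnings",
                          "files")]
  jsonlite::write_json(report_json, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("spermage run report\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-18s %6.2fs  %s\n", nm, s$wall_seconds,
                paste(names(s)[-1], unlist(s[-1]), sep = "=",
                      collapse = " ")))
  }
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

# Synthetic annotation for simulated cohorts: a TSS within the gene-
# assignment window of every planted region (plus decoys), and CpG-context
# tracks partitioning each chromosome.
synthetic_annotation <- function(ds, truth, seed = 1L, tss_window = 1000) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  man <- ds$manifest
  reg <- truth$probe_region[man$probe_id]
  # one TSS near the first probe of every region (so all clusters are
  # assignable), named gene_<region>
  first <- !duplicated(reg)
  tss <- data.frame(gene_id = paste0("gene_", reg[first]),
                    chrom = man$chrom[first],
                    strand = ifelse(runif(sum(first)) < 0.5, "+", "-"),
                    tss_pos = pmax(1L, man$pos[first] -
                                     sample(0:tss_window, sum(first),
                                            replace = TRUE)),
                    stringsAsFactors = FALSE)
  # CpG-context tracks: alternating island/shore/shelf/open-sea blocks
  tracks <- list()
  blocks <- list()
  for (ch in unique(man$chrom)) {
    maxpos <- max(man$pos[man$chrom == ch]) + 5000L
    cuts <- seq(0L, maxpos, by = 4000L)
    lab <- rep(c("cpg_island", "cpg_shore", "cpg_shelf", "open_sea"),
               length.out = length(cuts))
    blocks[[ch]] <- data.frame(chrom = ch, start0 = cuts,
                               end = cuts + 4000L, feature = lab)
  }
  blocks <- do.call(rbind, blocks)
  for (f in unique(blocks$feature)) {
    b <- blocks[blocks$feature == f, , drop = FALSE]
    tracks[[f]] <- annotation_track(f, b$chrom, b$start0, b$end)
  }
  # nucleosome-retention decoy track: random 2 kb windows
  nuc <- blocks[sample(nrow(blocks), ceiling(nrow(blocks) / 5)), ,
                drop = FALSE]
  tracks[["nucleosome_retained"]] <-
    annotation_track("nucleosome_retained", nuc$chrom, nuc$start0,
                     nuc$start0 + 2000L)
  list(tss = tss, tracks = tracks)
}
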