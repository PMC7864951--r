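region_df <- function(chrom, start, end) {
  data.frame(region_id = seq_along(chrom), chrom = chrom, start = start,
             end = end, stringsAsFactors = FALSE)
}

test_that("Fisher enrichment matches manual 2x2 construction", {
  flags <- c(rep(TRUE, 10), rep(FALSE, 30))
  mem <- matrix(FALSE, 40, 1, dimnames = list(1:40, "island"))
  mem[c(1:7, 11:14), "island"] <- TRUE           # 7/10 DMR, 4/30 non-DMR
  res <- fisher_enrichment(flags, mem, "island")
  expect_equal(unname(res$table[1, ]), c(7, 3))
  expect_equal(unname(res$table[2, ]), c(4, 26))
  expect_equal(res$p, fisher.test(res$table)$p.value)
  expect_equal(res$odds_ratio, (7 * 26) / (3 * 4))
  expect_equal(res$direction, "enriched")
  # zero cell: Haldane correction keeps the OR finite
  mem[, 1] <- c(rep(TRUE, 10), rep(FALSE, 30))
  res0 <- fisher_enrichment(flags, mem, "island")
  expect_true(is.finite(res0$odds_ratio))
  expect_equal(res0$odds_ratio, (10.5 * 30.5) / (0.5 * 0.5))
  expect_error(fisher_enrichment(rep(FALSE, 40), mem, "island"), "empty DMR")
})

test_that("feature membership equals a brute-force overlap oracle", {
  set.seed(30)
  for (rep in 1:10) {
    nr <- 25
    chrom <- sample(c("chr01", "chr02"), nr, replace = TRUE)
    start <- sample(1:5000, nr)
    regions <- region_df(chrom, start, start + sample(50:500, nr, TRUE))
    ts <- sample(0:5000, 8)
    track <- annotation_track("t", sample(c("chr01", "chr02"), 8, TRUE),
                              ts, ts + sample(100:800, 8, TRUE))
    mem <- annotate_features(regions, list(t = track))
    tchrom <- as.character(GenomeInfoDb::seqnames(track$granges))
    t1 <- BiocGenerics::start(track$granges)   # 1-based closed
    t2 <- BiocGenerics::end(track$granges)
    for (i in seq_len(nr)) {
      want <- any(tchrom == regions$chrom[i] &
                    t1 <= regions$end[i] & t2 >= regions$start[i])
      expect_equal(unname(mem[i, "t"]), want, info = paste(rep, i))
    }
  }
})

test_that("half-open BED abutment is not an overlap", {
  # BED [0, 100) covers 1-based 1..100; a region starting at 101 abuts it
  track <- annotation_track("t", "chr01", 0L, 100L)
  regions <- region_df(c("chr01", "chr01"), c(101L, 100L), c(150L, 150L))
  mem <- annotate_features(regions, list(t = track))
  expect_false(mem[1, "t"])
  expect_true(mem[2, "t"])
  expect_error(annotation_track("t", "chr01", 10L, 10L), "start must be <")
})

test_that("BED tracks round-trip through disk without coordinate drift", {
  reg <- region_df("chr01", c(101L, 500L), c(200L, 700L))
  class(reg) <- c("MethylRegionSet", "data.frame")
  reg$probe_ids <- list(c("a", "b"), c("c", "d"))
  reg$n_probes <- c(2L, 2L)
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(reg, bed)
  track <- read_bed_track(bed)
  expect_equal(BiocGenerics::start(track$granges), c(101L, 500L))
  expect_equal(BiocGenerics::end(track$granges), c(200L, 700L))
  unlink(bed)
})

test_that("nearest-gene assignment handles distance, window and ties", {
  regions <- region_df(rep("chr01", 4),
                       c(1000L, 5000L, 9000L, 20000L),
                       c(1500L, 5400L, 9300L, 20200L))
  tss <- data.frame(gene_id = c("gB", "gA", "gC", "gD"),
                    chrom = "chr01", strand = "+",
                    tss_pos = c(1200L, 1200L, 5600L, 30000L),
                    stringsAsFactors = FALSE)
  gm <- assign_nearest_gene(regions, tss, window = 1500)
  # TSS inside the region: distance 0; lexicographic tie-break gA before gB
  expect_equal(gm$gene_id[1], "gA")
  expect_equal(gm$distance[1], 0)
  expect_equal(gm$ambiguous[1], "gA,gB")
  # nearest edge distance: 5600 - 5400 = 200
  expect_equal(gm$gene_id[2], "gC")
  expect_equal(gm$distance[2], 200)
  # within window from the left edge: 9000 - 5600 = 3400 > 1500 -> unassigned
  expect_true(is.na(gm$gene_id[3]))
  expect_true(is.na(gm$gene_id[4]))
  # exact-window boundary counts as assigned
  gm2 <- assign_nearest_gene(region_df("chr01", 10000L, 10100L),
                             data.frame(gene_id = "gE", chrom = "chr01",
                                        strand = "-", tss_pos = 8500L),
                             window = 1500)
  expect_equal(gm2$gene_id, "gE")
  expect_equal(gm2$distance, 1500)
})

test_that("unmatched chromosome names fail loudly", {
  regions <- region_df("chr01", 100L, 200L)
  track <- annotation_track("t", "1", 50L, 400L)   # different naming scheme
  expect_error(annotate_features(regions, list(t = track)),
               "share nothing")
})

test_that("direction summaries report NA for featureless DMR sets", {
  dmr <- data.frame(region_id = 1:4,
                    direction = c("hyper", "hyper", "hypo", "hyper"))
  mem <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                  FALSE, FALSE, FALSE, FALSE), 4, 2,
                dimnames = list(1:4, c("island", "shelf")))
  ds <- direction_summary(dmr, mem)
  expect_equal(ds$pct_hyper[ds$feature == "island"], 100 * 2 / 3)
  expect_true(is.na(ds$pct_hyper[ds$feature == "shelf"]))
  expect_equal(ds$n_dmrs, c(3L, 0L))
})

test_that("the Spearman locus test matches the rank-correlation formula", {
  set.seed(31)
  vals <- rnorm(30); age <- rnorm(30)
  res <- spearman_locus(vals, age)
  expect_equal(res$rho, cor(vals, age, method = "spearman"))
  ref <- cor.test(vals, age, method = "spearman")    # AS89/exact p differs;
  expect_equal(res$rho, unname(ref$estimate))        # the rho must agree
  tv <- res$rho * sqrt(28 / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(-abs(tv), 28))
  # perfect monotone association
  expect_equal(spearman_locus(1:10, (1:10)^3)$p, 0)
  expect_error(spearman_locus(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(spearman_locus(rnorm(4), rnorm(4)), "at least 5")
})

test_that("TSS tables skip malformed rows and gene lists deduplicate", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttss_pos",
               "gA\tchr01\t+\t100",
               "gB\tchr01\t-\tnot_a_number",
               "gC\tchr02\t+\t500"), f)
  tt <- read_tss_table(f)
  expect_equal(nrow(tt), 2)
  expect_equal(attr(tt, "n_skipped"), 1)
  unlink(f)
  gm <- data.frame(region_id = 1:4, gene_id = c("gB", "gA", "gB", NA),
                   stringsAsFactors = FALSE)
  out <- tempfile()
  genes <- export_gene_list(gm, region_subset = 1:4, path = out)
  expect_equal(genes, c("gA", "gB"))
  expect_equal(readLines(out), c("gene_id", "gA", "gB"))
  unlink(out)
})
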