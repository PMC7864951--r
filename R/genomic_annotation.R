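#' Read a BED annotation track
#'
#' Imports a BED file (3+ columns, 0-based half-open) as a named annotation
#' track. Coordinates are held as a `GRanges` (1-based closed internally,
#' exactly as `rtracklayer` converts BED).
#'
#' @param path BED file.
#' @param name track name (defaults to the file name without extension).
#' @return object of class `AnnotationTrack`: list with `name` and
#'   `granges`.
#' @export
read_bed_track <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  gr <- rtracklayer::import(path, format = "BED")
  annotation_track(name,
                   chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start0 = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr))
}

#' Build an annotation track from coordinates
#'
#' @param name track name.
#' @param chrom chromosome labels.
#' @param start0 0-based half-open interval starts.
#' @param end interval ends (exclusive).
#' @return an `AnnotationTrack`.
#' @export
annotation_track <- function(name, chrom, start0, end) {
  if (any(start0 >= end)) stop("invalid intervals: start must be < end")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end))
  gr <- BiocGenerics::sort(gr)
  structure(list(name = name, granges = gr), class = "AnnotationTrack")
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start,
                                          end = regions$end))
}

#' Read a TSS table (TSV: gene_id, chrom, strand, tss_pos; 1-based)
#' @param path file path.
#' @return data.frame; malformed rows (missing fields, non-numeric position)
#'   are skipped and counted in attribute `"n_skipped"`.
#' @export
read_tss_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  fill = TRUE)
  stopifnot(all(c("gene_id", "chrom", "strand", "tss_pos") %in% names(d)))
  d$tss_pos <- suppressWarnings(as.integer(d$tss_pos))
  ok <- !is.na(d$tss_pos) & nzchar(d$gene_id) & nzchar(d$chrom)
  out <- d[ok, , drop = FALSE]
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Assign each region its nearest gene within a TSS window
#'
#' A region is assigned to the gene whose transcription start site is
#' closest (distance 0 when the TSS lies inside the region, unsigned
#' distance to the nearer region edge otherwise), provided the distance is
#' at most `window` bp; otherwise it stays unassigned. Strand is ignored.
#' Equidistant ties resolve to the lexicographically smallest gene id, with
#' all tied genes recorded.
#'
#' @param regions a `MethylRegionSet` (or data.frame with `region_id`,
#'   `chrom`, `start`, `end`; 1-based inclusive).
#' @param tss_table data.frame from [read_tss_table()].
#' @param window maximum TSS distance in bp (default 1500).
#' @return data.frame: `region_id`, `gene_id` (NA if unassigned),
#'   `distance`, `ambiguous` (comma-joined tied gene ids or NA).
#' @export
assign_nearest_gene <- function(regions, tss_table, window = 1500) {
  n <- nrow(regions)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  amb <- rep(NA_character_, n)
  for (ch in unique(regions$chrom)) {
    ridx <- which(regions$chrom == ch)
    tt <- tss_table[tss_table$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) next
    for (i in ridx) {
      d <- ifelse(tt$tss_pos >= regions$start[i] & tt$tss_pos <= regions$end[i],
                  0,
                  pmin(abs(tt$tss_pos - regions$start[i]),
                       abs(tt$tss_pos - regions$end[i])))
      dmin <- min(d)
      if (dmin <= window) {
        tied <- sort(tt$gene_id[d == dmin])
        gene[i] <- tied[1]
        dist[i] <- dmin
        if (length(tied) > 1) amb[i] <- paste(tied, collapse = ",")
      }
    }
  }
  data.frame(region_id = regions$region_id, gene_id = gene,
             distance = dist, ambiguous = amb, stringsAsFactors = FALSE)
}

#' Feature membership of regions (any-overlap)
#'
#' A region is a member of a feature when its interval overlaps any track
#' interval by at least one base pair; features are not mutually exclusive.
#'
#' @param regions a `MethylRegionSet`.
#' @param tracks list of `AnnotationTrack` objects (named list or tracks
#'   carrying their own names).
#' @return logical matrix, regions x features, rownames = region ids.
#' @export
annotate_features <- function(regions, tracks) {
  if (!is.null(names(tracks)) && all(nzchar(names(tracks)))) {
    nms <- names(tracks)
  } else nms <- vapply(tracks, `[[`, character(1), "name")
  rg <- regions_granges(regions)
  out <- matrix(FALSE, nrow(regions), length(tracks),
                dimnames = list(regions$region_id, nms))
  rchrom <- unique(regions$chrom)
  for (j in seq_along(tracks)) {
    gr <- tracks[[j]]$granges
    tchrom <- unique(as.character(GenomeInfoDb::seqnames(gr)))
    if (!length(intersect(rchrom, tchrom)))
      stop("chromosome names of track '", nms[j],
           "' share nothing with the region set; unmatched: ",
           paste(setdiff(tchrom, rchrom), collapse = ", "))
    hits <- GenomicRanges::findOverlaps(rg, gr, minoverlap = 1L)
    out[unique(S4Vectors::queryHits(hits)), j] <- TRUE
  }
  out
}

#' Fisher-exact enrichment of DMRs in a genomic feature
#'
#' Contrasts DMRs against non-DMR regions (disjoint rows) in a 2x2 table of
#' feature membership; two-sided exact p-value by summing hypergeometric
#' probabilities no larger than the observed table's. The odds ratio is the
#' sample OR, with a Haldane 0.5 correction when any cell is zero.
#'
#' @param dmr_flags logical vector over all regions (TRUE = DMR), aligned
#'   with the rows of `membership`.
#' @param membership logical membership matrix from [annotate_features()].
#' @param feature feature (column) name.
#' @return list of class `EnrichmentResult`: `feature`, `table` (2x2),
#'   `odds_ratio`, `p`, `direction` ("enriched"/"depleted"/"none").
#' @export
fisher_enrichment <- function(dmr_flags, membership, feature) {
  stopifnot(length(dmr_flags) == nrow(membership))
  if (!any(dmr_flags)) stop("empty DMR set")
  mem <- membership[, feature]
  tab <- matrix(c(sum(dmr_flags & mem), sum(dmr_flags & !mem),
                  sum(!dmr_flags & mem), sum(!dmr_flags & !mem)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("DMR", "nonDMR"),
                                c("in_feature", "not_in_feature")))
  p <- fisher.test(tab)$p.value
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  direction <- if (or > 1) "enriched" else if (or < 1) "depleted" else "none"
  structure(list(feature = feature, table = tab, odds_ratio = or, p = p,
                 direction = direction),
            class = "EnrichmentResult")
}

#' Enrichment scan over all features
#' @inheritParams fisher_enrichment
#' @return data.frame, one row per feature: counts, odds ratio, p,
#'   direction.
#' @export
enrichment_scan <- function(dmr_flags, membership) {
  res <- lapply(colnames(membership), function(f)
    fisher_enrichment(dmr_flags, membership, f))
  data.frame(
    feature = vapply(res, `[[`, character(1), "feature"),
    dmr_in = vapply(res, function(r) r$table[1, 1], numeric(1)),
    dmr_out = vapply(res, function(r) r$table[1, 2], numeric(1)),
    nondmr_in = vapply(res, function(r) r$table[2, 1], numeric(1)),
    nondmr_out = vapply(res, function(r) r$table[2, 2], numeric(1)),
    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
    p = vapply(res, `[[`, numeric(1), "p"),
    direction = vapply(res, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
}

#' Hyper/hypo direction summary per feature
#'
#' Percent of member DMRs that are hypermethylated, per feature. Features
#' containing no DMRs report `NA` (not 0%).
#'
#' @param dmr_results data.frame with `region_id` and `direction`
#'   ("hyper"/"hypo"), one row per DMR.
#' @param membership logical membership matrix over the same DMRs (rownames
#'   = region ids).
#' @return data.frame: `feature`, `n_dmrs`, `pct_hyper`.
#' @export
direction_summary <- function(dmr_results, membership) {
  mem <- membership[as.character(dmr_results$region_id), , drop = FALSE]
  out <- lapply(colnames(mem), function(f) {
    inside <- mem[, f]
    n <- sum(inside)
    pct <- if (n == 0) NA_real_
    else 100 * sum(dmr_results$direction[inside] == "hyper") / n
    data.frame(feature = f, n_dmrs = n, pct_hyper = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman correlation of a locus with age
#'
#' Rank correlation with average-rank ties; the p-value uses the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param values methylation values (one per subject).
#' @param age ages.
#' @return list with `rho` and `p`.
#' @export
spearman_locus <- function(values, age) {
  n <- length(values)
  stopifnot(length(age) == n)
  if (n < 5) stop("need at least 5 subjects")
  if (var(values) == 0 || var(age) == 0)
    stop("zero variance in values or age")
  rho <- cor(rank(values, ties.method = "average"),
             rank(age, ties.method = "average"))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), n - 2))
}

#' Export a deduplicated, sorted gene list
#'
#' @param gene_map data.frame from [assign_nearest_gene()].
#' @param region_subset region ids to include (e.g. the FDR-significant
#'   DMR set).
#' @param path output text file (header `gene_id`, one gene per line).
#' @return invisibly, the character vector of genes written.
#' @export
export_gene_list <- function(gene_map, region_subset, path) {
  g <- gene_map$gene_id[gene_map$region_id %in% region_subset]
  g <- sort(unique(g[!is.na(g)]))
  writeLines(c("gene_id", g), path)
  invisible(g)
}
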