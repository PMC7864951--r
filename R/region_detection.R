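#' Adjacent-site correlation clustering of probes into co-methylated regions
#'
#' Greedy left-to-right scan per chromosome over position-sorted probes: the
#' current cluster is extended to the next probe iff the gap to the previous
#' probe is at most `max_gap` base pairs AND the linkage correlation between
#' the candidate and the current cluster reaches `corr_threshold`; otherwise
#' the cluster is closed and a new one starts. Only clusters of two or more
#' probes are emitted. Correlations are computed between probes' M-values
#' across subjects.
#'
#' @param ds a `MethylomeDataset` (manifest position-sorted; >= 10 subjects
#'   recommended for stable correlations).
#' @param max_gap maximum distance between consecutive member probes (bp),
#'   default 1000.
#' @param corr_threshold correlation needed to join a cluster, in (0, 1).
#' @param corr_type `"spearman"` (default) or `"pearson"`.
#' @param linkage `"single"` (candidate vs the nearest member, i.e. the
#'   previous probe) or `"average"` (mean correlation with all members).
#' @return data.frame of class `MethylRegionSet`: `region_id`, `chrom`,
#'   `start`, `end` (1-based positions of the first/last probe), `n_probes`,
#'   and a list-column `probe_ids` ordered by position.
#' @export
find_clusters <- function(ds, max_gap = 1000, corr_threshold = 0.5,
                          corr_type = c("spearman", "pearson"),
                          linkage = c("single", "average")) {
  corr_type <- match.arg(corr_type)
  linkage <- match.arg(linkage)
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop("corr_threshold must lie in (0, 1)")
  man <- ds$manifest
  for (ch in unique(man$chrom)) {
    ps <- man$pos[man$chrom == ch]
    if (is.unsorted(ps)) stop("manifest positions unsorted within ", ch)
  }
  M <- m_values(ds)
  # Spearman = Pearson on row ranks; precompute transformed rows once
  R <- if (corr_type == "spearman")
    t(apply(M, 1, rank, ties.method = "average")) else M
  Rc <- R - rowMeans(R)
  Rn <- Rc / sqrt(pmax(rowSums(Rc^2), .Machine$double.eps))
  pair_cor <- function(i, j) sum(Rn[i, ] * Rn[j, ])

  out <- list()
  rid <- 0L
  for (ch in unique(man$chrom)) {
    idx <- which(man$chrom == ch)
    if (length(idx) < 2) next
    cur <- idx[1]
    for (k in idx[-1]) {
      prev <- cur[length(cur)]
      gap_ok <- (man$pos[k] - man$pos[prev]) <= max_gap
      if (gap_ok) {
        cc <- if (linkage == "single") pair_cor(k, prev)
        else mean(vapply(cur, pair_cor, numeric(1), j = k))
        join <- !is.na(cc) && cc >= corr_threshold
      } else join <- FALSE
      if (join) {
        cur <- c(cur, k)
      } else {
        if (length(cur) >= 2) {
          rid <- rid + 1L
          out[[rid]] <- list(region_id = rid, chrom = ch,
                             start = man$pos[cur[1]],
                             end = man$pos[cur[length(cur)]],
                             n_probes = length(cur),
                             probe_ids = man$probe_id[cur])
        }
        cur <- k
      }
    }
    if (length(cur) >= 2) {
      rid <- rid + 1L
      out[[rid]] <- list(region_id = rid, chrom = ch,
                         start = man$pos[cur[1]],
                         end = man$pos[cur[length(cur)]],
                         n_probes = length(cur),
                         probe_ids = man$probe_id[cur])
    }
  }
  if (!length(out)) {
    res <- data.frame(region_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0))
    res$probe_ids <- list()
  } else {
    res <- data.frame(
      region_id = vapply(out, `[[`, integer(1), "region_id"),
      chrom = vapply(out, `[[`, character(1), "chrom"),
      start = vapply(out, function(x) as.integer(x$start), integer(1)),
      end = vapply(out, function(x) as.integer(x$end), integer(1)),
      n_probes = vapply(out, `[[`, integer(1), "n_probes"),
      stringsAsFactors = FALSE)
    res$probe_ids <- lapply(out, `[[`, "probe_ids")
  }
  class(res) <- c("MethylRegionSet", "data.frame")
  res
}

#' Write regions as BED (0-based half-open) plus a probe-membership TSV
#' @param regions a `MethylRegionSet`.
#' @param bed_path,membership_path output paths.
#' @return invisibly, the paths.
#' @export
write_regions_bed <- function(regions, bed_path, membership_path = NULL) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end,
                    name = paste0("region_", regions$region_id))
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(membership_path)) {
    mem <- data.frame(
      region_id = rep(regions$region_id, lengths(regions$probe_ids)),
      probe_id = unlist(regions$probe_ids))
    write.table(mem, membership_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(bed_path, membership_path))
}
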