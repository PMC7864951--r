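#' spermage: male age, the sperm methylome and ART outcomes
#'
#' Analysis pipeline for epigenome-wide association of male age with sperm
#' DNA methylation, region-level testing, genomic enrichment, oocyte-weighted
#' outcome models, and high-dimensional mediation of age effects on assisted
#' reproduction outcomes through sperm methylation.
#'
#' @useDynLib spermage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm lm.fit coef pnorm pt qnorm quantile var sd cor
#'   p.adjust fisher.test plogis qlogis rnorm runif rbinom rnbinom
#'   complete.cases setNames hclust cutree dist median
#' @importFrom utils read.table write.table write.csv read.csv head
#' @keywords internal
"_PACKAGE"

#' Convert beta-values to M-values
#'
#' The M-value is the log2 logit of the methylation proportion,
#' `M = log2(beta / (1 - beta))`, the scale on which methylation linear
#' models are homoscedastic. Values are clipped into `[eps, 1 - eps]` before
#' the transform so boundary betas map to finite M-values.
#'
#' @param beta numeric vector/matrix of methylation proportions in (0, 1).
#' @param eps clipping bound, `0 < eps < 0.5`. Default `1e-6`.
#' @return M-values with the same shape as `beta`.
#' @seealso [m_to_beta()] for the inverse.
#' @export
#' @examples
#' beta_to_m(0.5)   # 0
#' beta_to_m(0.8)   # 2
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  if (any(!is.finite(beta))) stop("non-finite beta values")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m numeric vector/matrix of M-values.
#' @return methylation proportions in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("non-finite M-values")
  plogis(m * log(2))
}

#' Construct a methylome dataset
#'
#' Bundles a probe manifest with a probes-by-subjects beta-value matrix.
#' The manifest is sorted by chromosome and ascending position, and the
#' matrix rows are reordered to match.
#'
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based probe coordinate).
#' @param beta numeric matrix of beta-values, probes x subjects, rownames =
#'   probe ids, colnames = subject ids (required if `subject_ids` missing).
#' @param subject_ids optional character vector overriding `colnames(beta)`.
#' @return object of class `MethylomeDataset`: list with elements
#'   `manifest`, `beta`, `subject_ids`.
#' @export
methylome_dataset <- function(manifest, beta, subject_ids = NULL) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(manifest)))
  manifest$probe_id <- as.character(manifest$probe_id)
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe ids in manifest")
  if (is.null(subject_ids)) subject_ids <- colnames(beta)
  if (is.null(subject_ids)) stop("subject ids missing (no colnames on beta)")
  if (nrow(beta) != nrow(manifest)) stop("beta rows != manifest rows")
  if (is.null(rownames(beta))) rownames(beta) <- manifest$probe_id
  if (!identical(rownames(beta), manifest$probe_id)) {
    beta <- beta[manifest$probe_id, , drop = FALSE]
  }
  if (anyNA(beta)) stop("missing beta values; impute or drop before building the dataset")
  if (any(beta <= 0 | beta >= 1)) stop("beta values must lie strictly in (0, 1)")
  ord <- order(manifest$chrom, manifest$pos)
  manifest <- manifest[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  rownames(manifest) <- NULL
  colnames(beta) <- subject_ids
  structure(list(manifest = manifest, beta = beta, subject_ids = subject_ids),
            class = "MethylomeDataset")
}

#' @export
print.MethylomeDataset <- function(x, ...) {
  cat(sprintf("MethylomeDataset: %d probes x %d subjects on %d chromosome(s)\n",
              nrow(x$beta), ncol(x$beta), length(unique(x$manifest$chrom))))
  invisible(x)
}

#' M-value matrix of a dataset
#'
#' @param ds a `MethylomeDataset`.
#' @param eps clipping bound passed to [beta_to_m()].
#' @return probes x subjects matrix of M-values.
#' @export
m_values <- function(ds, eps = 1e-6) beta_to_m(ds$beta, eps)

#' Remove probes named in exclusion lists
#'
#' Drops every probe that appears in any of the supplied lists (cross-reactive
#' probes, sex-chromosome probes, SNP-proximal probes, user lists, ...).
#' Probes appearing in several lists are attributed to the first list that
#' names them. Unknown ids are ignored but counted.
#'
#' @param ds a `MethylomeDataset`.
#' @param exclusion_lists named list of character vectors of probe ids.
#' @return filtered `MethylomeDataset` with attribute `"filter_report"`:
#'   a list with per-reason exclusion counts, unknown-id counts, and
#'   probes in/out.
#' @export
apply_probe_filters <- function(ds, exclusion_lists = list()) {
  ids <- ds$manifest$probe_id
  reason <- rep(NA_character_, length(ids))
  names(reason) <- ids
  unknown <- integer(length(exclusion_lists))
  names(unknown) <- names(exclusion_lists)
  for (nm in names(exclusion_lists)) {
    lst <- unique(as.character(exclusion_lists[[nm]]))
    unknown[nm] <- sum(!(lst %in% ids))
    hit <- ids %in% lst & is.na(reason)
    reason[hit] <- nm
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("all probes excluded; empty dataset")
  counts <- table(factor(reason[!keep], levels = names(exclusion_lists)))
  out <- methylome_dataset(ds$manifest[keep, , drop = FALSE],
                           ds$beta[keep, , drop = FALSE], ds$subject_ids)
  attr(out, "filter_report") <- list(
    n_in = length(ids), n_out = sum(keep),
    excluded_by_reason = as.list(counts),
    unknown_ids = as.list(unknown))
  out
}

#' Imprinted-locus contamination QC
#'
#' Somatic-cell contamination of a sperm sample shifts maternally imprinted
#' loci away from ~0% methylation and paternally imprinted loci away from
#' ~100%. A subject passes when the mean beta of every maternal locus is
#' strictly below `maternal_max` and of every paternal locus strictly above
#' `paternal_min`.
#'
#' @param ds a `MethylomeDataset`.
#' @param maternal_loci named list; each element a character vector of probe
#'   ids for one maternally imprinted locus.
#' @param paternal_loci as above, paternally imprinted.
#' @param maternal_max pass threshold for maternal loci (default 0.10).
#' @param paternal_min pass threshold for paternal loci (default 0.85).
#' @return list of class `QCReport`: per-subject/per-locus mean betas
#'   (`locus_means`), logical `pass` per subject, and `offending` loci per
#'   failing subject.
#' @export
imprinting_qc <- function(ds, maternal_loci, paternal_loci,
                          maternal_max = 0.10, paternal_min = 0.85) {
  if (length(maternal_loci) == 0 || length(paternal_loci) == 0)
    stop("imprinted locus sets must be non-empty")
  all_loci <- c(maternal_loci, paternal_loci)
  missing <- setdiff(unique(unlist(all_loci)), ds$manifest$probe_id)
  if (length(missing))
    stop("imprinted probes absent from manifest: ", paste(missing, collapse = ", "))
  locus_mean <- function(probes)
    colMeans(ds$beta[ds$manifest$probe_id %in% probes, , drop = FALSE])
  mat <- vapply(maternal_loci, locus_mean, numeric(length(ds$subject_ids)))
  pat <- vapply(paternal_loci, locus_mean, numeric(length(ds$subject_ids)))
  mat <- matrix(mat, nrow = length(ds$subject_ids),
                dimnames = list(ds$subject_ids, names(maternal_loci)))
  pat <- matrix(pat, nrow = length(ds$subject_ids),
                dimnames = list(ds$subject_ids, names(paternal_loci)))
  ok_mat <- mat < maternal_max
  ok_pat <- pat > paternal_min
  pass <- apply(ok_mat, 1, all) & apply(ok_pat, 1, all)
  offending <- lapply(ds$subject_ids, function(s) {
    c(colnames(mat)[!ok_mat[s, ]], colnames(pat)[!ok_pat[s, ]])
  })
  names(offending) <- ds$subject_ids
  structure(list(locus_means = list(maternal = mat, paternal = pat),
                 pass = pass,
                 offending = offending[!pass],
                 thresholds = c(maternal_max = maternal_max,
                                paternal_min = paternal_min)),
            class = "QCReport")
}

# ---- file I/O -------------------------------------------------------------

#' Read a probe manifest (TSV: probe_id, chrom, pos)
#' @param path file path.
#' @return data.frame sorted by chromosome then position.
#' @export
read_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(m)))
  m$probe_id <- as.character(m$probe_id)
  m$pos <- as.integer(m$pos)
  m[order(m$chrom, m$pos), , drop = FALSE]
}

#' Read a beta-value matrix (TSV, probes as rows, header = subject ids)
#' @param path file path.
#' @return numeric matrix with probe rownames and subject colnames.
#' @export
read_beta_matrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  as.matrix(d)
}

#' Write manifest + beta matrix of a dataset
#' @param ds a `MethylomeDataset`.
#' @param manifest_path,beta_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_methylome <- function(ds, manifest_path, beta_path) {
  write.table(ds$manifest[c("probe_id", "chrom", "pos")], manifest_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = rownames(ds$beta), ds$beta,
                         check.names = FALSE),
              beta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(manifest_path, beta_path))
}

#' Read an exclusion list (one probe id per line)
#' @param path file path.
#' @return character vector.
#' @export
read_exclusion_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}
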