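#' Count matrix with sample metadata
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with one row per sample: columns `sample`,
#'   `stage` (one of `oocyte`, `1-cell`, `2-cell`), `genotype` (`WT`/`KO`);
#'   further columns (e.g. batch) are carried along.
#' @return list with elements `counts`, `samples`, class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry feature rownames and sample colnames",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  miss <- setdiff(c("sample", "stage", "genotype"), names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!setequal(colnames(counts), samples$sample) ||
      anyDuplicated(samples$sample)) {
    stop("sample metadata must match count columns exactly", call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  print(table(stage = x$samples$stage, genotype = x$samples$genotype))
  invisible(x)
}

#' Subset a count matrix by sample
#'
#' @param m a [count_matrix()].
#' @param keep logical or character selector over samples.
#' @return a [count_matrix()].
#' @export
subset_samples <- function(m, keep) {
  if (is.logical(keep)) keep <- m$samples$sample[keep]
  count_matrix(m$counts[, keep, drop = FALSE],
               m$samples[m$samples$sample %in% keep, , drop = FALSE])
}

#' log2 CPM transform
#'
#' Computes `log2(count / sample_total * 1e6 + 1)` per entry, the expression
#' scale used for co-expression analysis.
#'
#' @param m a [count_matrix()] or bare numeric matrix.
#' @return numeric matrix of the same shape.
#' @export
cpm_log_transform <- function(m) {
  x <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  totals <- colSums(x)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(x)[totals == 0], collapse = ", "), call. = FALSE)
  }
  log2(sweep(x, 2, totals, "/") * 1e6 + 1)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of
#' `count[f, s] / geometric_mean_f`, taken across features with a nonzero
#' count in every sample (so the geometric mean is finite).
#'
#' @param m a [count_matrix()] or bare numeric matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  x <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  use <- rowSums(x == 0) == 0
  if (!any(use)) {
    stop("no feature has nonzero counts in every sample; ",
         "size factors are undefined", call. = FALSE)
  }
  xs <- x[use, , drop = FALSE]
  gm <- exp(rowMeans(log(xs)))
  apply(xs, 2, function(col) stats::median(col / gm))
}

#' Normalize counts by size factors
#'
#' @param m a [count_matrix()] or matrix.
#' @param factors optional precomputed factors; defaults to [size_factors()].
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(m, factors = NULL) {
  x <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (is.null(factors)) factors <- size_factors(x)
  sweep(x, 2, factors, "/")
}

#' Per-sample quality-control report
#'
#' Counts, for each sample, the reads whose alignment overlaps any annotated
#' exon and the proportion of reads on mitochondrial contigs. Reads are
#' counted once each (multi-mapped reads by their full alignment list
#' overlapping an exon at least once).
#'
#' @param alns an [alignment_set()] (may span samples).
#' @param ann a [genome_annotation()].
#' @param mito_contigs contig name(s) treated as mitochondrial.
#' @return data.frame `sample`, `total_reads`, `exon_reads`, `mito_fraction`.
#' @export
compute_qc <- function(alns, ann, mito_contigs = "chrM") {
  key <- paste(alns$sample, alns$read_id, sep = "\r")
  segs <- alignment_segments(alns)
  hit_exon <- IRanges::overlapsAny(segs, ann$exons, ignore.strand = TRUE)
  exon_keys <- unique(segs$record[hit_exon])
  exon_keys <- unique(key[exon_keys])
  mito_keys <- unique(key[alns$chrom %in% mito_contigs])
  all_keys <- unique(key)
  key_sample <- sub("\r.*$", "", all_keys)
  res <- do.call(rbind, lapply(unique(alns$sample), function(s) {
    ks <- all_keys[key_sample == s]
    data.frame(sample = s, total_reads = length(ks),
               exon_reads = sum(ks %in% exon_keys),
               mito_fraction = sum(ks %in% mito_keys) / max(length(ks), 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Sample quality filter
#'
#' A sample passes iff its exon-mapped read count is strictly greater than
#' `exon_min` AND its mitochondrial read proportion is strictly less than
#' `mito_max` (both inequalities strict).
#'
#' @param report data.frame with columns `sample`, `exon_reads`,
#'   `mito_fraction` (as produced by [compute_qc()]).
#' @param exon_min minimum exon-mapped reads (default 500,000).
#' @param mito_max maximum mitochondrial proportion (default 0.10).
#' @return the report with a logical `pass` column appended.
#' @export
qc_filter <- function(report, exon_min = 500000, mito_max = 0.10) {
  miss <- setdiff(c("sample", "exon_reads", "mito_fraction"), names(report))
  if (length(miss)) stop("QC report lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(report$mito_fraction < 0 | report$mito_fraction > 1)) {
    stop("mito_fraction outside [0, 1]", call. = FALSE)
  }
  report$pass <- report$exon_reads > exon_min & report$mito_fraction < mito_max
  report
}
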