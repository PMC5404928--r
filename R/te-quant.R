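te_level_labels <- function(tes, level) {
  switch(level,
         copy = tes$te_id,
         element = tes$repName,
         family = tes$repFamily,
         class = tes$repClass,
         stop("unknown level: ", level, call. = FALSE))
}

# rows of `alns` retained under a counting mode; for "all_alignments" every
# non-supplementary record becomes its own read unit (the NH := 1 trick)
retained_alignments <- function(alns, mode, seed) {
  switch(mode,
    unique_only = alns[alns$nh == 1L & !alns$secondary, , drop = FALSE],
    unique_plus_one_random =
      alns[select_one_alignment(alns, seed), , drop = FALSE],
    all_alignments = alns[!alns$supplementary, , drop = FALSE],
    stop("unknown mode: ", mode, call. = FALSE))
}

#' Count reads per TE feature
#'
#' Counts retained reads against the TE annotation at a chosen level of the
#' RepeatMasker hierarchy. Mode `unique_only` keeps multiplicity-1 reads
#' only; `unique_plus_one_random` first selects one alignment per
#' multi-mapped read uniformly at random (seeded) and then counts every
#' retained read; `all_alignments` counts each alignment of a multi-read as
#' its own read. A retained read is assigned to a feature iff the union of
#' its aligned segments (N gaps excluded) overlaps exactly one distinct
#' feature label at the counting level; reads touching two or more labels
#' are discarded as ambiguous, and reads touching none count only toward the
#' mapped-read denominator. Overlap is strand-agnostic.
#'
#' @param alns an [alignment_set()].
#' @param ann a [genome_annotation()].
#' @param mode counting mode (see above).
#' @param level `"copy"` (per genomic region), `"element"` (repName),
#'   `"family"` (repFamily) or `"class"` (repClass).
#' @param seed seed for the random alignment choice.
#' @return object of class `te_count_table`: counts (features x samples),
#'   plus per-sample `mapped_total`, `te_total`, `ambiguous` and `non_te`
#'   read counts.
#' @export
count_te <- function(alns, ann,
                     mode = c("unique_plus_one_random", "unique_only",
                              "all_alignments"),
                     level = c("element", "family", "class", "copy"),
                     seed = 1L) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  sub <- retained_alignments(alns, mode, seed)
  labels <- te_level_labels(ann$tes, level)
  features <- sort(unique(labels))
  samples <- sort(unique(alns$sample))

  key <- if (mode == "all_alignments") {
    paste(sub$sample, sub$read_id, seq_len(nrow(sub)), sep = "\r")
  } else {
    paste(sub$sample, sub$read_id, sep = "\r")
  }
  segs <- alignment_segments(sub)
  seg_key <- key[segs$record]
  hits <- GenomicRanges::findOverlaps(segs, ann$tes, ignore.strand = TRUE)
  hit_df <- unique(data.frame(
    key = seg_key[S4Vectors::queryHits(hits)],
    label = labels[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  n_labels <- table(hit_df$key)
  uniq_keys <- names(n_labels)[n_labels == 1L]
  assigned <- hit_df[hit_df$key %in% uniq_keys, , drop = FALSE]

  ukey <- unique(key)
  read_sample <- sub("\r.*$", "", ukey)
  amb_keys <- names(n_labels)[n_labels > 1L]
  status <- ifelse(ukey %in% assigned$key, "assigned",
                   ifelse(ukey %in% amb_keys, "ambiguous", "non_te"))

  counts <- matrix(0L, length(features), length(samples),
                   dimnames = list(features, samples))
  if (nrow(assigned)) {
    tab <- table(factor(assigned$label, levels = features),
                 factor(sub("\r.*$", "", assigned$key), levels = samples))
    counts <- counts + unclass(tab)
  }
  per_sample <- function(st) {
    v <- table(factor(read_sample[status == st], levels = samples))
    stats::setNames(as.integer(v), samples)
  }
  structure(list(
    counts = counts, level = level, mode = mode, seed = seed,
    mapped_total = stats::setNames(
      as.integer(table(factor(read_sample, levels = samples))), samples),
    te_total = per_sample("assigned"),
    ambiguous = per_sample("ambiguous"),
    non_te = per_sample("non_te")),
    class = "te_count_table")
}

#' @export
print.te_count_table <- function(x, ...) {
  cat(sprintf("te_count_table: %d features (level %s, mode %s) x %d samples\n",
              nrow(x$counts), x$level, x$mode, ncol(x$counts)))
  cat("TE-mapped / mapped reads per sample:\n")
  print(rbind(te = x$te_total, mapped = x$mapped_total))
  invisible(x)
}

#' Multi-mapping assignment ambiguity across the repeat hierarchy
#'
#' For each multi-mapped read whose alignments all land in TEs, the read is
#' unambiguous at a hierarchy level iff all its alignments carry the same
#' label at that level. Reports the unambiguous fraction at the class,
#' family and element levels; by nesting these are non-increasing from
#' class down to element.
#'
#' @param alns an [alignment_set()] with full alignment lists for
#'   multi-mapped reads (`nh > 1`).
#' @param ann a [genome_annotation()].
#' @return object of class `ambiguity_report`: list with `proportion`
#'   (named vector over element/family/class), `n_reads`, and `empty`
#'   (TRUE when no multi-mapped TE read exists; proportions are then NA,
#'   not zero).
#' @export
assignment_ambiguity <- function(alns, ann) {
  multi <- alns[alns$nh > 1L & !alns$supplementary, , drop = FALSE]
  out <- list(proportion = c(element = NA_real_, family = NA_real_,
                             class = NA_real_),
              n_reads = 0L, empty = TRUE)
  class(out) <- "ambiguity_report"
  if (!nrow(multi)) return(out)
  segs <- alignment_segments(multi)
  hits <- GenomicRanges::findOverlaps(segs, ann$tes, ignore.strand = TRUE)
  rec_in_te <- seq_len(nrow(multi)) %in%
    segs$record[S4Vectors::queryHits(hits)]
  key <- paste(multi$sample, multi$read_id, sep = "\r")
  all_te <- tapply(rec_in_te, key, all)
  use_keys <- names(all_te)[all_te]
  if (!length(use_keys)) return(out)
  rec_key <- key[segs$record[S4Vectors::queryHits(hits)]]
  keep <- rec_key %in% use_keys
  te_idx <- S4Vectors::subjectHits(hits)[keep]
  rec_key <- rec_key[keep]
  prop <- vapply(c(element = "element", family = "family", class = "class"),
                 function(level) {
    lab <- te_level_labels(ann$tes, level)[te_idx]
    n_lab <- tapply(lab, rec_key, function(v) length(unique(v)))
    mean(n_lab == 1L)
  }, numeric(1))
  out$proportion <- prop
  out$n_reads <- length(use_keys)
  out$empty <- FALSE
  out
}

#' @export
print.ambiguity_report <- function(x, ...) {
  if (x$empty) {
    cat("ambiguity_report: no multi-mapped TE reads\n")
  } else {
    cat(sprintf(
      "ambiguity_report over %d multi-mapped TE reads:\n", x$n_reads))
    print(round(x$proportion, 4))
  }
  invisible(x)
}

#' Fraction of mapped reads assigned to TEs
#'
#' Counts under the `unique_plus_one_random` policy at class level and
#' reports, per sample, TE-assigned reads over all mapped reads.
#'
#' @inheritParams count_te
#' @return named numeric vector in `[0, 1]`, one value per sample.
#' @export
te_fraction <- function(alns, ann, seed = 1L) {
  t <- count_te(alns, ann, mode = "unique_plus_one_random", level = "class",
                seed = seed)
  if (!length(t$mapped_total)) {
    stop("no mapped reads in the alignment set", call. = FALSE)
  }
  if (any(t$mapped_total == 0)) {
    stop("sample(s) with zero mapped reads: ",
         paste(names(t$mapped_total)[t$mapped_total == 0], collapse = ", "),
         call. = FALSE)
  }
  t$te_total / t$mapped_total
}

#' Normalize a TE count table
#'
#' `within_sample` divides each feature count by the sample's TE-mapped
#' total (per-sample values then sum to 1 over TE features);
#' `between_sample` divides by median-of-ratios size factors.
#'
#' @param t a `te_count_table` from [count_te()].
#' @param method `"within_sample"` or `"between_sample"`.
#' @return numeric matrix of normalized values.
#' @export
normalize_te <- function(t, method = c("within_sample", "between_sample")) {
  method <- match.arg(method)
  stopifnot(inherits(t, "te_count_table"))
  if (method == "within_sample") {
    if (any(t$te_total == 0)) {
      stop("sample(s) with zero TE-mapped reads: ",
           paste(names(t$te_total)[t$te_total == 0], collapse = ", "),
           call. = FALSE)
    }
    sweep(t$counts, 2, t$te_total, "/")
  } else {
    sweep(t$counts, 2, size_factors(t$counts), "/")
  }
}

#' Aggregate TE counts up the repeat hierarchy
#'
#' Sums element-level (repName) counts into family or class totals using the
#' annotation's hierarchy map. For fully unambiguous data this equals direct
#' counting at the coarser level.
#'
#' @param t a `te_count_table` at level `"element"` (or `"copy"`).
#' @param ann the [genome_annotation()] supplying the hierarchy.
#' @param level `"family"` or `"class"`.
#' @return a `te_count_table` at the requested level.
#' @export
aggregate_hierarchy <- function(t, ann, level = c("family", "class")) {
  level <- match.arg(level)
  stopifnot(inherits(t, "te_count_table"))
  if (!t$level %in% c("copy", "element")) {
    stop("aggregate_hierarchy expects a copy- or element-level table",
         call. = FALSE)
  }
  from <- te_level_labels(ann$tes, t$level)
  to <- te_level_labels(ann$tes, level)
  map <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  if (anyDuplicated(map$from)) {
    stop("inconsistent hierarchy: a ", t$level,
         " maps to several ", level, " labels", call. = FALSE)
  }
  idx <- match(rownames(t$counts), map$from)
  if (anyNA(idx)) {
    stop("feature absent from hierarchy map: ",
         rownames(t$counts)[which(is.na(idx))[1]], call. = FALSE)
  }
  out <- t
  out$counts <- rowsum(t$counts, group = map$to[idx])
  out$level <- level
  out
}
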