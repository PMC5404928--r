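#' siRNA sequences used in the knockdown experiments
#'
#' Returns the sense-strand 25-mer siRNA sequences (RNA alphabet) shipped
#' with the package: the MuERV-L-targeting siRNA and the scramble control.
#'
#' @return named character vector of RNA sequences.
#' @export
sirna_sequences <- function() {
  path <- system.file("extdata", "sirna_queries.tsv", package = "retromzt")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "sirna_queries.tsv")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$sequence, d$name)
}

#' Identify full-length internal-element copies by query overlap
#'
#' Locates occurrences of the gag and pol query sequences inside each
#' internal-element copy by local alignment (both strands) and returns the
#' copies whose interval overlaps at least one hit of each query. A hit
#' requires the aligned span to cover at least `min_coverage` of the query
#' at `min_identity` percent identity.
#'
#' @param genome `DNAStringSet` genome.
#' @param internal_tes `GRanges` of internal-element copies (a subset of a
#'   [genome_annotation()]'s `tes`, e.g. one repName).
#' @param gag_query,pol_query DNA sequences (character or `DNAString`).
#' @param min_identity minimum percent identity over the aligned span, as a
#'   fraction (default 0.9).
#' @param min_coverage minimum aligned fraction of the query (default 0.8).
#' @return object of class `full_length_set`: `full_length` (copy ids) and
#'   `evidence` (per-copy hit intervals in genome coordinates, NA when a
#'   query is absent).
#' @export
find_full_length_elements <- function(genome, internal_tes, gag_query,
                                      pol_query, min_identity = 0.9,
                                      min_coverage = 0.8) {
  if (!length(internal_tes)) {
    stop("internal-element annotation subset is empty", call. = FALSE)
  }
  if (!nchar(as.character(gag_query)) || !nchar(as.character(pol_query))) {
    stop("query sequences must be non-empty", call. = FALSE)
  }
  q <- list(gag = Biostrings::DNAString(as.character(gag_query)),
            pol = Biostrings::DNAString(as.character(pol_query)))
  hit_one <- function(copy_seq, query) {
    best <- NULL
    for (pat in list(query, Biostrings::reverseComplement(query))) {
      pa <- Biostrings::pairwiseAlignment(pat, copy_seq, type = "local")
      patr <- Biostrings::pattern(pa)
      cov <- (IRanges::end(patr) - IRanges::start(patr) + 1) / length(query)
      if (cov >= min_coverage && Biostrings::pid(pa) >= 100 * min_identity) {
        subr <- Biostrings::subject(pa)
        best <- c(IRanges::start(subr), IRanges::end(subr))
        break
      }
    }
    best
  }
  rows <- lapply(seq_along(internal_tes), function(i) {
    ch <- as.character(GenomicRanges::seqnames(internal_tes))[i]
    copy_seq <- Biostrings::subseq(genome[[ch]],
                                   GenomicRanges::start(internal_tes)[i],
                                   GenomicRanges::end(internal_tes)[i])
    off <- GenomicRanges::start(internal_tes)[i] - 1L
    g <- hit_one(copy_seq, q$gag)
    p <- hit_one(copy_seq, q$pol)
    data.frame(
      te_id = internal_tes$te_id[i],
      gag_start = if (is.null(g)) NA_integer_ else g[1] + off,
      gag_end = if (is.null(g)) NA_integer_ else g[2] + off,
      pol_start = if (is.null(p)) NA_integer_ else p[1] + off,
      pol_end = if (is.null(p)) NA_integer_ else p[2] + off,
      stringsAsFactors = FALSE)
  })
  evidence <- do.call(rbind, rows)
  full <- evidence$te_id[!is.na(evidence$gag_start) &
                           !is.na(evidence$pol_start)]
  structure(list(full_length = full, evidence = evidence),
            class = "full_length_set")
}

#' @export
print.full_length_set <- function(x, ...) {
  cat("full_length_set:", length(x$full_length), "of", nrow(x$evidence),
      "copies carry both gag and pol hits\n")
  invisible(x)
}

#' Genome-wide siRNA target scan with mismatch stratification
#'
#' Slides a window of siRNA length over both strands of the genome and
#' records every window within Hamming distance `max_mismatch` of the siRNA
#' (U/T normalised; ungapped matching, no indels). Hits are stratified by
#' mismatch count and split into on-target (overlapping a full-length
#' element interval) and off-target. A target copy counts as hit at stratum
#' k when its best overlapping hit has k mismatches.
#'
#' @param sirna RNA (or DNA) sequence of the siRNA.
#' @param genome `DNAStringSet`.
#' @param targets a `full_length_set` from [find_full_length_elements()],
#'   or a `GRanges` of target intervals with a `te_id` column.
#' @param target_ranges `GRanges` of the target copies (required when
#'   `targets` is a `full_length_set`; typically the annotation subset).
#' @param max_mismatch maximum Hamming distance (default 2).
#' @return object of class `sirna_hit_report`: `hits` (data.frame `chrom`,
#'   `start`, `end`, `strand`, `mismatch`, `on_target`), `per_target`
#'   (best mismatch per target copy, NA if unhit), `target_fraction`
#'   (cumulative fraction of targets hit at <= k mismatches, k = 0..max),
#'   `n_off_target`.
#' @export
sirna_scan <- function(sirna, genome, targets, target_ranges = NULL,
                       max_mismatch = 2L) {
  s <- toupper(as.character(sirna))
  if (grepl("[^ACGUT]", s)) {
    stop("siRNA contains non-ACGU characters", call. = FALSE)
  }
  s <- gsub("U", "T", s)
  pat <- Biostrings::DNAString(s)
  if (inherits(targets, "full_length_set")) {
    if (is.null(target_ranges)) {
      stop("target_ranges required with a full_length_set", call. = FALSE)
    }
    tgt <- target_ranges[target_ranges$te_id %in% targets$full_length]
  } else {
    tgt <- targets
  }

  scan_strand <- function(p, strand_label) {
    hits <- Biostrings::vmatchPattern(p, genome, max.mismatch = max_mismatch,
                                      fixed = TRUE)
    out <- list()
    for (ch in names(genome)) {
      ir <- hits[[ch]]
      ir <- ir[IRanges::width(ir) == length(p)]  # ungapped windows only
      if (!length(ir)) next
      mm <- Biostrings::neditStartingAt(p, genome[[ch]],
                                        starting.at = IRanges::start(ir),
                                        with.indels = FALSE)
      out[[ch]] <- data.frame(
        chrom = ch, start = IRanges::start(ir), end = IRanges::end(ir),
        strand = strand_label, mismatch = as.integer(mm),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  fwd <- scan_strand(pat, "+")
  rev <- scan_strand(Biostrings::reverseComplement(pat), "-")
  hits <- rbind(fwd, rev)
  if (is.null(hits)) {
    hits <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       mismatch = integer(), stringsAsFactors = FALSE)
  }
  hits <- hits[hits$mismatch <= max_mismatch, , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL

  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end))
  ov <- GenomicRanges::findOverlaps(gr, tgt, ignore.strand = TRUE)
  hits$on_target <- seq_len(nrow(hits)) %in% S4Vectors::queryHits(ov)
  best <- rep(NA_integer_, length(tgt))
  if (length(ov)) {
    agg <- tapply(hits$mismatch[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), min)
    best[as.integer(names(agg))] <- as.integer(agg)
  }
  per_target <- data.frame(te_id = tgt$te_id, best_mismatch = best,
                           stringsAsFactors = FALSE)
  ks <- 0:max_mismatch
  frac <- vapply(ks, function(k) {
    if (!length(tgt)) return(NA_real_)
    mean(!is.na(best) & best <= k)
  }, numeric(1))
  structure(list(
    hits = hits, per_target = per_target,
    target_fraction = stats::setNames(frac, paste0("le_", ks)),
    n_off_target = sum(!hits$on_target)),
    class = "sirna_hit_report")
}

#' @export
print.sirna_hit_report <- function(x, ...) {
  cat(sprintf(
    "sirna_hit_report: %d hits (%d off-target); target coverage:\n",
    nrow(x$hits), x$n_off_target))
  print(round(x$target_fraction, 4))
  invisible(x)
}
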