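#' Extract split and translocated reads
#'
#' Keeps one genomic alignment per multi-mapped read (seeded), derives each
#' retained read's reference segments from its CIGAR(s), and emits reads
#' with two or more segments: `split_same_chromosome` when an N-containing
#' CIGAR splits the alignment on one chromosome, `translocated` when the
#' retained alignment pieces lie on different chromosomes (the SAM-level
#' realisation of a cross-chromosome junction, carried as supplementary
#' records).
#'
#' @param alns an [alignment_set()].
#' @param seed seed for the one-alignment-per-multi-read choice.
#' @return data.frame of class `split_reads`: one row per segment, columns
#'   `read_id`, `sample`, `kind`, `chrom`, `start`, `end`, `cigar`, `pos`.
#' @export
extract_split_reads <- function(alns, seed = 1L) {
  sub <- alns[select_one_alignment(alns, seed), , drop = FALSE]
  segs <- alignment_segments(sub)
  df <- data.frame(
    read_id = segs$read_id, sample = segs$sample,
    chrom = as.character(GenomicRanges::seqnames(segs)),
    start = GenomicRanges::start(segs), end = GenomicRanges::end(segs),
    cigar = sub$cigar[segs$record], pos = sub$pos[segs$record],
    stringsAsFactors = FALSE)
  key <- paste(df$sample, df$read_id, sep = "\r")
  n_seg <- table(key)
  n_chrom <- tapply(df$chrom, key, function(v) length(unique(v)))
  kind <- ifelse(n_chrom[key] > 1L, "translocated",
                 ifelse(n_seg[key] > 1L, "split_same_chromosome", "plain"))
  df$kind <- as.character(kind)
  df <- df[df$kind != "plain", , drop = FALSE]
  df <- df[order(df$sample, df$read_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("split_reads", "data.frame")
  df
}

#' Call chimeric TE-gene transcripts from split reads
#'
#' A read supports a chimeric transcript iff, among its segments (of at
#' least `min_anchor` bp), exactly one overlaps exactly one gene and no TE,
#' and exactly one other overlaps exactly one TE copy and no gene. Any
#' segment overlapping both a gene and a TE, or two genes, or two TEs,
#' makes the read ambiguous (counted, never called). Gene overlap is
#' evaluated against exons including UTRs by default, since chimeric
#' junctions are splice events onto exonic sequence; `gene_overlap =
#' "gene"` switches to whole gene bodies. Overlap is strand-agnostic.
#'
#' Junction coordinates are oriented by genomic position: the TE-side
#' coordinate is the TE segment boundary adjacent to the gene segment, and
#' conversely for the gene side.
#'
#' @param splits a `split_reads` table from [extract_split_reads()].
#' @param ann a [genome_annotation()].
#' @param min_anchor minimum segment length (bp) considered for overlap
#'   testing (default 8, guarding against spurious 1 bp anchors).
#' @param gene_overlap `"exon"` or `"gene"`.
#' @return object of class `chimeric_calls`: list with `calls` (one row per
#'   calling read: ids, segments, junction coordinates, kind) and `status`
#'   (per split read: `called`, `ambiguous`, `non_chimeric` or
#'   `short_anchor`).
#' @export
call_chimeras <- function(splits, ann, min_anchor = 8L,
                          gene_overlap = c("exon", "gene")) {
  gene_overlap <- match.arg(gene_overlap)
  gene_gr <- if (gene_overlap == "exon") ann$exons else ann$genes
  gene_lab <- gene_gr$gene_id
  te_gr <- ann$tes

  empty_calls <- data.frame(
    read_id = character(), sample = character(), kind = character(),
    gene_id = character(), te_id = character(), te_chrom = character(),
    te_start = integer(), te_end = integer(), gene_chrom = character(),
    gene_start = integer(), gene_end = integer(),
    junction_te = integer(), junction_gene = integer(),
    stringsAsFactors = FALSE)
  if (!nrow(splits)) {
    return(structure(list(calls = empty_calls,
                          status = data.frame(read_id = character(),
                                              sample = character(),
                                              status = character())),
                     class = "chimeric_calls"))
  }

  key <- paste(splits$sample, splits$read_id, sep = "\r")
  long <- splits$end - splits$start + 1L >= min_anchor
  segs <- GenomicRanges::GRanges(splits$chrom,
                                 IRanges::IRanges(splits$start, splits$end))
  gh <- GenomicRanges::findOverlaps(segs, gene_gr, ignore.strand = TRUE)
  th <- GenomicRanges::findOverlaps(segs, te_gr, ignore.strand = TRUE)
  gene_sets <- tapply(gene_lab[S4Vectors::subjectHits(gh)],
                      S4Vectors::queryHits(gh), function(v) unique(v),
                      simplify = FALSE)
  te_sets <- tapply(te_gr$te_id[S4Vectors::subjectHits(th)],
                    S4Vectors::queryHits(th), function(v) unique(v),
                    simplify = FALSE)
  n_gene <- integer(nrow(splits))
  n_te <- integer(nrow(splits))
  n_gene[as.integer(names(gene_sets))] <- lengths(gene_sets)
  n_te[as.integer(names(te_sets))] <- lengths(te_sets)
  n_gene[!long] <- 0L
  n_te[!long] <- 0L

  calls <- list()
  status <- list()
  rows_by_read <- split(seq_along(key), key)
  for (rows in rows_by_read) {
    use <- rows[long[rows]]
    st <- if (length(use) < 2L) {
      "short_anchor"
    } else if (any(n_gene[use] > 0 & n_te[use] > 0) ||
               any(n_gene[use] > 1) || any(n_te[use] > 1)) {
      "ambiguous"
    } else {
      g_seg <- use[n_gene[use] == 1 & n_te[use] == 0]
      t_seg <- use[n_te[use] == 1 & n_gene[use] == 0]
      if (length(g_seg) == 1L && length(t_seg) == 1L) "called"
      else "non_chimeric"
    }
    status[[length(status) + 1L]] <- data.frame(
      read_id = splits$read_id[rows[1]], sample = splits$sample[rows[1]],
      status = st, stringsAsFactors = FALSE)
    if (st != "called") next
    te_row <- t_seg
    g_row <- g_seg
    same_chrom <- splits$chrom[te_row] == splits$chrom[g_row]
    if (same_chrom && splits$start[te_row] > splits$start[g_row]) {
      j_te <- splits$start[te_row]
      j_gene <- splits$end[g_row]
    } else {
      j_te <- splits$end[te_row]
      j_gene <- splits$start[g_row]
    }
    calls[[length(calls) + 1L]] <- data.frame(
      read_id = splits$read_id[rows[1]], sample = splits$sample[rows[1]],
      kind = splits$kind[rows[1]],
      gene_id = gene_sets[[as.character(g_row)]],
      te_id = te_sets[[as.character(te_row)]],
      te_chrom = splits$chrom[te_row], te_start = splits$start[te_row],
      te_end = splits$end[te_row], gene_chrom = splits$chrom[g_row],
      gene_start = splits$start[g_row], gene_end = splits$end[g_row],
      junction_te = j_te, junction_gene = j_gene,
      stringsAsFactors = FALSE)
  }
  structure(list(
    calls = if (length(calls)) do.call(rbind, calls) else empty_calls,
    status = do.call(rbind, status)),
    class = "chimeric_calls")
}

#' @export
print.chimeric_calls <- function(x, ...) {
  cat("chimeric_calls:", nrow(x$calls), "calling reads;",
      "status:", paste(sprintf("%s=%d", names(table(x$status$status)),
                               table(x$status$status)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tabulate read support per chimeric junction
#'
#' Groups calls by (TE copy, gene, exact junction coordinates) and reports
#' supporting-read counts per sample; with sample metadata, per
#' stage-by-genotype group totals are attached.
#'
#' @param calls a `chimeric_calls` object (or its `calls` data.frame).
#' @param samples optional sample sheet (`sample`, `stage`, `genotype`).
#' @return data.frame: one row per junction and sample with `support`;
#'   attribute `"group_support"` holds the per-group totals when metadata
#'   is supplied.
#' @export
quantify_chimeras <- function(calls, samples = NULL) {
  df <- if (inherits(calls, "chimeric_calls")) calls$calls else calls
  if (!nrow(df)) {
    return(data.frame(te_id = character(), gene_id = character(),
                      junction_te = integer(), junction_gene = integer(),
                      sample = character(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(support = rep(1L, nrow(df))),
    by = df[, c("te_id", "gene_id", "junction_te", "junction_gene",
                "sample")], FUN = sum)
  agg <- agg[order(agg$te_id, agg$gene_id, agg$sample), , drop = FALSE]
  rownames(agg) <- NULL
  if (!is.null(samples)) {
    m <- merge(agg, samples[, c("sample", "stage", "genotype")],
               by = "sample")
    grp <- stats::aggregate(
      list(support = m$support),
      by = m[, c("te_id", "gene_id", "junction_te", "junction_gene",
                 "stage", "genotype")], FUN = sum)
    attr(agg, "group_support") <- grp
  }
  agg
}
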