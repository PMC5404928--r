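#' Genome annotation container
#'
#' Bundles gene models and RepeatMasker-style TE records for one genome.
#' Coordinates are held as `GRanges` (1-based, closed), the standard R
#' representation; BED input is converted at the boundary.
#'
#' @param genes `GRanges` with metadata columns `gene_id` and `tss`
#'   (genomic coordinate of the transcription start site, strand-aware).
#' @param exons `GRanges` with metadata column `gene_id`; exons include UTRs
#'   and must lie within their gene's interval.
#' @param tes `GRanges` with metadata columns `te_id`, `repName`, `repFamily`
#'   and `repClass` (the three-level RepeatMasker hierarchy).
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes`, `exons`, `tes`.
#' @export
genome_annotation <- function(genes, exons, tes) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRanges"), is(tes, "GRanges"))
  need <- function(gr, cols, what) {
    miss <- setdiff(cols, colnames(S4Vectors::mcols(gr)))
    if (length(miss)) {
      stop(sprintf("%s records lack required column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(genes, c("gene_id", "tss"), "gene")
  need(exons, "gene_id", "exon")
  need(tes, c("te_id", "repName", "repFamily", "repClass"), "TE")
  for (col in c("repName", "repFamily", "repClass")) {
    bad <- which(is.na(S4Vectors::mcols(tes)[[col]]) |
                   S4Vectors::mcols(tes)[[col]] == "")
    if (length(bad)) {
      stop(sprintf("TE record %d: missing attribute %s", bad[1], col),
           call. = FALSE)
    }
  }
  # exons must sit inside their gene's interval
  gi <- match(exons$gene_id, genes$gene_id)
  if (anyNA(gi)) {
    stop("exon references unknown gene_id: ",
         exons$gene_id[which(is.na(gi))[1]], call. = FALSE)
  }
  ok <- as.character(GenomicRanges::seqnames(exons)) ==
    as.character(GenomicRanges::seqnames(genes))[gi] &
    GenomicRanges::start(exons) >= GenomicRanges::start(genes)[gi] &
    GenomicRanges::end(exons) <= GenomicRanges::end(genes)[gi]
  if (!all(ok)) {
    stop("exon outside its gene interval (gene ",
         exons$gene_id[which(!ok)[1]], ")", call. = FALSE)
  }
  structure(list(genes = genes, exons = exons, tes = tes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      length(x$genes), "genes,",
      length(x$exons), "exons,",
      length(x$tes), "TE copies",
      sprintf("(%d element names, %d families, %d classes)\n",
              length(unique(x$tes$repName)),
              length(unique(x$tes$repFamily)),
              length(unique(x$tes$repClass))))
  invisible(x)
}

# --- light GTF machinery -----------------------------------------------------
# A minimal tab/attribute parser is used (instead of a full GFF stack) so that
# malformed records can be reported with their literal line number, which the
# package's error contract requires.

parse_gtf_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) stop("no records in GTF file: ", path, call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop(sprintf("malformed GTF record at line %d of %s (found %d fields)",
                 idx[which(nf < 9)[1]], path, min(nf)), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 1 | end < start)
  if (length(bad)) {
    stop(sprintf("malformed coordinates at line %d of %s", idx[bad[1]], path),
         call. = FALSE)
  }
  list(chrom = m[, 1], feature = m[, 3], start = start, end = end,
       strand = m[, 7], attr = m[, 9], line = idx)
}

gtf_attr <- function(attr_strings, key) {
  pat <- paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regmatches(attr_strings, regexec(pat, attr_strings))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

fmt_attrs <- function(...) {
  kv <- list(...)
  paste(vapply(names(kv), function(k) sprintf('%s "%s";', k, kv[[k]]),
               character(1)), collapse = " ")
}

#' Read gene models from GTF
#'
#' Accepts GTF with `gene` and `exon` feature rows (exons including UTRs).
#' If no explicit `gene` rows are present, gene intervals are taken as the
#' span of each gene's exons.
#'
#' @param path GTF file path (1-based, closed coordinates).
#' @return A list with `GRanges` elements `genes` (with `gene_id`, `tss`)
#'   and `exons` (with `gene_id`).
#' @export
read_gene_gtf <- function(path) {
  g <- parse_gtf_lines(path)
  gene_id <- gtf_attr(g$attr, "gene_id")
  if (anyNA(gene_id)) {
    stop(sprintf("record lacking gene_id at line %d of %s",
                 g$line[which(is.na(gene_id))[1]], path), call. = FALSE)
  }
  is_exon <- g$feature == "exon"
  exons <- GenomicRanges::GRanges(
    g$chrom[is_exon],
    IRanges::IRanges(g$start[is_exon], g$end[is_exon]),
    strand = g$strand[is_exon], gene_id = gene_id[is_exon])
  is_gene <- g$feature == "gene"
  if (any(is_gene)) {
    genes <- GenomicRanges::GRanges(
      g$chrom[is_gene],
      IRanges::IRanges(g$start[is_gene], g$end[is_gene]),
      strand = g$strand[is_gene], gene_id = gene_id[is_gene])
  } else {
    st <- tapply(GenomicRanges::start(exons), exons$gene_id, min)
    en <- tapply(GenomicRanges::end(exons), exons$gene_id, max)
    ch <- tapply(as.character(GenomicRanges::seqnames(exons)),
                 exons$gene_id, `[`, 1)
    sr <- tapply(as.character(GenomicRanges::strand(exons)),
                 exons$gene_id, `[`, 1)
    ids <- names(st)
    genes <- GenomicRanges::GRanges(unname(ch[ids]),
                                    IRanges::IRanges(unname(st[ids]),
                                                     unname(en[ids])),
                                    strand = unname(sr[ids]),
                                    gene_id = ids)
  }
  genes$tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                      GenomicRanges::end(genes),
                      GenomicRanges::start(genes))
  list(genes = genes, exons = exons)
}

#' Read RepeatMasker-style TE annotation (GTF or BED)
#'
#' GTF records must carry `repName`, `repFamily` and `repClass` attributes
#' (`transcript_id`, when present, names the individual copy). BED input
#' (0-based half-open) must have six standard columns plus `repFamily` and
#' `repClass` as columns 7-8, with the BED `name` field holding `repName`.
#'
#' @param path file path; format chosen by `.bed` extension.
#' @return `GRanges` with `te_id`, `repName`, `repFamily`, `repClass`.
#' @export
read_te_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    return(read_te_bed(path))
  }
  g <- parse_gtf_lines(path)
  vals <- lapply(c(repName = "repName", repFamily = "repFamily",
                   repClass = "repClass"), gtf_attr, attr_strings = g$attr)
  for (key in names(vals)) {
    bad <- which(is.na(vals[[key]]))
    if (length(bad)) {
      stop(sprintf("TE record missing attribute %s at line %d of %s",
                   key, g$line[bad[1]], path), call. = FALSE)
    }
  }
  te_id <- gtf_attr(g$attr, "transcript_id")
  auto <- sprintf("%s:%d-%d", g$chrom, g$start, g$end)
  te_id <- ifelse(is.na(te_id), auto, te_id)
  GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    te_id = te_id, repName = vals$repName, repFamily = vals$repFamily,
    repClass = vals$repClass)
}

read_te_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 8) {
    stop("TE BED needs 8 columns (chrom start end repName score strand ",
         "repFamily repClass); found ", ncol(d), call. = FALSE)
  }
  GenomicRanges::GRanges(
    d[[1]], IRanges::IRanges(d[[2]] + 1L, d[[3]]), strand = d[[6]],
    te_id = sprintf("%s:%d-%d", d[[1]], d[[2]] + 1L, d[[3]]),
    repName = d[[4]], repFamily = d[[7]], repClass = d[[8]])
}

#' Read a full genome annotation (genes + TEs)
#'
#' @param gene_path gene-model GTF.
#' @param te_path TE annotation GTF or BED.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(gene_path, te_path) {
  g <- read_gene_gtf(gene_path)
  genome_annotation(g$genes, g$exons, read_te_annotation(te_path))
}

#' Write gene models as GTF
#'
#' @param genes,exons `GRanges` as held in a [genome_annotation()].
#' @param path output file.
#' @export
write_gene_gtf <- function(genes, exons, path) {
  fmt <- function(gr, feature) {
    sprintf("%s\tretromzt\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(GenomicRanges::seqnames(gr)), feature,
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            as.character(GenomicRanges::strand(gr)),
            vapply(gr$gene_id, function(id) fmt_attrs(gene_id = id),
                   character(1)))
  }
  writeLines(c(fmt(genes, "gene"), fmt(exons, "exon")), path)
  invisible(path)
}

#' Write TE records as RepeatMasker-style GTF
#'
#' @param tes `GRanges` with `te_id`, `repName`, `repFamily`, `repClass`.
#' @param path output file.
#' @export
write_te_gtf <- function(tes, path) {
  lines <- sprintf(
    "%s\tRepeatMasker\texon\t%d\t%d\t.\t%s\t.\t%s",
    as.character(GenomicRanges::seqnames(tes)),
    GenomicRanges::start(tes), GenomicRanges::end(tes),
    as.character(GenomicRanges::strand(tes)),
    mapply(function(nm, id, fam, cls) {
      fmt_attrs(gene_id = nm, transcript_id = id, repName = nm,
                repFamily = fam, repClass = cls)
    }, tes$repName, tes$te_id, tes$repFamily, tes$repClass))
  writeLines(lines, path)
  invisible(path)
}
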