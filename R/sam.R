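#' Alignment set
#'
#' A data.frame-backed container for single-end read alignments: one row per
#' SAM record. Multi-mapped reads appear as several rows sharing `read_id`
#' within a sample (the non-primary alternatives flagged `secondary`);
#' translocated reads carry extra `supplementary` rows for the distal piece.
#'
#' @param df data.frame with columns `read_id`, `sample`, `flag`, `chrom`,
#'   `pos` (1-based leftmost), `cigar`, `nh` (number of genomic alignments).
#' @return The validated data.frame with class `alignment_set`; helper
#'   columns `secondary` and `supplementary` are derived from `flag`.
#' @export
alignment_set <- function(df) {
  need <- c("read_id", "sample", "flag", "chrom", "pos", "cigar", "nh")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("alignment_set lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$nh < 1)) stop("multiplicity (nh) must be >= 1", call. = FALSE)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  if (any(ref_w < 1)) {
    stop("CIGAR consuming no reference base at record ",
         which(ref_w < 1)[1], call. = FALSE)
  }
  df$secondary <- bitwAnd(df$flag, 256L) > 0L
  df$supplementary <- bitwAnd(df$flag, 2048L) > 0L
  class(df) <- c("alignment_set", "data.frame")
  df
}

#' Read a minimal single-end SAM file
#'
#' Parses mandatory fields plus the `NH` tag (number of genomic alignments,
#' defaulting to 1 when absent). Unmapped records (flag 0x4) are dropped.
#'
#' @param path SAM file.
#' @param sample sample identifier attached to every record.
#' @return An [alignment_set()].
#' @export
read_sam <- function(path, sample) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(alignment_set(data.frame(
      read_id = character(), sample = character(), flag = integer(),
      chrom = character(), pos = integer(), cigar = character(),
      nh = integer(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    stop("malformed SAM record (fewer than 11 fields) in ", path,
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else 1L
  }, integer(1))
  df <- data.frame(
    read_id = get(1), sample = sample, flag = as.integer(get(2)),
    chrom = get(3), pos = as.integer(get(4)), cigar = get(6), nh = nh,
    stringsAsFactors = FALSE)
  df <- df[bitwAnd(df$flag, 4L) == 0L, , drop = FALSE]
  alignment_set(df)
}

#' Write an alignment set as SAM
#'
#' Minimal dialect: header (`@HD`, `@SQ`), mandatory fields with `*`
#' sequence/quality, and the `NH` optional tag for multiplicity.
#'
#' @param alns an [alignment_set()] (one sample).
#' @param path output file.
#' @param seqlengths named integer vector of contig lengths for `@SQ` lines.
#' @export
write_sam <- function(alns, path, seqlengths) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)))
  records <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
                     alns$read_id, alns$flag, alns$chrom, alns$pos,
                     alns$cigar, alns$nh)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Genomic segments of one aligned record
#'
#' Computes the maximal reference-consuming runs of a CIGAR: M/D/=/X consume
#' reference, N splits segments, and I/S/H consume none. A spliced CIGAR such
#' as `20M1000N30M` at position 101 yields segments 101-120 and 1121-1150.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based leftmost mapping position.
#' @param chrom chromosome name.
#' @return `GRanges` of reference segments, in genomic order.
#' @export
segment_coordinates <- function(cigar, pos, chrom) {
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)[[1]]
  GenomicRanges::GRanges(chrom, rl)
}

# All reference segments for every record of an alignment set, with the
# originating row index carried in mcols.
alignment_segments <- function(alns) {
  if (!nrow(alns)) {
    gr <- GenomicRanges::GRanges()
    gr$record <- integer()
    gr$read_id <- character()
    gr$sample <- character()
    return(gr)
  }
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    alns$cigar, pos = alns$pos, drop.D.ranges = FALSE)
  n <- lengths(rl)
  gr <- GenomicRanges::GRanges(rep(alns$chrom, n), unlist(rl))
  gr$record <- rep(seq_len(nrow(alns)), n)
  gr$read_id <- rep(alns$read_id, n)
  gr$sample <- rep(alns$sample, n)
  gr
}

# Retain one genomic alignment per read: unique reads keep their primary
# record (plus supplementary pieces); for multi-mapped reads one alternative
# (primary or secondary, uniformly at random, seeded) is kept. Returns the
# row indices retained.
select_one_alignment <- function(alns, seed) {
  key <- paste(alns$sample, alns$read_id, sep = "\r")
  keep <- logical(nrow(alns))
  alt_rows <- which(!alns$supplementary)
  grp <- split(alt_rows, key[alt_rows])
  withr::with_seed(seed, {
    picked <- vapply(grp, function(rows) {
      if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
    }, integer(1))
  })
  keep[picked] <- TRUE
  # supplementary pieces travel with a retained primary alignment
  supp <- which(alns$supplementary)
  if (length(supp)) {
    prim_kept <- keep & !alns$secondary
    kept_keys <- unique(key[prim_kept])
    keep[supp] <- key[supp] %in% kept_keys
  }
  keep
}
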