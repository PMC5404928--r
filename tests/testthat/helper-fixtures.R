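# Hand-built micro fixtures shared across tests.

# two genes and five TE copies spanning the three-level hierarchy
tiny_annotation <- function() {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1"),
    IRanges::IRanges(c(10001, 30001), c(12000, 32000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  genes$tss <- c(10001, 32000)
  exons <- GenomicRanges::GRanges(
    rep(c("chr1", "chr1"), each = 2),
    IRanges::IRanges(c(10001, 11501, 30001, 31501),
                     c(10400, 12000, 30400, 32000)),
    strand = rep(c("+", "-"), each = 2),
    gene_id = rep(c("gA", "gB"), each = 2))
  tes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2", "chr2"),
    IRanges::IRanges(c(1001, 2001, 5001, 1001, 4001),
                     c(1500, 2500, 5600, 3000, 4200)),
    strand = c("+", "-", "+", "+", "-"),
    te_id = c("MERVL-int_1", "MERVL-int_2", "MT2_1", "L1_1", "B1_1"),
    repName = c("MERVL-int", "MERVL-int", "MT2", "L1Md", "B1"),
    repFamily = c("ERVL", "ERVL", "ERVL", "L1", "Alu"),
    repClass = c("LTR", "LTR", "LTR", "LINE", "SINE"))
  orr1 <- GenomicRanges::GRanges(
    "chr2", IRanges::IRanges(6001, 6600), strand = "+", te_id = "ORR1_1",
    repName = "ORR1", repFamily = "ERVL-MaLR", repClass = "LTR")
  tes <- c(tes, orr1)
  retromzt::genome_annotation(genes, exons, tes)
}

# quick alignment rows with sensible defaults
aln_row <- function(read_id, chrom, pos, cigar = "51M", flag = 0L, nh = 1L,
                    sample = "s1") {
  data.frame(read_id = read_id, sample = sample, flag = flag, chrom = chrom,
             pos = as.integer(pos), cigar = cigar, nh = as.integer(nh),
             stringsAsFactors = FALSE)
}

make_alns <- function(...) {
  retromzt::alignment_set(do.call(rbind, list(...)))
}

# a multi-mapped read hitting the given (chrom, pos) alignment list
multi_read <- function(read_id, chroms, positions, sample = "s1",
                       cigar = "51M") {
  k <- length(positions)
  data.frame(read_id = read_id, sample = sample,
             flag = c(0L, rep(256L, k - 1L)), chrom = chroms,
             pos = as.integer(positions), cigar = cigar, nh = k,
             stringsAsFactors = FALSE)
}

# compact simulation settings used where genome content does not matter
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    chrom_length = 150000L,
    n_genes = 40L,
    te_elements = data.frame(
      rep_name = c("MERVL-like-int", "MT2-like", "ORR1-like", "L1-like",
                   "B1-like"),
      rep_family = c("ERVL", "ERVL", "ERVL-MaLR", "L1", "Alu"),
      rep_class = c("LTR", "LTR", "LTR", "LINE", "SINE"),
      n_copies = c(6L, 5L, 4L, 5L, 5L),
      copy_length = c(1200L, 400L, 500L, 900L, 200L),
      stringsAsFactors = FALSE),
    n_full_length_te = 3L,
    samples_per_group = 2L,
    mean_library_size = 1500L,
    n_chimeric_junctions = 4L)
  do.call(retromzt::simulation_config,
          utils::modifyList(defaults, list(...)))
}
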