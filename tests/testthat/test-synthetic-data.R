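test_that("identical configuration and seed give byte-identical outputs", {
  cfg <- small_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference(generate_reference(cfg), d1)
  write_reference(generate_reference(cfg), d2)
  for (f in c("genome.fa", "genes.gtf", "tes.gtf", "gene_truth.tsv",
              "junctions.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ref <- generate_reference(cfg)
  expect_identical(simulate_counts(cfg, ref$truth)$counts,
                   simulate_counts(cfg, ref$truth)$counts)
  expect_identical(simulate_alignments(cfg, ref$truth)$alignments,
                   simulate_alignments(cfg, ref$truth)$alignments)
  # a different seed changes the genome
  other <- generate_reference(small_config(seed = 6))
  expect_false(identical(as.character(other$genome[[1]]),
                         as.character(ref$genome[[1]])))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(class_proportions = c(EE = 1)),
               "nine dynamics classes")
  p <- c(EE = 0.5, ED = 0.5, EU = 0.1, DE = 0, DD = 0, DU = 0,
         UE = 0, UD = 0, UU = 0)
  expect_error(simulation_config(class_proportions = p), "sum to 1")
  expect_error(simulation_config(multi_map_fraction = 1.2), "fractions")
  expect_error(simulation_config(n_genes = -1L), "counts")
  expect_error(generate_reference(small_config(chrom_length = 20000L)),
               "impossible geometry")
  expect_error(generate_reference(small_config(chrom_length = 20000L)),
               "chrom_length")
})

test_that("ground truth reflects the planted construction", {
  cfg <- small_config(seed = 9)
  ref <- generate_reference(cfg)
  truth <- ref$truth
  expect_length(truth$full_length, cfg$n_full_length_te)
  # every full-length copy carries both query subsequences verbatim
  tes <- ref$annotation$tes
  for (id in truth$full_length) {
    te <- tes[tes$te_id == id]
    s <- as.character(Biostrings::subseq(
      ref$genome[[as.character(GenomicRanges::seqnames(te))]],
      GenomicRanges::start(te), GenomicRanges::end(te)))
    expect_true(grepl(truth$gag_query, s, fixed = TRUE))
    expect_true(grepl(truth$pol_query, s, fixed = TRUE))
  }
  # truncated internal copies lack the pol query
  internal <- tes$te_id[tes$repName == cfg$internal_element]
  for (id in setdiff(internal, truth$full_length)) {
    te <- tes[tes$te_id == id]
    s <- as.character(Biostrings::subseq(
      ref$genome[[as.character(GenomicRanges::seqnames(te))]],
      GenomicRanges::start(te), GenomicRanges::end(te)))
    expect_false(grepl(truth$pol_query, s, fixed = TRUE))
  }
  # class labels cover the configured proportions
  expect_equal(length(truth$gene_classes), cfg$n_genes)
  expect_setequal(unique(truth$gene_classes),
                  names(cfg$class_proportions)[cfg$class_proportions > 0])
  # at least two element names share a family in the annotation
  fam <- table(unique(data.frame(tes$repName, tes$repFamily))[, 2])
  expect_gte(max(fam), 2)
})

test_that("simulated counts follow the planted class means and KO effects", {
  cfg <- small_config(seed = 2, samples_per_group = 60L, dispersion = 0)
  ref <- generate_reference(cfg)
  cm <- simulate_counts(cfg, ref$truth)
  truth <- ref$truth
  sheet <- cm$samples
  grp_mean <- function(gene, stage, genotype) {
    cols <- sheet$sample[sheet$stage == stage & sheet$genotype == genotype]
    mean(cm$counts[gene, cols])
  }
  eu <- names(truth$gene_classes)[truth$gene_classes == "EU"]
  ee <- names(truth$gene_classes)[truth$gene_classes == "EE"]
  ed <- names(truth$gene_classes)[truth$gene_classes == "ED"]
  # EU: 2-cell / 1-cell WT ratio approaches the planted fold
  g <- eu[1]
  expect_equal(grp_mean(g, "2-cell", "WT") / grp_mean(g, "1-cell", "WT"),
               cfg$effect_size, tolerance = 0.15)
  # EE: stage means equal by construction
  g <- ee[1]
  expect_equal(grp_mean(g, "oocyte", "WT") / grp_mean(g, "2-cell", "WT"), 1,
               tolerance = 0.15)
  # ED: oocyte and 1-cell equal, 2-cell reduced by the fold
  g <- ed[1]
  expect_equal(grp_mean(g, "oocyte", "WT") / grp_mean(g, "1-cell", "WT"), 1,
               tolerance = 0.15)
  expect_equal(grp_mean(g, "1-cell", "WT") / grp_mean(g, "2-cell", "WT"),
               cfg$effect_size, tolerance = 0.15)
  # KO dampening on affected zygotic genes
  aff_eu <- intersect(eu, truth$ko_affected)
  g <- aff_eu[1]
  expect_equal(grp_mean(g, "2-cell", "KO") / grp_mean(g, "2-cell", "WT"),
               cfg$ko_dampening, tolerance = 0.2)
  # affected maternal-decay genes retain transcripts in KO
  aff_ed <- intersect(ed, truth$ko_affected)
  g <- aff_ed[1]
  expect_gt(grp_mean(g, "2-cell", "KO") / grp_mean(g, "2-cell", "WT"), 4)
})

test_that("alignment simulation honours multiplicity and read-name encoding", {
  cfg <- small_config(seed = 4, multi_map_fraction = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_alignments(cfg, ref$truth)
  expect_true(all(sim$alignments$nh == 1L))
  # with multi-mapping on, every nh > 1 read has exactly nh records
  cfg2 <- small_config(seed = 4, multi_map_fraction = 0.5)
  ref2 <- generate_reference(cfg2)
  sim2 <- simulate_alignments(cfg2, ref2$truth)
  multi <- sim2$alignments[sim2$alignments$nh > 1, ]
  recs <- table(paste(multi$sample, multi$read_id))
  expect_true(all(recs == multi$nh[match(names(recs),
                                         paste(multi$sample,
                                               multi$read_id))]))
  # read names encode the ground-truth origin
  expect_true(all(vapply(strsplit(sim2$read_truth$read_id, "|",
                                  fixed = TRUE), length, integer(1)) == 4))
  expect_identical(
    vapply(strsplit(sim2$read_truth$read_id, "|", fixed = TRUE), `[`,
           character(1), 4),
    sim2$read_truth$origin)
  # every planted junction has at least one supporting simulated read
  supported <- unique(sim2$read_truth$origin[
    sim2$read_truth$type %in% c("split", "trl")])
  expect_setequal(supported, ref2$truth$junctions$junction_id)
})

test_that("a high-mitochondria sample fails the downstream QC filter", {
  cfg <- small_config(seed = 8, mean_library_size = 4000L)
  ref <- generate_reference(cfg)
  sheet <- retromzt:::sim_sample_sheet(cfg)
  mito <- stats::setNames(rep(0.01, nrow(sheet)), sheet$sample)
  mito[1] <- 0.12
  cfg$mito_read_fraction <- mito
  sim <- simulate_alignments(cfg, ref$truth)
  qc <- qc_filter(compute_qc(sim$alignments, ref$annotation),
                  exon_min = 100)  # exon depth rescaled to the toy library
  bad <- qc[qc$sample == sheet$sample[1], ]
  good <- qc[qc$sample != sheet$sample[1], ]
  expect_false(bad$pass)
  expect_true(all(good$pass))
})

test_that("noiseless unique counting recovers planted per-copy read numbers", {
  cfg <- small_config(seed = 12, multi_map_fraction = 0,
                      n_chimeric_junctions = 0L, mito_read_fraction = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_alignments(cfg, ref$truth)
  tab <- count_te(sim$alignments, ref$annotation, mode = "unique_only",
                  level = "copy")
  truth_te <- sim$read_truth[sim$read_truth$origin %in%
                               ref$annotation$tes$te_id, ]
  expected <- table(factor(truth_te$origin, levels = rownames(tab$counts)),
                    factor(truth_te$sample, levels = colnames(tab$counts)))
  expect_equal(unclass(tab$counts), unclass(expected),
               ignore_attr = TRUE)
})
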