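test_that("unique counting applies the exactly-one-feature rule", {
  ann <- tiny_annotation()
  alns <- make_alns(
    aln_row("r1", "chr1", 1010),   # inside MERVL-int_1
    aln_row("r2", "chr1", 1100),
    aln_row("r3", "chr1", 1200),
    aln_row("r4", "chr1", 8000))   # outside all TEs
  tab <- count_te(alns, ann, mode = "unique_only", level = "copy")
  expect_equal(tab$counts["MERVL-int_1", "s1"], 3L)
  expect_equal(unname(tab$te_total["s1"]), 3L)
  expect_equal(unname(tab$mapped_total["s1"]), 4L)
  expect_equal(unname(tab$non_te["s1"]), 1L)

  # a read spanning two distinct copies is discarded as ambiguous at copy
  # level; at element level the two MERVL-int copies share a label, so a
  # spliced read touching both is assigned
  spl <- make_alns(aln_row("r5", "chr1", 1480, cigar = "21M500N30M"))
  t_copy <- count_te(spl, ann, mode = "unique_only", level = "copy")
  expect_equal(unname(t_copy$ambiguous["s1"]), 1L)
  expect_equal(sum(t_copy$counts), 0L)
  t_el <- count_te(spl, ann, mode = "unique_only", level = "element")
  expect_equal(t_el$counts["MERVL-int", "s1"], 1L)

  expect_error(count_te(alns, ann, mode = "nope"), "arg")
})

test_that("counting modes treat multi-mapped reads as documented", {
  ann <- tiny_annotation()
  alns <- make_alns(
    aln_row("u1", "chr1", 1010),
    multi_read("m1", c("chr1", "chr1"), c(1010, 2010)),   # two MERVL copies
    multi_read("m2", c("chr1", "chr2"), c(5010, 1100)))   # MT2 vs L1
  uo <- count_te(alns, ann, mode = "unique_only", level = "element")
  expect_equal(sum(uo$counts), 1L)
  expect_equal(unname(uo$mapped_total["s1"]), 1L)

  # one-random keeps one alignment per read; m1 lands in MERVL-int either
  # way, m2 in MT2 or L1Md depending on the draw
  r <- count_te(alns, ann, mode = "unique_plus_one_random",
                level = "element", seed = 1)
  expect_equal(unname(r$mapped_total["s1"]), 3L)
  expect_equal(sum(r$counts), 3L)
  expect_equal(r$counts["MERVL-int", "s1"], 2L)
  expect_identical(r$counts,
                   count_te(alns, ann, mode = "unique_plus_one_random",
                            level = "element", seed = 1)$counts)

  # all-alignments counts each alignment once
  aa <- count_te(alns, ann, mode = "all_alignments", level = "element")
  expect_equal(unname(aa$mapped_total["s1"]), 5L)
  expect_equal(aa$counts["MERVL-int", "s1"], 3L)
  expect_equal(aa$counts["MT2", "s1"], 1L)
  expect_equal(aa$counts["L1Md", "s1"], 1L)
})

test_that("random alignment selection is uniform across seeds", {
  ann <- tiny_annotation()
  # one read multi-mapping to k = 2 copies: expected count 1/2 each
  alns <- make_alns(multi_read("m", c("chr1", "chr1"), c(1010, 2010)))
  picks <- vapply(1:200, function(s) {
    t <- count_te(alns, ann, mode = "unique_plus_one_random",
                  level = "copy", seed = s)
    t$counts["MERVL-int_1", "s1"]
  }, integer(1))
  # binomial(200, 1/2): 3.5 sigma band around 100
  expect_gt(sum(picks), 100 - 25)
  expect_lt(sum(picks), 100 + 25)
})

test_that("ambiguity report follows hierarchy nesting and exact fractions", {
  ann <- tiny_annotation()
  # MERVL-int vs MT2: same family and class, different element
  fam_ok <- multi_read("f1", c("chr1", "chr1"), c(1010, 5010))
  # MT2 (LTR) vs L1 (LINE): ambiguous at every level
  cls_bad <- multi_read("c1", c("chr1", "chr2"), c(5010, 1100))
  r <- assignment_ambiguity(make_alns(fam_ok, cls_bad), ann)
  expect_false(r$empty)
  expect_equal(unname(r$proportion["element"]), 0)
  expect_equal(unname(r$proportion["family"]), 0.5)
  expect_equal(unname(r$proportion["class"]), 0.5)

  # no multi-mapped TE reads: report empty, not zero
  e <- assignment_ambiguity(make_alns(aln_row("u", "chr1", 1010)), ann)
  expect_true(e$empty)
  expect_true(all(is.na(e$proportion)))

  # reads whose alignments fall outside TEs are not part of the denominator
  part <- assignment_ambiguity(
    make_alns(fam_ok, multi_read("x", c("chr1", "chr1"), c(8000, 9000))),
    ann)
  expect_equal(part$n_reads, 1L)
  expect_equal(unname(part$proportion["family"]), 1)
})

test_that("hierarchy proportions are monotone on simulated data", {
  cfg <- small_config(seed = 21, multi_map_fraction = 0.6)
  ref <- generate_reference(cfg)
  sim <- simulate_alignments(cfg, ref$truth)
  r <- assignment_ambiguity(sim$alignments, ref$annotation)
  expect_gte(r$proportion["class"], r$proportion["family"])
  expect_gte(r$proportion["family"], r$proportion["element"])
})

test_that("TE fraction and within-sample normalization behave as ratios", {
  ann <- tiny_annotation()
  alns <- make_alns(
    aln_row("r1", "chr1", 1010), aln_row("r2", "chr1", 2010),
    aln_row("r3", "chr1", 5010), aln_row("r4", "chr1", 8000),
    aln_row("r5", "chr2", 9000))
  expect_equal(unname(te_fraction(alns, ann)["s1"]), 3 / 5)

  tab <- count_te(alns, ann, mode = "unique_only", level = "copy")
  w <- normalize_te(tab, "within_sample")
  expect_equal(colSums(w), c(s1 = 1))
  expect_equal(w["MERVL-int_1", "s1"], 1 / 3)
  # tripling a sample's reads leaves within-sample values unchanged
  tripled <- make_alns(do.call(rbind, lapply(1:3, function(i) {
    df <- as.data.frame(alns)[, 1:7]
    df$read_id <- paste0(df$read_id, "_", i)
    df
  })))
  tab3 <- count_te(tripled, ann, mode = "unique_only", level = "copy")
  expect_equal(normalize_te(tab3, "within_sample"), w)

  none <- make_alns(aln_row("r", "chr1", 8000))
  expect_error(normalize_te(count_te(none, ann, mode = "unique_only",
                                     level = "copy"), "within_sample"),
               "zero TE-mapped")
  expect_error(te_fraction(alns[0, ], ann), "mapped reads")
})

test_that("hierarchy aggregation sums element counts into families and classes", {
  ann <- tiny_annotation()
  alns <- make_alns(
    aln_row("a1", "chr1", 1010), aln_row("a2", "chr1", 1100),
    aln_row("a3", "chr1", 1200), aln_row("b1", "chr1", 5010),
    aln_row("b2", "chr1", 5100), aln_row("c1", "chr2", 1100))
  el <- count_te(alns, ann, mode = "unique_only", level = "element")
  fam <- aggregate_hierarchy(el, ann, "family")
  expect_equal(fam$counts["ERVL", "s1"], 5L)
  expect_equal(fam$counts["L1", "s1"], 1L)
  cls <- aggregate_hierarchy(el, ann, "class")
  expect_equal(sort(rowSums(cls$counts)), sort(rowSums(
    rowsum(fam$counts, c(Alu = "SINE", ERVL = "LTR", L1 = "LINE",
                         `ERVL-MaLR` = "LTR")[rownames(fam$counts)]))))
  # single-element family: family count equals element count
  expect_equal(fam$counts["Alu", "s1"], el$counts["B1", "s1"])
  expect_error(aggregate_hierarchy(fam, ann, "class"), "element-level")
})

test_that("counts match a brute-force overlap oracle and conserve reads", {
  cfg <- small_config(seed = 31, multi_map_fraction = 0.3)
  ref <- generate_reference(cfg)
  sim <- simulate_alignments(cfg, ref$truth)
  alns <- sim$alignments
  te_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ref$annotation$tes)),
    start = GenomicRanges::start(ref$annotation$tes),
    end = GenomicRanges::end(ref$annotation$tes),
    stringsAsFactors = FALSE)
  for (level in c("copy", "element", "family", "class")) {
    lab <- switch(level, copy = ref$annotation$tes$te_id,
                  element = ref$annotation$tes$repName,
                  family = ref$annotation$tes$repFamily,
                  class = ref$annotation$tes$repClass)
    tab <- count_te(alns, ann = ref$annotation, mode = "unique_only",
                    level = level)
    sub <- as.data.frame(alns[alns$nh == 1L & !alns$secondary, ])
    res <- oracle_count_te(sub, te_df, lab)
    expect_identical(unclass(tab$counts),
                     unclass(oracle_count_matrix(res, rownames(tab$counts),
                                                 colnames(tab$counts))),
                     label = paste("oracle", level))
    # conservation: assigned + ambiguous + non-TE = retained reads
    expect_equal(tab$te_total + tab$ambiguous + tab$non_te,
                 tab$mapped_total, label = paste("conservation", level))
  }
})
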