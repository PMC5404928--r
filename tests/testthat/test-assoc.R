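# annotation with controlled TE-gene geometry on one long chromosome
assoc_annotation <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 300001), c(105000, 305000)),
    strand = "+", gene_id = c("g1", "g2"))
  genes$tss <- GenomicRanges::start(genes)
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 104001, 300001, 304001),
                             c(100500, 105000, 300500, 305000)),
    strand = "+", gene_id = rep(c("g1", "g2"), each = 2))
  tes <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(99000, 100531, 110000, 2500000, 304970),
                     c(99400, 100700, 110400, 2500400, 305400)),
    strand = "+",
    te_id = c("near_g1", "gap30", "mid", "far", "in_exon"),
    repName = "MT2", repFamily = "ERVL", repClass = "LTR")
  genome_annotation(genes, exons, tes)
}

test_that("nearest-gene pairing applies exon-gap and distance exclusions", {
  ann <- assoc_annotation()
  samples <- paste0("s", 1:8)
  gene_expr <- rbind(g1 = c(1, 3, 5, 7, 9, 11, 13, 15),
                     g2 = c(8, 2, 9, 1, 7, 3, 6, 4))
  colnames(gene_expr) <- samples
  te_expr <- rbind(near_g1 = 2 * gene_expr["g1", ] + 1,  # monotone copy
                   gap30 = rnorm(8), mid = rnorm(8), far = rnorm(8),
                   in_exon = rnorm(8))
  colnames(te_expr) <- samples
  pairs <- nearest_gene_correlation(te_expr, gene_expr, ann,
                                    max_distance = 1e6, exon_gap = 51)
  p <- function(id) pairs[pairs$te_id == id, ]
  # identical (monotone) profile: Spearman exactly 1
  expect_false(p("near_g1")$excluded)
  expect_identical(p("near_g1")$gene_id, "g1")
  expect_equal(p("near_g1")$rho, 1)
  # 30 bp from an exon (<= 51): excluded with reason exon_gap
  expect_true(p("gap30")$excluded)
  expect_identical(p("gap30")$reason, "exon_gap")
  expect_true(is.na(p("gap30")$rho))
  # overlapping an exon: excluded too
  expect_identical(p("in_exon")$reason, "exon_gap")
  # beyond the distance cap: excluded with reason distance
  expect_true(p("far")$excluded)
  expect_identical(p("far")$reason, "distance")
  # plain intergenic TE pairs with the closer gene
  expect_identical(p("mid")$gene_id, "g1")
  expect_equal(p("mid")$distance, 110000 - 105000 - 1)
  expect_error(nearest_gene_correlation(
    te_expr, gene_expr[, 1:4, drop = FALSE] * NA, ann), NA)
  colnames(te_expr) <- paste0("x", 1:8)
  expect_error(nearest_gene_correlation(te_expr, gene_expr, ann),
               "in common")
})

test_that("Spearman coefficients equal a midrank oracle, including ties", {
  set.seed(13)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)   # heavy ties
    y <- rnorm(12)
    expect_equal(suppressWarnings(cor(x, y, method = "spearman")),
                 oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("DE-TE neighbourhood overlap uses an upper-tail hypergeometric test", {
  ann <- assoc_annotation()
  universe <- c("g1", "g2")
  # g1 has a DE TE 5 kb away (mid at 110000 vs g1 end 105000): within 20 kb
  res <- de_te_gene_overlap(de_genes = "g1", de_tes = "mid", ann = ann,
                            window = 2e4, universe = universe)
  expect_identical(res$neighbour_genes, "g1")
  expect_equal(res$n_overlap, 1)
  expect_equal(res$p, oracle_hyper_upper(1, 2, 1, 1), tolerance = 1e-12)
  # overlap 0 gives p = 1 (the upper tail includes zero)
  res0 <- de_te_gene_overlap("g2", "mid", ann, window = 2e4,
                             universe = universe)
  expect_equal(res0$p, 1)
  # randomized agreement with the enumeration oracle
  set.seed(7)
  for (i in 1:20) {
    N <- 100; A <- 10; B <- 10
    k <- sample(0:10, 1)
    p <- phyper(k - 1, A, N - A, B, lower.tail = FALSE)
    expect_equal(p, oracle_hyper_upper(k, N, A, B), tolerance = 1e-10)
  }
  # monotone: more overlap, smaller p (fixed margins)
  ps <- vapply(0:10, function(k) phyper(k - 1, 10, 90, 10,
                                        lower.tail = FALSE), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(de_te_gene_overlap("zz", "mid", ann, universe = universe),
               "subset")
})

test_that("TSS permutation test is calibrated at its degenerate limits", {
  # universe where every gene has the same TE neighbourhood count
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(10000, 10000 + 99 * 30000, by = 30000),
                             width = 2000), strand = "+",
    gene_id = sprintf("g%03d", 1:100))
  genes$tss <- GenomicRanges::start(genes)
  exons <- genes
  tes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(genes$tss + 3000, width = 300), strand = "+",
    te_id = sprintf("t%03d", 1:100), repName = "MT2", repFamily = "ERVL",
    repClass = "LTR")
  ann <- genome_annotation(genes, exons, tes)
  focus <- sprintf("g%03d", 1:20)
  r <- tss_enrichment_permutation(tes$te_id, focus, genes$gene_id, ann,
                                  window = 1e4, n_perm = 200, seed = 4)
  expect_equal(r$p, 1)

  # TEs exclusively near focus genes: the smallest achievable p
  ann2 <- ann
  ann2$tes <- ann2$tes[1:20]
  r2 <- tss_enrichment_permutation(ann2$tes$te_id, focus, genes$gene_id,
                                   ann2, window = 1e4, n_perm = 999,
                                   seed = 4)
  expect_equal(r2$p, 1 / 1000)
  expect_gte(min(r2$null), 0)
  expect_true(r2$p >= 1 / (r2$n_perm + 1) && r2$p <= 1)
  # exon-overlapping TEs are removed before counting
  expect_equal(r2$n_te_used, 20)
  expect_error(tss_enrichment_permutation(ann2$tes$te_id, character(),
                                          genes$gene_id, ann2), "empty")
})

test_that("maternal and zygotic TE labels partition and odds ratios verify", {
  set.seed(19)
  samples <- data.frame(
    sample = sprintf("s%02d", 1:12),
    stage = rep(c("oocyte", "2-cell"), each = 6),
    genotype = "WT", stringsAsFactors = FALSE)
  mu <- matrix(50, 6, 12)
  mu[1, 7:12] <- 400   # zygotic
  mu[2, 1:6] <- 400    # maternal
  x <- matrix(rnbinom(length(mu), mu = mu, size = 10), 6,
              dimnames = list(paste0("t", 1:6), samples$sample))
  mz <- maternal_zygotic_te(count_matrix(x, samples), alpha = 0.05,
                            normalize = FALSE)
  expect_identical(mz$label[mz$feature == "t1"], "zygotic")
  expect_identical(mz$label[mz$feature == "t2"], "maternal")
  expect_true(all(table(mz$feature) == 1))  # mutually exclusive labels

  orr <- odds_ratio_enrichment(
    set_a = c(paste0("a", 1:30), paste0("b", 1:10)),
    set_b = c(paste0("a", 1:30), paste0("c", 1:10)),
    universe = c(paste0("a", 1:30), paste0("b", 1:10), paste0("c", 1:10),
                 paste0("d", 1:30)))
  expect_equal(orr$odds_ratio, 9)
  expect_equal(orr$p, oracle_fisher_two_sided(30, 10, 10, 30),
               tolerance = 1e-9)
  # Haldane correction engages on zero cells
  oz <- odds_ratio_enrichment("a", "a", c("a", "b", "c"))
  expect_true(is.finite(oz$odds_ratio))
  # independent random sets: log-OR centred at zero
  set.seed(23)
  lor <- replicate(200, {
    u <- paste0("u", 1:80)
    o <- odds_ratio_enrichment(sample(u, 30), sample(u, 30), u)
    log(o$odds_ratio)
  })
  expect_lt(abs(mean(lor)), 2 * sd(lor) / sqrt(length(lor)) + 0.1)
})
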