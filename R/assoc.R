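#' Nearest-gene expression correlation for TE copies
#'
#' Pairs each TE copy with its nearest gene (minimal interval-to-interval
#' distance, ties broken by lower gene coordinate) and computes Spearman's
#' rank correlation (midranks for ties) of the two expression profiles over
#' the shared samples. TE copies lying within `exon_gap` bp of any exon
#' (including UTRs; overlap counts as distance 0) are excluded, as are
#' copies with no gene within `max_distance`. Exclusions carry a reason and
#' no coefficient.
#'
#' @param te_expr numeric matrix, TE copies x samples (rownames = `te_id`;
#'   e.g. within-sample normalised TE values).
#' @param gene_expr numeric matrix, genes x samples (e.g. size-factor
#'   normalised counts).
#' @param ann a [genome_annotation()].
#' @param max_distance maximum TE-to-gene distance in bp (default 1 Mbp).
#' @param exon_gap maximum gap to an exon that still triggers exclusion
#'   (default 51 bp, the read length).
#' @return data.frame of class `te_gene_pairs`: `te_id`, `gene_id`,
#'   `distance`, `rho`, `excluded`, `reason`.
#' @export
nearest_gene_correlation <- function(te_expr, gene_expr, ann,
                                     max_distance = 1e6, exon_gap = 51) {
  te_expr <- as.matrix(te_expr)
  gene_expr <- as.matrix(gene_expr)
  shared <- intersect(colnames(te_expr), colnames(gene_expr))
  if (!length(shared)) stop("no samples in common", call. = FALSE)
  tes <- ann$tes[match(rownames(te_expr), ann$tes$te_id)]
  if (anyNA(match(rownames(te_expr), ann$tes$te_id))) {
    stop("te_expr contains copies absent from the annotation", call. = FALSE)
  }
  genes <- ann$genes

  near_exon <- IRanges::overlapsAny(tes, ann$exons, maxgap = exon_gap,
                                    ignore.strand = TRUE)
  d <- GenomicRanges::distanceToNearest(tes, genes, ignore.strand = TRUE,
                                        select = "all")
  # resolve ties toward the lower-coordinate gene
  dd <- data.frame(q = S4Vectors::queryHits(d), s = S4Vectors::subjectHits(d),
                   dist = S4Vectors::mcols(d)$distance)
  dd <- dd[order(dd$q, dd$dist, GenomicRanges::start(genes)[dd$s]), ,
           drop = FALSE]
  dd <- dd[!duplicated(dd$q), , drop = FALSE]
  nearest_gene <- rep(NA_character_, length(tes))
  nearest_dist <- rep(NA_real_, length(tes))
  nearest_gene[dd$q] <- genes$gene_id[dd$s]
  nearest_dist[dd$q] <- dd$dist

  res <- data.frame(
    te_id = tes$te_id, gene_id = nearest_gene, distance = nearest_dist,
    rho = NA_real_, excluded = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE)
  res$excluded <- near_exon | is.na(res$distance) |
    res$distance > max_distance
  res$reason[near_exon] <- "exon_gap"
  far <- !near_exon & (is.na(res$distance) | res$distance > max_distance)
  res$reason[far] <- "distance"
  res$gene_id[res$excluded] <- NA_character_
  res$distance[res$excluded & far] <- NA_real_

  keep <- which(!res$excluded)
  for (i in keep) {
    g <- res$gene_id[i]
    if (!g %in% rownames(gene_expr)) {
      res$excluded[i] <- TRUE
      res$reason[i] <- "gene_not_quantified"
      next
    }
    res$rho[i] <- suppressWarnings(
      stats::cor(te_expr[res$te_id[i], shared], gene_expr[g, shared],
                 method = "spearman"))
  }
  class(res) <- c("te_gene_pairs", "data.frame")
  res
}

#' Overlap of DE genes with neighbours of DE TEs
#'
#' Builds the set of universe genes having at least one differentially
#' expressed TE within `window` bp (anchored at the TE, measured to the
#' gene interval; overlap = distance 0), intersects it with the DE gene
#' set, and tests the overlap with an upper-tail hypergeometric test.
#'
#' @param de_genes character vector of DE gene ids (subset of `universe`).
#' @param de_tes character vector of DE TE copy ids.
#' @param ann a [genome_annotation()].
#' @param window half-width in bp (default 20 kb).
#' @param universe background gene ids (all tested genes).
#' @return list: `neighbour_genes`, `overlap` (ids), `n_overlap`,
#'   `expected`, `p` (hypergeometric upper tail).
#' @export
de_te_gene_overlap <- function(de_genes, de_tes, ann, window = 2e4,
                               universe) {
  if (!all(de_genes %in% universe)) {
    stop("de_genes must be a subset of the universe", call. = FALSE)
  }
  genes <- ann$genes[ann$genes$gene_id %in% universe]
  tes <- ann$tes[ann$tes$te_id %in% de_tes]
  nb <- IRanges::overlapsAny(genes, tes, maxgap = window,
                             ignore.strand = TRUE)
  neighbour <- genes$gene_id[nb]
  overlap <- intersect(de_genes, neighbour)
  N <- length(universe)
  p <- stats::phyper(length(overlap) - 1, length(de_genes),
                     N - length(de_genes), length(neighbour),
                     lower.tail = FALSE)
  list(neighbour_genes = neighbour, overlap = overlap,
       n_overlap = length(overlap),
       expected = length(de_genes) * length(neighbour) / N, p = p)
}

#' TSS-neighbourhood permutation enrichment test
#'
#' Tests whether a set of TE copies (e.g. TEs depleted in KO embryos) is
#' enriched within `window` bp of the transcription start sites of a focus
#' gene set (e.g. zygotically activated genes). The statistic is the mean,
#' over focus genes, of the number of candidate TEs within the TSS window;
#' the null distribution repeats the statistic for `n_perm` random gene
#' sets of identical size drawn without replacement from `all_genes`. TEs
#' overlapping any exon are removed first (`exon_gap = 0`: strict overlap).
#' The empirical p-value uses the add-one convention
#' `(1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' @param te_ids candidate TE copy ids.
#' @param focus_genes focus gene ids (e.g. ZAGs).
#' @param all_genes universe gene ids the random sets are drawn from.
#' @param ann a [genome_annotation()].
#' @param window TSS half-width in bp (default 10 kb).
#' @param n_perm number of resamples (default 10,000).
#' @param seed RNG seed.
#' @param exon_gap maximum exon gap triggering TE exclusion (default 0).
#' @return object of class `permutation_result`: `observed`, `null`
#'   (numeric vector), `p`, `window`, `n_perm`, `seed`, `n_focus`,
#'   `n_te_used`.
#' @export
tss_enrichment_permutation <- function(te_ids, focus_genes, all_genes, ann,
                                       window = 1e4, n_perm = 1e4,
                                       seed = 1L, exon_gap = 0) {
  if (!length(focus_genes)) stop("focus gene set is empty", call. = FALSE)
  if (!all(focus_genes %in% all_genes)) {
    stop("focus genes must belong to the universe", call. = FALSE)
  }
  tes <- ann$tes[ann$tes$te_id %in% te_ids]
  drop <- IRanges::overlapsAny(tes, ann$exons, maxgap = exon_gap,
                               ignore.strand = TRUE)
  tes <- tes[!drop]
  genes <- ann$genes[match(all_genes, ann$genes$gene_id)]
  if (anyNA(match(all_genes, ann$genes$gene_id))) {
    stop("universe contains genes absent from the annotation", call. = FALSE)
  }
  tss_win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, genes$tss - as.integer(window)),
                     genes$tss + as.integer(window)))
  counts <- GenomicRanges::countOverlaps(tss_win, tes,
                                         ignore.strand = TRUE)
  names(counts) <- all_genes
  observed <- mean(counts[focus_genes])
  k <- length(focus_genes)
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    mean(counts[sample.int(length(counts), k)])
  }, numeric(1)))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p = p, window = window,
                 n_perm = n_perm, seed = seed, n_focus = k,
                 n_te_used = length(tes)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed mean %.4f vs null (n_perm=%d), p = %.4g\n",
    x$observed, x$n_perm, x$p))
  cat("null quantiles:\n")
  print(round(stats::quantile(x$null, c(0.025, 0.25, 0.5, 0.75, 0.975)), 4))
  invisible(x)
}

#' Maternal / zygotic TE classification
#'
#' Classifies TE features from WT samples: `maternal` when expression is
#' significantly higher in oocytes than 2-cell embryos (rank-sum +
#' Benjamini-Hochberg at `alpha`), `zygotic` for the converse, `neither`
#' otherwise. The labels are mutually exclusive by construction.
#'
#' @param m a [count_matrix()] of TE features (WT samples with stages
#'   `oocyte` and `2-cell` present).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param ... passed to [differential_test()] (e.g. `min_count`,
#'   `normalize`).
#' @return data.frame `feature`, `label`, plus the underlying `de` result
#'   as attribute `"de"`.
#' @export
maternal_zygotic_te <- function(m, alpha = 0.05, ...) {
  stopifnot(inherits(m, "count_matrix"))
  wt <- m$samples[m$samples$genotype == "WT", , drop = FALSE]
  ooc <- wt$sample[wt$stage == "oocyte"]
  two <- wt$sample[wt$stage == "2-cell"]
  if (!length(ooc) || !length(two)) {
    stop("WT oocyte and 2-cell samples are both required", call. = FALSE)
  }
  de <- differential_test(m, ooc, two, ...)
  sig <- !is.na(de$padj) & de$padj < alpha
  label <- ifelse(sig & de$log2fc > 0, "maternal",
                  ifelse(sig & de$log2fc < 0, "zygotic", "neither"))
  out <- data.frame(feature = de$feature, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "de") <- de
  out
}

#' Odds ratio of membership between two feature sets
#'
#' Cross-product (sample) odds ratio of the 2x2 table (in `set_a` vs. not)
#' x (in `set_b` vs. not) over a universe, with the Haldane correction
#' (0.5 added to every cell) when any cell is zero, and Fisher's exact
#' p-value on the uncorrected table.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe background feature ids.
#' @return list: `table` (2x2 matrix), `odds_ratio`, `p`.
#' @export
odds_ratio_enrichment <- function(set_a, set_b, universe) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  list(table = tab, odds_ratio = or,
       p = stats::fisher.test(tab)$p.value)
}
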