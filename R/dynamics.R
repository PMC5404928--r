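#' Two-group differential expression test
#'
#' A substitute differential test for count matrices: size-factor
#' normalisation (median-of-ratios), a per-feature two-group test, and
#' Benjamini-Hochberg adjustment across tested features. The default test is
#' the Wilcoxon rank-sum on normalised counts (normal approximation with
#' continuity correction); `method = "wald"` uses a Welch-type normal
#' approximation on `log2(normalised + 1)`. Features whose mean normalised
#' count across the two groups falls below `min_count` are excluded before
#' adjustment (their `padj` is NA and they are never called).
#'
#' The reported `log2fc` is `log2` of (mean of group A + 0.5) over (mean of
#' group B + 0.5), i.e. A over B on normalised counts.
#'
#' @param m a [count_matrix()] or bare matrix.
#' @param group_a,group_b character vectors of sample ids (each of size
#'   >= 2).
#' @param method `"ranksum"` or `"wald"`.
#' @param min_count minimum mean normalised count to be tested.
#' @param normalize apply size-factor normalisation first (TRUE) or test
#'   the matrix as supplied (FALSE).
#' @return data.frame of class `de_result`: `feature`, `mean_a`, `mean_b`,
#'   `log2fc`, `pvalue`, `padj`, `tested`.
#' @export
differential_test <- function(m, group_a, group_b,
                              method = c("ranksum", "wald"),
                              min_count = 5, normalize = TRUE) {
  method <- match.arg(method)
  x <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  miss <- setdiff(c(group_a, group_b), colnames(x))
  if (length(miss)) stop("unknown sample(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  sub <- x[, c(group_a, group_b), drop = FALSE]
  norm <- if (normalize) normalize_counts(sub) else sub
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  tested <- (mean_a + mean_b) / 2 >= min_count
  p <- rep(NA_real_, nrow(norm))
  test_one <- if (method == "ranksum") {
    function(va, vb) {
      if (stats::var(c(va, vb)) == 0) return(1)
      stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE)$p.value
    }
  } else {
    function(va, vb) {
      la <- log2(va + 1); lb <- log2(vb + 1)
      se <- sqrt(stats::var(la) / length(la) + stats::var(lb) / length(lb))
      if (se == 0) return(1)
      2 * stats::pnorm(-abs((mean(la) - mean(lb)) / se))
    }
  }
  for (i in which(tested)) p[i] <- test_one(a[i, ], b[i, ])
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  res <- data.frame(
    feature = rownames(norm), mean_a = mean_a, mean_b = mean_b,
    log2fc = log2((mean_a + 0.5) / (mean_b + 0.5)),
    pvalue = p, padj = padj, tested = tested,
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Nine-class time-series dynamics assignment
#'
#' Combines two adjacent-stage differential results (earlier vs. later
#' stage) into one of nine classes: each transition is called `U`
#' (upregulated at the later stage) or `D` (downregulated) when the
#' adjusted p-value is below `alpha`, and `E` (equally expressed)
#' otherwise; the class concatenates the two calls (e.g. `ED` = equal
#' from oocyte to 1-cell, then down at 2-cell). Direction comes from the
#' sign of the later-over-earlier fold change. Untested features (below
#' the expression filter) are called `E` for that transition.
#'
#' @param de_t1 `de_result` for transition 1, computed with group A = later
#'   stage and group B = earlier stage (so `log2fc > 0` means upregulated).
#' @param de_t2 same for transition 2.
#' @param alpha adjusted-p threshold for calling D/U (default 0.1).
#' @return data.frame `feature`, `t1`, `t2`, `class`.
#' @export
classify_dynamics <- function(de_t1, de_t2, alpha = 0.1) {
  if (!setequal(de_t1$feature, de_t2$feature)) {
    stop("the two differential results must cover the same features",
         call. = FALSE)
  }
  de_t2 <- de_t2[match(de_t1$feature, de_t2$feature), , drop = FALSE]
  call_one <- function(de) {
    sig <- !is.na(de$padj) & de$padj < alpha
    ifelse(!sig, "E", ifelse(de$log2fc > 0, "U", "D"))
  }
  t1 <- call_one(de_t1)
  t2 <- call_one(de_t2)
  data.frame(feature = de_t1$feature, t1 = t1, t2 = t2,
             class = paste0(t1, t2), stringsAsFactors = FALSE)
}

#' Stage-series dynamics classification from a count matrix
#'
#' Convenience wrapper: runs the differential test between each pair of
#' adjacent stages (later vs. earlier) on the given samples and classifies
#' each feature into the nine dynamics classes.
#'
#' @param m a [count_matrix()] whose samples span the ordered stages.
#' @param stages ordered stage labels (default oocyte, 1-cell, 2-cell).
#' @param alpha adjusted-p threshold per transition.
#' @param ... passed to [differential_test()].
#' @return as [classify_dynamics()].
#' @export
classify_mzt_dynamics <- function(m,
                                  stages = c("oocyte", "1-cell", "2-cell"),
                                  alpha = 0.1, ...) {
  stopifnot(inherits(m, "count_matrix"), length(stages) == 3)
  grp <- function(st) m$samples$sample[m$samples$stage == st]
  de1 <- differential_test(m, grp(stages[2]), grp(stages[1]), ...)
  de2 <- differential_test(m, grp(stages[3]), grp(stages[2]), ...)
  classify_dynamics(de1, de2, alpha = alpha)
}

#' Thresholded co-expression network around an anchor gene
#'
#' Computes pairwise Pearson correlations `rho[i, j]` over samples on a
#' `log2(CPM + 1)` matrix and applies the hard-threshold adjacency rule:
#' `C[i, j] = rho[i, j]` when `|rho[i, j]| >= x`, else 0. The anchor's
#' positively (`rho >= x`) and negatively (`rho <= -x`) correlated partners
#' are reported separately. Zero-variance features yield no edges and are
#' flagged rather than propagating NaN.
#'
#' @param logcpm numeric matrix, features in rows (e.g. from
#'   [cpm_log_transform()]); needs >= 3 samples.
#' @param anchor feature id of the anchor gene.
#' @param x correlation threshold in (0, 1] (default 0.9).
#' @return object of class `coexpression_network`: `adjacency` matrix `C`,
#'   `threshold`, `anchor`, `positive`, `negative`, `zero_variance`.
#' @export
coexpression_network <- function(logcpm, anchor, x = 0.9) {
  logcpm <- as.matrix(logcpm)
  if (ncol(logcpm) < 3) stop("need at least 3 samples", call. = FALSE)
  if (!anchor %in% rownames(logcpm)) {
    stop("anchor feature not present: ", anchor, call. = FALSE)
  }
  if (x <= 0 || x > 1) stop("threshold x must lie in (0, 1]", call. = FALSE)
  zv <- apply(logcpm, 1, stats::var) == 0
  rho <- suppressWarnings(stats::cor(t(logcpm)))
  rho[zv, ] <- 0
  rho[, zv] <- 0
  C <- ifelse(abs(rho) >= x, rho, 0)
  diag(C) <- 0
  av <- C[anchor, ]
  structure(list(
    adjacency = C, threshold = x, anchor = anchor,
    positive = sort(names(av)[av >= x & names(av) != anchor]),
    negative = sort(names(av)[av <= -x]),
    zero_variance = rownames(logcpm)[zv]),
    class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d features, threshold %.2f, anchor %s (%d +, %d -)\n",
    nrow(x$adjacency), x$threshold, x$anchor, length(x$positive),
    length(x$negative)))
  invisible(x)
}

#' Category enrichment ratio of up- vs. downregulated genes
#'
#' For each user-supplied category, reports `log2` of the ratio of
#' upregulated to downregulated members and a Fisher's exact p-value from
#' the 2x2 table (in category vs. not) x (up vs. down). A pseudocount
#' (default 1) enters the ratio only when one of the two member counts is
#' zero; raw counts are always reported alongside.
#'
#' @param up,down disjoint character vectors of feature ids, subsets of
#'   `background`.
#' @param categories named list of character vectors (a DBTMEE-style
#'   gene-to-category map).
#' @param background the tested universe.
#' @param pseudocount value added to both ratio cells when either is zero.
#' @return data.frame `category`, `n_up`, `n_down`, `log2_ratio`,
#'   `fisher_p`; empty categories are skipped with a warning.
#' @export
category_enrichment <- function(up, down, categories, background,
                                pseudocount = 1) {
  if (!all(up %in% background) || !all(down %in% background)) {
    stop("up/down sets must be subsets of the background", call. = FALSE)
  }
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], background)
    if (!length(cat_genes)) {
      warning("skipping empty category: ", nm, call. = FALSE)
      return(NULL)
    }
    u <- sum(up %in% cat_genes)
    d <- sum(down %in% cat_genes)
    c0 <- if (u == 0 || d == 0) pseudocount else 0
    tab <- matrix(c(u, d, length(up) - u, length(down) - d), 2,
                  byrow = TRUE)
    data.frame(category = nm, n_up = u, n_down = d,
               log2_ratio = log2((u + c0) / (d + c0)),
               fisher_p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(category = character(), n_up = integer(),
                      n_down = integer(), log2_ratio = numeric(),
                      fisher_p = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
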