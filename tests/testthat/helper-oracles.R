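# Independent brute-force oracles. These deliberately avoid the package's
# code paths (GenomicRanges overlap machinery, vmatchPattern, stats::cor)
# so that agreement is informative.

# CIGAR -> list of (start, end) reference segments, split at N
oracle_segments <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  segs <- list()
  cur_start <- pos
  cur_end <- pos - 1
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "D", "=", "X")) {
      cur_end <- cur_end + n
    } else if (type == "N") {
      if (cur_end >= cur_start) segs[[length(segs) + 1]] <- c(cur_start, cur_end)
      cur_start <- cur_end + n + 1
      cur_end <- cur_start - 1
    }
    # I, S, H, P consume no reference
  }
  if (cur_end >= cur_start) segs[[length(segs) + 1]] <- c(cur_start, cur_end)
  segs
}

# naive interval overlap of one segment against TE records (data.frame with
# chrom/start/end columns)
oracle_overlapping_tes <- function(chrom, start, end, te_df) {
  which(te_df$chrom == chrom & te_df$start <= end & te_df$end >= start)
}

# brute-force TE counting over a retained alignment subset: per read, the set
# of level labels its segments touch; 0 -> non_te, 1 -> assigned, >1 ->
# ambiguous. `sub` is a plain data.frame of retained records.
oracle_count_te <- function(sub, te_df, label) {
  key <- paste(sub$sample, sub$read_id, sep = "\r")
  res <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    labs <- character()
    for (r in rows) {
      for (seg in oracle_segments(sub$cigar[r], sub$pos[r])) {
        idx <- oracle_overlapping_tes(sub$chrom[r], seg[1], seg[2], te_df)
        labs <- c(labs, label[idx])
      }
    }
    labs <- unique(labs)
    res[[k]] <- list(sample = sub$sample[rows[1]],
                     status = if (length(labs) == 0) "non_te"
                              else if (length(labs) == 1) "assigned"
                              else "ambiguous",
                     label = if (length(labs) == 1) labs else NA_character_)
  }
  res
}

oracle_count_matrix <- function(res, features, samples) {
  m <- matrix(0L, length(features), length(samples),
              dimnames = list(features, samples))
  for (r in res) {
    if (r$status == "assigned") m[r$label, r$sample] <- m[r$label, r$sample] + 1L
  }
  m
}

# exhaustive two-strand Hamming scan of a character genome
oracle_hamming_scan <- function(seqs, sirna_dna, max_mm) {
  pat <- strsplit(sirna_dna, "")[[1]]
  L <- length(pat)
  revcomp <- function(v) rev(chartr("ACGT", "TGCA", v))
  out <- list()
  for (ch in names(seqs)) {
    g <- strsplit(as.character(seqs[[ch]]), "")[[1]]
    n <- length(g)
    if (n < L) next
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp(pat)
      mm <- integer(n - L + 1)
      for (j in seq_len(L)) {
        mm <- mm + (g[j:(n - L + j)] != p[j])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = hit, end = hit + L - 1L, strand = strand,
          mismatch = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatch = integer(), stringsAsFactors = FALSE))
  }
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# midrank-based Spearman: rank by explicit tie-averaging, then the Pearson
# sum formula written out
oracle_midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))
}

# hypergeometric upper tail P(X >= k) by direct summation of choose() terms
oracle_hyper_upper <- function(k, N, K, n) {
  i <- max(k, 0):min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# two-sided Fisher p: sum of hypergeometric point probabilities <= that of
# the observed table (up to relative slack, as fisher.test does)
oracle_fisher_two_sided <- function(a, b, cc, d) {
  K <- a + b; n <- a + cc; N <- a + b + cc + d
  support <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
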