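#' Simulation configuration
#'
#' Defines the synthetic study: a toy genome with genes and RepeatMasker-style
#' TE copies, stage-by-genotype expression programs across the
#' maternal-to-zygotic transition, and read-level alignment structure
#' (multi-mapping, split reads over planted chimeric junctions, mitochondrial
#' contamination). The defaults emulate the study design: three ordered
#' stages (oocyte, 1-cell, 2-cell), WT and KO genotypes, maternal-decay and
#' zygotic-activation gene classes, a 2-cell TE burst for the ERVL elements,
#' and a 51 bp read length that also sets the exon-gap exclusion rule.
#'
#' @param seed integer; fixes every random choice (same seed, same bytes).
#' @param n_chromosomes,chrom_length autosome count and length (bp).
#' @param mito_length length of the dedicated mitochondrial contig `chrM`.
#' @param n_genes number of genes (three exons each).
#' @param te_elements data.frame with columns `rep_name`, `rep_family`,
#'   `rep_class`, `n_copies`, `copy_length`; at least two element names share
#'   a family so that element-level multi-mapping ambiguity exists.
#' @param n_full_length_te number of internal-element copies carrying both
#'   the gag-like and pol-like query subsequences (plus the siRNA site).
#' @param stages,genotypes ordered stage labels and genotype labels.
#' @param samples_per_group samples per stage-by-genotype group.
#' @param mean_library_size mean simulated reads per sample.
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param class_proportions named proportions over the nine dynamics classes
#'   (EE, ED, EU, DE, DD, DU, UE, UD, UU); must sum to 1.
#' @param effect_size fold change applied per D/U transition.
#' @param ko_dampening KO multiplier on zygotic activation (and on zygotic
#'   TE/junction read support) at the 2-cell stage.
#' @param ko_affected_fraction fraction of ED/EU genes perturbed in KO.
#' @param n_chimeric_junctions planted TE-gene junctions.
#' @param translocated_fraction fraction of junctions realised as
#'   cross-chromosome (translocated) read pairs rather than spliced CIGARs.
#' @param multi_map_fraction fraction of TE reads emitted as multi-mapped.
#' @param mito_read_fraction mitochondrial read fraction; scalar, or a named
#'   vector keyed by sample id to vary per sample.
#' @param read_length read length in bp (51 by default; the downstream
#'   exon-gap rule follows it).
#' @param copy_identity sequence identity of TE copies to their element
#'   consensus (creates multi-mapping homology).
#' @param internal_element element name whose copies form the gag/pol-coding
#'   internal body (default: first row of `te_elements`); its `copy_length`
#'   must be at least 1100 bp.
#'
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 300000L,
                              mito_length = 16000L,
                              n_genes = 80L,
                              te_elements = default_te_elements(),
                              n_full_length_te = 5L,
                              stages = c("oocyte", "1-cell", "2-cell"),
                              genotypes = c("WT", "KO"),
                              samples_per_group = 6L,
                              mean_library_size = 4000L,
                              dispersion = 0.1,
                              class_proportions = c(
                                EE = 0.20, ED = 0.15, EU = 0.15,
                                DE = 0.10, DD = 0.10, DU = 0.05,
                                UE = 0.10, UD = 0.05, UU = 0.10),
                              effect_size = 8,
                              ko_dampening = 0.25,
                              ko_affected_fraction = 0.5,
                              n_chimeric_junctions = 6L,
                              translocated_fraction = 0.2,
                              multi_map_fraction = 0.2,
                              mito_read_fraction = 0.02,
                              read_length = 51L,
                              copy_identity = 0.95,
                              internal_element = te_elements$rep_name[1]) {
  cfg <- as.list(environment())
  classes <- c("EE", "ED", "EU", "DE", "DD", "DU", "UE", "UD", "UU")
  if (!setequal(names(class_proportions), classes)) {
    stop("class_proportions must be named over the nine dynamics classes",
         call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  counts <- c(n_chromosomes, n_genes, n_full_length_te, samples_per_group,
              n_chimeric_junctions, te_elements$n_copies)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  fracs <- c(multi_map_fraction, mito_read_fraction, translocated_fraction,
             ko_affected_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  need <- c("rep_name", "rep_family", "rep_class", "n_copies", "copy_length")
  if (!all(need %in% names(te_elements))) {
    stop("te_elements lacks column(s): ",
         paste(setdiff(need, names(te_elements)), collapse = ", "),
         call. = FALSE)
  }
  if (max(table(te_elements$rep_family)) < 2) {
    stop("at least two TE element names must share a repFamily",
         call. = FALSE)
  }
  if (!internal_element %in% te_elements$rep_name) {
    stop("internal_element must name a row of te_elements", call. = FALSE)
  }
  if (te_elements$copy_length[te_elements$rep_name == internal_element] <
        1100L) {
    stop("the internal element needs copy_length >= 1100 to hold the ",
         "gag/pol query subsequences and the siRNA site", call. = FALSE)
  }
  cfg$class_proportions <- class_proportions[classes]
  structure(cfg, class = "simulation_config")
}

#' Default TE element panel
#'
#' Five element names spanning the LTR / LINE / SINE classes. The two ERVL
#' members (an internal element and an LTR, mirroring the MERVL-int / MT2
#' pairing) share a family, so reads multi-mapping between them are
#' family-unambiguous but element-ambiguous.
#'
#' @return data.frame of element names, hierarchy labels, copy numbers and
#'   copy lengths.
#' @export
default_te_elements <- function() {
  data.frame(
    rep_name = c("MERVL-like-int", "MT2-like", "ORR1-like", "L1-like",
                 "B1-like"),
    rep_family = c("ERVL", "ERVL", "ERVL-MaLR", "L1", "Alu"),
    rep_class = c("LTR", "LTR", "LTR", "LINE", "SINE"),
    n_copies = c(12L, 10L, 8L, 10L, 10L),
    copy_length = c(1500L, 500L, 600L, 2000L, 200L),
    stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

sim_sample_sheet <- function(config) {
  grid <- expand.grid(rep = seq_len(config$samples_per_group),
                      stage = config$stages, genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%s_s%02d", grid$genotype,
                         gsub("-", "", grid$stage), grid$rep)
  grid[, c("sample", "stage", "genotype")]
}

#' Generate the synthetic reference: genome, annotation and ground truth
#'
#' Lays out genes and TE copies along random chromosomes, installs TE copy
#' sequences mutated from a per-element consensus (creating multi-mapping
#' homology), embeds gag-like and pol-like query subsequences plus the siRNA
#' target site into the designated full-length internal-element copies, and
#' plants chimeric TE-gene junctions (a fraction of them cross-chromosome).
#'
#' @param config a [simulation_config()].
#' @return list with elements `genome` (`DNAStringSet`), `annotation`
#'   (a [genome_annotation()]) and `truth` (ground-truth list: per-gene
#'   dynamics class, KO-affected genes, per-element stage activity, planted
#'   junctions, full-length copies, query/siRNA sequences, baseline
#'   expression levels).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_reference_impl(config))
}

generate_reference_impl <- function(config) {
  te <- config$te_elements
  rl <- config$read_length

  # per-gene structure: three exons each
  n_exon <- 3L
  exon_w <- matrix(sample(150:400, config$n_genes * n_exon, replace = TRUE),
                   ncol = n_exon)
  intron_w <- matrix(sample(500:1500, config$n_genes * (n_exon - 1),
                            replace = TRUE), ncol = n_exon - 1)
  gene_w <- rowSums(exon_w) + rowSums(intron_w)

  feat <- data.frame(
    type = c(rep("gene", config$n_genes), rep("te", sum(te$n_copies))),
    id = c(sprintf("g%03d", seq_len(config$n_genes)),
           unlist(lapply(seq_len(nrow(te)), function(i) {
             sprintf("%s_%d", te$rep_name[i], seq_len(te$n_copies[i]))
           }))),
    width = c(gene_w,
              rep(te$copy_length, te$n_copies)),
    rep_name = c(rep(NA, config$n_genes), rep(te$rep_name, te$n_copies)),
    stringsAsFactors = FALSE)

  # scatter features over chromosomes, sequential placement with random gaps
  feat <- feat[sample.int(nrow(feat)), , drop = FALSE]
  feat$chrom <- sprintf("chr%d", rep_len(seq_len(config$n_chromosomes),
                                         nrow(feat)))
  feat$start <- NA_integer_
  for (chr in unique(feat$chrom)) {
    rows <- which(feat$chrom == chr)
    gaps <- sample(200:1200, length(rows), replace = TRUE)
    starts <- 1L + cumsum(gaps) +
      cumsum(c(0L, feat$width[rows][-length(rows)]))
    ends <- starts + feat$width[rows] - 1L
    if (max(ends) > config$chrom_length - 100L) {
      stop(sprintf(
        "impossible geometry: features on %s need %d bp but chrom_length is %d",
        chr, max(ends) + 100L, config$chrom_length), call. = FALSE)
    }
    feat$start[rows] <- starts
  }
  feat$end <- feat$start + feat$width - 1L

  # genome sequences
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  seqs <- vapply(chroms, function(ch) random_dna(config$chrom_length),
                 character(1))
  seqs <- c(seqs, chrM = random_dna(config$mito_length))

  # TE copy sequences: mutated from a per-element consensus
  consensus <- stats::setNames(
    vapply(te$copy_length, random_dna, character(1)), te$rep_name)
  gag_query <- random_dna(150)
  pol_query <- random_dna(150)
  sirna_site <- gsub("U", "T", sirna_sequences()[["MuERV-L"]])

  internal <- config$internal_element  # the gag/pol-coding element body
  te_rows <- which(feat$type == "te")
  copy_seq <- vapply(te_rows, function(i) {
    mutate_dna(consensus[[feat$rep_name[i]]], 1 - config$copy_identity)
  }, character(1))
  names(copy_seq) <- feat$id[te_rows]

  internal_ids <- feat$id[te_rows][feat$rep_name[te_rows] == internal]
  if (config$n_full_length_te > length(internal_ids)) {
    stop("n_full_length_te exceeds the number of internal-element copies",
         call. = FALSE)
  }
  full_length <- internal_ids[seq_len(config$n_full_length_te)]
  truncated <- setdiff(internal_ids, full_length)
  embed <- function(seq, insert, at) {
    paste0(substr(seq, 1, at - 1), insert,
           substr(seq, at + nchar(insert), nchar(seq)))
  }
  for (id in full_length) {
    s <- copy_seq[[id]]
    s <- embed(s, gag_query, 101L)
    s <- embed(s, pol_query, 701L)
    s <- embed(s, sirna_site, 1001L)
    copy_seq[[id]] <- s
  }
  for (id in truncated) {  # fragmentary copies retain only the gag region
    copy_seq[[id]] <- embed(copy_seq[[id]], gag_query, 101L)
  }
  for (i in te_rows) {
    ch <- feat$chrom[i]
    seqs[[ch]] <- paste0(substr(seqs[[ch]], 1, feat$start[i] - 1),
                         copy_seq[[feat$id[i]]],
                         substr(seqs[[ch]], feat$end[i] + 1,
                                nchar(seqs[[ch]])))
  }

  # annotation objects
  gene_rows <- which(feat$type == "gene")
  gidx <- match(feat$id[gene_rows], sprintf("g%03d", seq_len(config$n_genes)))
  strand <- sample(c("+", "-"), length(gene_rows), replace = TRUE)
  genes <- GenomicRanges::GRanges(
    feat$chrom[gene_rows],
    IRanges::IRanges(feat$start[gene_rows], feat$end[gene_rows]),
    strand = strand, gene_id = feat$id[gene_rows])
  genes$tss <- ifelse(strand == "-", GenomicRanges::end(genes),
                      GenomicRanges::start(genes))
  exon_list <- lapply(seq_along(gene_rows), function(k) {
    i <- gene_rows[k]
    ew <- exon_w[gidx[k], ]
    iw <- intron_w[gidx[k], ]
    st <- feat$start[i] + cumsum(c(0L, ew[-n_exon] + iw))
    data.frame(chrom = feat$chrom[i], start = st, end = st + ew - 1L,
               strand = strand[k], gene_id = feat$id[i],
               stringsAsFactors = FALSE)
  })
  exdf <- do.call(rbind, exon_list)
  exons <- GenomicRanges::GRanges(
    exdf$chrom, IRanges::IRanges(exdf$start, exdf$end),
    strand = exdf$strand, gene_id = exdf$gene_id)
  tes <- GenomicRanges::GRanges(
    feat$chrom[te_rows],
    IRanges::IRanges(feat$start[te_rows], feat$end[te_rows]),
    strand = sample(c("+", "-"), length(te_rows), replace = TRUE),
    te_id = feat$id[te_rows], repName = feat$rep_name[te_rows],
    repFamily = te$rep_family[match(feat$rep_name[te_rows], te$rep_name)],
    repClass = te$rep_class[match(feat$rep_name[te_rows], te$rep_name)])
  ann <- genome_annotation(genes, exons, tes)

  # planted chimeric junctions: TE 3' end spliced onto a downstream exon
  junctions <- plant_junctions(config, feat, exdf, te_rows, gene_rows)

  # expression programs
  classes <- names(config$class_proportions)
  n_per <- floor(config$class_proportions * config$n_genes)
  left <- config$n_genes - sum(n_per)
  if (left > 0) {
    top <- order(config$class_proportions * config$n_genes - n_per,
                 decreasing = TRUE)[seq_len(left)]
    n_per[top] <- n_per[top] + 1L
  }
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  gene_classes <- stats::setNames(
    sample(rep(classes, n_per)), gene_ids)
  candidates <- gene_ids[gene_classes %in% c("ED", "EU")]
  ko_affected <- sort(sample(candidates,
                             round(config$ko_affected_fraction *
                                     length(candidates))))
  gene_base <- stats::setNames(stats::rlnorm(config$n_genes, log(200), 0.5),
                               gene_ids)

  # TE stage activity: ERVL members burst at 2-cell (zygotic), the MaLR-like
  # family decays (maternal), LINE/SINE stay flat
  prof <- matrix(1, nrow(te), length(config$stages),
                 dimnames = list(te$rep_name, config$stages))
  ervl <- te$rep_name[te$rep_family == "ERVL"]
  prof[ervl, ] <- rep(c(0.2, 1, 30), each = length(ervl))
  malr <- te$rep_name[te$rep_family == "ERVL-MaLR"]
  if (length(malr)) prof[malr, ] <- rep(c(3, 1.5, 0.3), each = length(malr))
  te_base <- stats::setNames(stats::rlnorm(length(te_rows), log(30), 0.4),
                             feat$id[te_rows])

  # mark junction KO response: junctions on zygotic TEs are dampened in KO
  junctions$ko_dampened <- junctions$te_id %in%
    feat$id[te_rows][feat$rep_name[te_rows] %in% ervl]

  layout <- list(
    exons = exdf[, c("chrom", "start", "end", "gene_id")],
    tes = data.frame(
      te_id = feat$id[te_rows], chrom = feat$chrom[te_rows],
      start = feat$start[te_rows], end = feat$end[te_rows],
      rep_name = feat$rep_name[te_rows],
      rep_family = te$rep_family[match(feat$rep_name[te_rows], te$rep_name)],
      rep_class = te$rep_class[match(feat$rep_name[te_rows], te$rep_name)],
      stringsAsFactors = FALSE))

  truth <- list(
    config = config,
    layout = layout,
    gene_classes = gene_classes,
    ko_affected = ko_affected,
    gene_base = gene_base,
    te_profile = prof,
    te_zygotic_elements = ervl,
    te_base = te_base,
    junctions = junctions,
    full_length = full_length,
    gag_query = gag_query,
    pol_query = pol_query,
    sirna_site = data.frame(te_id = full_length, mismatch = 0L,
                            stringsAsFactors = FALSE))
  list(genome = Biostrings::DNAStringSet(seqs), annotation = ann,
       truth = truth)
}

plant_junctions <- function(config, feat, exdf, te_rows, gene_rows) {
  n <- config$n_chimeric_junctions
  if (n == 0) {
    return(data.frame(junction_id = character(), te_id = character(),
                      gene_id = character(), te_chrom = character(),
                      te_end = integer(), gene_chrom = character(),
                      gene_start = integer(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  n_trl <- floor(n * config$translocated_fraction)
  n_split <- n - n_trl
  first_exon <- exdf[!duplicated(exdf$gene_id), , drop = FALSE]
  # same-chromosome candidates: a gene's first exon 100 bp - 60 kb downstream
  cand <- do.call(rbind, lapply(seq_along(te_rows), function(k) {
    i <- te_rows[k]
    ok <- first_exon$chrom == feat$chrom[i] &
      first_exon$start >= feat$end[i] + 100L &
      first_exon$start <= feat$end[i] + 60000L
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(first_exon$start[ok])]
    data.frame(te_id = feat$id[i], gene_id = first_exon$gene_id[j],
               te_chrom = feat$chrom[i], te_end = feat$end[i],
               gene_chrom = first_exon$chrom[j],
               gene_start = first_exon$start[j], stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < n_split) {
    stop(sprintf(
      "impossible geometry: only %d same-chromosome TE-gene junction sites available, %d requested",
      if (is.null(cand)) 0L else nrow(cand), n_split), call. = FALSE)
  }
  split_j <- cand[sample.int(nrow(cand), n_split), , drop = FALSE]
  split_j$kind <- "split_same_chromosome"
  out <- split_j
  if (n_trl > 0) {
    used <- split_j$te_id
    pool_te <- setdiff(feat$id[te_rows], used)
    trl <- do.call(rbind, lapply(seq_len(n_trl), function(q) {
      tid <- pool_te[q]
      i <- which(feat$id == tid)
      ok <- first_exon$chrom != feat$chrom[i]
      if (!any(ok)) {
        stop("impossible geometry: no cross-chromosome gene available for ",
             "translocated junctions", call. = FALSE)
      }
      j <- sample(which(ok), 1)
      data.frame(te_id = tid, gene_id = first_exon$gene_id[j],
                 te_chrom = feat$chrom[i], te_end = feat$end[i],
                 gene_chrom = first_exon$chrom[j],
                 gene_start = first_exon$start[j],
                 kind = "translocated", stringsAsFactors = FALSE)
    }))
    out <- rbind(out, trl)
  }
  out$junction_id <- sprintf("j%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("junction_id", "te_id", "gene_id", "te_chrom", "te_end",
          "gene_chrom", "gene_start", "kind")]
}

# stage/genotype mean multiplier for one gene, given its dynamics class
stage_means <- function(truth, genotype) {
  config <- truth$config
  f <- config$effect_size
  step <- function(m, call) {
    switch(call, E = m, U = m * f, D = m / f)
  }
  cls <- truth$gene_classes
  m1 <- rep(1, length(cls))
  m2 <- vapply(substr(cls, 1, 1), function(cc) step(1, cc), numeric(1))
  m3 <- m2 * vapply(seq_along(cls), function(i) {
    step(1, substr(cls[i], 2, 2))
  }, numeric(1))
  if (genotype == "KO") {
    aff <- names(cls) %in% truth$ko_affected
    damp <- aff & cls == "EU"     # dampened zygotic activation
    m3[damp] <- m3[damp] * config$ko_dampening
    keep <- aff & cls == "ED"     # retained maternal transcripts
    m3[keep] <- m2[keep]
  }
  mm <- cbind(m1, m2, m3)
  dimnames(mm) <- list(names(cls), config$stages)
  mm
}

#' Simulate gene-level counts
#'
#' Negative-binomial counts whose group means follow each gene's planted
#' dynamics class (fold `effect_size` per D/U transition); KO samples dampen
#' zygotic activation of affected EU genes by `ko_dampening` and retain the
#' maternal transcripts of affected ED genes at the 2-cell stage.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [generate_reference()].
#' @return a [count_matrix()] of genes by samples.
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  sheet <- sim_sample_sheet(config)
  withr::with_seed(config$seed + 1L, {
    libf <- stats::rlnorm(nrow(sheet), 0, 0.15)
    mm <- lapply(config$genotypes, function(gt) stage_means(truth, gt))
    names(mm) <- config$genotypes
    counts <- vapply(seq_len(nrow(sheet)), function(s) {
      mu <- truth$gene_base * mm[[sheet$genotype[s]]][, sheet$stage[s]] *
        libf[s]
      if (config$dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      }
    }, numeric(length(truth$gene_base)))
    dimnames(counts) <- list(names(truth$gene_base), sheet$sample)
    count_matrix(counts, sheet)
  })
}

#' Simulate single-end alignments with ground truth
#'
#' Emits, per sample: unique reads inside genes and TE copies (weighted by
#' the planted stage/genotype expression program), multi-mapped TE reads with
#' all alignments recorded and `NH` set to the multiplicity, spliced reads
#' (`kM nN mM` CIGARs) across each planted same-chromosome junction,
#' cross-chromosome read pairs for translocated junctions, and mitochondrial
#' reads at the configured fraction. Read names encode origin
#' (`sample|r#####|type|feature`) and a per-read truth table is returned.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [generate_reference()].
#' @return list with `alignments` (an [alignment_set()] over all samples),
#'   `read_truth` (data.frame: `read_id`, `sample`, `type`, `origin`,
#'   `ambiguity`), and `samples` (the sample sheet).
#' @export
simulate_alignments <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  sheet <- sim_sample_sheet(config)
  withr::with_seed(config$seed + 2L, {
    out <- lapply(seq_len(nrow(sheet)), function(s) {
      simulate_sample_alignments(config, truth, sheet$sample[s],
                                 sheet$stage[s], sheet$genotype[s])
    })
    alns <- alignment_set(do.call(rbind, lapply(out, `[[`, "alns")))
    read_truth <- do.call(rbind, lapply(out, `[[`, "truth"))
    rownames(read_truth) <- NULL
    list(alignments = alns, read_truth = read_truth, samples = sheet)
  })
}

simulate_sample_alignments <- function(config, truth, sample_id, stage,
                                       genotype) {
  rl <- config$read_length
  te <- config$te_elements
  te_ids <- names(truth$te_base)
  rep_name <- sub("_[0-9]+$", "", te_ids)

  # expression weights for this stage/genotype
  gene_w <- truth$gene_base * stage_means(truth, genotype)[, stage]
  te_w <- truth$te_base * truth$te_profile[rep_name, stage]
  if (genotype == "KO" && stage == utils::tail(config$stages, 1)) {
    z <- rep_name %in% truth$te_zygotic_elements
    te_w[z] <- te_w[z] * config$ko_dampening
  }
  mf <- config$mito_read_fraction
  if (!is.null(names(mf))) {
    mf <- if (sample_id %in% names(mf)) mf[[sample_id]] else 0.02
  }
  w <- c(gene_w, te_w)
  w <- c(w, MITO = if (mf > 0) mf / (1 - mf) * sum(w) else 0)

  n_reads <- stats::rpois(1, config$mean_library_size)
  alloc <- as.vector(stats::rmultinom(1, n_reads, w))
  names(alloc) <- names(w)

  lay <- truth$layout
  rows <- list()
  tr <- list()
  idx <- 0L
  nm <- function(type, origin) {
    idx <<- idx + 1L
    sprintf("%s|r%05d|%s|%s", sample_id, idx, type, origin)
  }

  # gene reads: uniform within a random exon
  for (g in names(truth$gene_base)) {
    k <- alloc[[g]]
    if (k == 0) next
    ex <- lay$exons[lay$exons$gene_id == g, , drop = FALSE]
    ex <- ex[ex$end - ex$start + 1L >= rl, , drop = FALSE]
    pick <- sample.int(nrow(ex), k, replace = TRUE)
    pos <- ex$start[pick] +
      floor(stats::runif(k) * (ex$end[pick] - ex$start[pick] - rl + 2L))
    ids <- vapply(seq_len(k), function(i) nm("uniq", g), character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = ids, sample = sample_id, flag = 0L, chrom = ex$chrom[pick],
      pos = as.integer(pos), cigar = sprintf("%dM", rl), nh = 1L,
      stringsAsFactors = FALSE)
    tr[[length(tr) + 1L]] <- data.frame(
      read_id = ids, sample = sample_id, type = "uniq", origin = g,
      ambiguity = NA_character_, stringsAsFactors = FALSE)
  }

  # TE reads: unique or multi-mapped
  tedf <- lay$tes
  for (t in te_ids) {
    k <- alloc[[t]]
    if (k == 0) next
    n_multi <- stats::rbinom(1, k, config$multi_map_fraction)
    n_uni <- k - n_multi
    row_t <- tedf[tedf$te_id == t, , drop = FALSE]
    if (n_uni > 0) {
      pos <- row_t$start +
        floor(stats::runif(n_uni) * (row_t$end - row_t$start - rl + 2L))
      ids <- vapply(seq_len(n_uni), function(i) nm("uniq", t), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = ids, sample = sample_id, flag = 0L, chrom = row_t$chrom,
        pos = as.integer(pos), cigar = sprintf("%dM", rl), nh = 1L,
        stringsAsFactors = FALSE)
      tr[[length(tr) + 1L]] <- data.frame(
        read_id = ids, sample = sample_id, type = "uniq", origin = t,
        ambiguity = NA_character_, stringsAsFactors = FALSE)
    }
    if (n_multi > 0) {
      for (q in seq_len(n_multi)) {
        mm <- multi_map_partners(tedf, row_t, te)
        partners <- rbind(row_t[, c("te_id", "chrom", "start", "end")],
                          mm$partners[, c("te_id", "chrom", "start", "end")])
        off <- floor(stats::runif(1) *
                       (min(partners$end - partners$start + 1L) - rl + 1L))
        id <- nm("multi", t)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = id, sample = sample_id,
          flag = c(0L, rep(256L, nrow(partners) - 1L)),
          chrom = partners$chrom,
          pos = as.integer(partners$start + off),
          cigar = sprintf("%dM", rl), nh = nrow(partners),
          stringsAsFactors = FALSE)
        tr[[length(tr) + 1L]] <- data.frame(
          read_id = id, sample = sample_id, type = "multi", origin = t,
          ambiguity = mm$kind, stringsAsFactors = FALSE)
      }
    }
  }

  # split / translocated reads over planted junctions
  jx <- truth$junctions
  if (nrow(jx)) {
    base_support <- c(0L, 1L, 5L)[match(stage, config$stages)]
    for (j in seq_len(nrow(jx))) {
      supp <- base_support
      if (genotype == "KO" && jx$ko_dampened[j] &&
          stage == utils::tail(config$stages, 1)) {
        supp <- max(1L, as.integer(round(supp * config$ko_dampening)))
      }
      if (supp == 0) next
      for (q in seq_len(supp)) {
        k <- sample(20:31, 1)
        m <- rl - k
        id <- nm(if (jx$kind[j] == "translocated") "trl" else "split",
                 jx$junction_id[j])
        if (jx$kind[j] == "translocated") {
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = id, sample = sample_id, flag = c(0L, 2048L),
            chrom = c(jx$te_chrom[j], jx$gene_chrom[j]),
            pos = as.integer(c(jx$te_end[j] - k + 1L, jx$gene_start[j])),
            cigar = c(sprintf("%dM%dS", k, m), sprintf("%dS%dM", k, m)),
            nh = 1L, stringsAsFactors = FALSE)
        } else {
          gap <- jx$gene_start[j] - jx$te_end[j] - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = id, sample = sample_id, flag = 0L,
            chrom = jx$te_chrom[j],
            pos = as.integer(jx$te_end[j] - k + 1L),
            cigar = sprintf("%dM%dN%dM", k, gap, m), nh = 1L,
            stringsAsFactors = FALSE)
        }
        tr[[length(tr) + 1L]] <- data.frame(
          read_id = id, sample = sample_id,
          type = if (jx$kind[j] == "translocated") "trl" else "split",
          origin = jx$junction_id[j], ambiguity = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }

  # mitochondrial reads
  k <- alloc[["MITO"]]
  if (k > 0) {
    pos <- 1L + floor(stats::runif(k) * (config$mito_length - rl))
    ids <- vapply(seq_len(k), function(i) nm("mito", "chrM"), character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = ids, sample = sample_id, flag = 0L, chrom = "chrM",
      pos = as.integer(pos), cigar = sprintf("%dM", rl), nh = 1L,
      stringsAsFactors = FALSE)
    tr[[length(tr) + 1L]] <- data.frame(
      read_id = ids, sample = sample_id, type = "mito", origin = "chrM",
      ambiguity = NA_character_, stringsAsFactors = FALSE)
  }

  list(alns = do.call(rbind, rows), truth = do.call(rbind, tr))
}

# choose multi-mapping partner copies for a home copy, by ambiguity kind
multi_map_partners <- function(tedf, row_t, te) {
  fam <- te$rep_family[match(row_t$rep_name, te$rep_name)]
  cls <- te$rep_class[match(row_t$rep_name, te$rep_name)]
  kind <- sample(c("same_element", "same_family", "same_class",
                   "cross_class"), 1, prob = c(0.5, 0.3, 0.15, 0.05))
  pool <- switch(kind,
    same_element = tedf[tedf$rep_name == row_t$rep_name &
                          tedf$te_id != row_t$te_id, , drop = FALSE],
    same_family = tedf[tedf$rep_family == fam &
                         tedf$rep_name != row_t$rep_name, , drop = FALSE],
    same_class = tedf[tedf$rep_class == cls &
                        tedf$rep_family != fam, , drop = FALSE],
    cross_class = tedf[tedf$rep_class != cls, , drop = FALSE])
  if (!nrow(pool)) {  # fall back to same-element homology
    kind <- "same_element"
    pool <- tedf[tedf$rep_name == row_t$rep_name &
                   tedf$te_id != row_t$te_id, , drop = FALSE]
  }
  n_extra <- min(nrow(pool), sample(1:2, 1))
  list(kind = kind,
       partners = pool[sample.int(nrow(pool), n_extra), , drop = FALSE])
}

#' Write the synthetic reference to disk
#'
#' Writes the genome FASTA, gene and TE GTFs, and tab-separated ground-truth
#' tables (gene classes, junctions, full-length copies). Output is
#' byte-deterministic for a fixed configuration.
#'
#' @param ref result of [generate_reference()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_reference <- function(ref, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(outdir, "genome.fa"))
  write_gene_gtf(ref$annotation$genes, ref$annotation$exons,
                 file.path(outdir, "genes.gtf"))
  write_te_gtf(ref$annotation$tes, file.path(outdir, "tes.gtf"))
  truth <- ref$truth
  utils::write.table(
    data.frame(gene_id = names(truth$gene_classes),
               class = unname(truth$gene_classes),
               ko_affected = names(truth$gene_classes) %in%
                 truth$ko_affected),
    file.path(outdir, "gene_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(truth$junctions, file.path(outdir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(truth$full_length, file.path(outdir, "full_length_te.txt"))
  invisible(outdir)
}
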