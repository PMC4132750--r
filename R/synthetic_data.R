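#' Specification for synthetic genome generation
#'
#' Defines the study conditions under which the pipeline is exercised and
#' calibrated: a background genome with a given (first-order Markov)
#' dinucleotide composition, phased AT-tract arrays implanted at period
#' `implant_period`, and protein-coding genes whose periodic AT2 bias is
#' carried preferentially by codon position III (and, more weakly, by the
#' correlated position I of the next codon).
#'
#' Implants are arrays ("clusters") of AT-tracts: within an array,
#' `tracts_per_array` tracts of `tract_length` bp are placed with
#' start-to-start spacing drawn as `implant_period + Normal(0,
#' phase_jitter)` rounded to integer bp, giving arrays of roughly 100 bp.
#' Arrays are dropped into the implant regions until `coverage` of the
#' region is covered. Each tract is drawn uniformly from the A/T strings of
#' its length whose internal dinucleotides all lie in AT2 (i.e. without a
#' TpA step): the strings A^j T^(m-j).
#'
#' @param genome_length genome length in bp (default 100000).
#' @param background 4x4 first-order Markov transition matrix over A,C,G,T
#'   (rows sum to 1) or NULL for uniform iid.
#' @param implant_period T0, the implant phasing period in bp (default 11).
#' @param tract_length AT-tract length in bp (default 4).
#' @param tracts_per_array tracts per phased array (default 9, spanning
#'   roughly 8 periods ~ 100 bp).
#' @param implant_regions list of length-2 numeric 0-based half-open
#'   intervals; NULL = whole genome.
#' @param phase_jitter SD (bp) of the Gaussian spacing jitter (default 0.3).
#' @param coverage fraction of implant-region bp covered by arrays
#'   (default 0.4).
#' @param n_genes number of genes for [generate_cds_set()] (default 100).
#' @param gene_length length-2 range (bp) from which gene body lengths are
#'   drawn uniformly, rounded to codons (default 450–900).
#' @param positionIII_bias probability that a codon position III inside a
#'   phased tract is set to extend the tract (default 0.8).
#' @param positionI_bias same for position I of the next codon (default
#'   0.4; weaker, as the coding signal is carried foremost by the
#'   synonymous third position).
#' @param positionII_bias same for position II (default 0.2; weakest, but
#'   non-zero — codon position II carries a substantial minority share of
#'   the periodic signal in coding regions).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(genome_length = 100000L, background = NULL,
                           implant_period = 11, tract_length = 4L,
                           tracts_per_array = 9L, implant_regions = NULL,
                           phase_jitter = 0.3, coverage = 0.4,
                           n_genes = 100L, gene_length = c(450L, 900L),
                           positionIII_bias = 0.8, positionI_bias = 0.4,
                           positionII_bias = 0.2, seed = 1L) {
  if (implant_period < 2 || implant_period > 15)
    stop("implant_period must lie in [2, 15] bp", call. = FALSE)
  if (coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1]", call. = FALSE)
  if (is.null(implant_regions))
    implant_regions <- list(c(0, genome_length))
  for (rg in implant_regions)
    if (rg[1] < 0 || rg[2] > genome_length || rg[2] <= rg[1])
      stop("implant region outside the genome: [", rg[1], ",", rg[2], ")",
           call. = FALSE)
  if (!is.null(background)) {
    background <- as.matrix(background)
    stopifnot(all(dim(background) == c(4L, 4L)))
    if (any(abs(rowSums(background) - 1) > 1e-8))
      stop("background transition rows must sum to 1", call. = FALSE)
  }
  structure(list(genome_length = as.integer(genome_length),
                 background = background, implant_period = implant_period,
                 tract_length = as.integer(tract_length),
                 tracts_per_array = as.integer(tracts_per_array),
                 implant_regions = implant_regions,
                 phase_jitter = phase_jitter, coverage = coverage,
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 positionIII_bias = positionIII_bias,
                 positionI_bias = positionI_bias,
                 positionII_bias = positionII_bias,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Markov (or uniform iid) background as a character vector of bases
sample_background <- function(L, background) {
  if (is.null(background))
    return(c("A", "C", "G", "T")[sample.int(4L, L, replace = TRUE)])
  cum <- t(apply(background, 1L, cumsum))
  out <- integer(L)
  out[1L] <- sample.int(4L, 1L)
  u <- runif(L)
  for (i in 2:L) {
    r <- cum[out[i - 1L], ]
    out[i] <- findInterval(u[i], r, left.open = TRUE) + 1L
  }
  c("A", "C", "G", "T")[out]
}

# uniform draw from the AT2-internal tract strings A^j T^(m-j)
sample_tract <- function(m) {
  j <- sample.int(m + 1L, 1L) - 1L
  c(rep("A", j), rep("T", m - j))
}

#' Generate a synthetic genome with implanted phased AT-tracts
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (a [genome_sequence()]) and `truth` (feature
#'   data.frame of the implanted array intervals, 0-based half-open).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    chars <- sample_background(spec$genome_length, spec$background)
    truth <- NULL
    span <- as.integer(ceiling((spec$tracts_per_array - 1L) *
                                 spec$implant_period) + spec$tract_length)
    for (rg in spec$implant_regions) {
      rlen <- rg[2] - rg[1]
      n_arr <- floor(spec$coverage * rlen / span)
      if (n_arr < 1L) next
      # partition the slack into n_arr + 1 random gaps
      slack <- rlen - n_arr * span
      g <- rexp(n_arr + 1L)
      gaps <- floor(slack * cumsum(g) / sum(g))
      starts <- rg[1] + gaps[seq_len(n_arr)] + (seq_len(n_arr) - 1L) * span
      for (s0 in starts) {
        pos <- s0
        arr_end <- s0
        for (j in seq_len(spec$tracts_per_array)) {
          tr <- sample_tract(spec$tract_length)
          if (pos + spec$tract_length > rg[2]) break
          chars[(pos + 1L):(pos + spec$tract_length)] <- tr
          arr_end <- pos + spec$tract_length
          pos <- pos + round(spec$implant_period +
                               rnorm(1L, 0, spec$phase_jitter))
        }
        truth <- rbind(truth, data.frame(start = s0, end = arr_end))
      }
    }
    truth <- if (is.null(truth)) feature_frame() else
      feature_frame(seq_id = rep("synthetic", nrow(truth)),
                    start = truth$start, end = truth$end,
                    strand = rep(".", nrow(truth)),
                    kind = rep("implant", nrow(truth)),
                    id = sprintf("implant%d", seq_len(nrow(truth))))
    list(genome = genome_sequence("synthetic", paste(chars, collapse = "")),
         truth = truth)
  })
}

#' Generate a synthetic CDS set with codon-position-encoded periodicity
#'
#' Genes are sampled codon-wise on a background genome: every gene starts
#' with ATG, ends with a single stop codon, and carries no internal stop.
#' Along each gene, phased AT-tract windows track the implant period; inside
#' such a window, codon position III is set to extend an AT2 tract with
#' probability `positionIII_bias` and position I with `positionI_bias`,
#' while position II is never touched (any stop codon created by the biased
#' bases is repaired at position II). Genes are placed on alternating
#' strands with random intergenic gaps.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `cds` (named list of [cds_record()], genome order,
#'   coding strand), `genome` (the assembled [genome_sequence()]),
#'   `features` (CDS feature data.frame), and `truth` (per-gene parameter
#'   table).
#' @export
generate_cds_set <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed + 1L, {
    cds <- list()
    pieces <- character(0)
    feats <- NULL
    pos <- 0L
    non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
    for (g in seq_len(spec$n_genes)) {
      lo <- spec$gene_length[1] %/% 3L
      hi <- spec$gene_length[2] %/% 3L
      n_cod <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      body <- sample(non_stop, n_cod - 2L, replace = TRUE)
      chars <- strsplit(paste0("ATG", paste(body, collapse = "")), "")[[1L]]
      chars <- bias_gene(chars, spec)
      gene <- paste0(paste(chars, collapse = ""),
                     sample(c("TAA", "TAG", "TGA"), 1L))
      gid <- sprintf("g%03d", g)
      cds[[gid]] <- cds_record(gid, gene)
      gap <- sample(50:200, 1L)
      strand <- if (g %% 2L == 0L) "-" else "+"
      genomic <- if (strand == "-") revcomp(gene) else gene
      pieces <- c(pieces,
                  paste(sample_background(gap, spec$background), collapse = ""),
                  genomic)
      start <- pos + gap
      feats <- rbind(feats, feature_frame(
        seq_id = "cds_synthetic", start = start, end = start + nchar(gene),
        strand = strand, kind = "CDS", id = gid))
      pos <- start + nchar(gene)
    }
    tail_gap <- paste(sample_background(100L, spec$background), collapse = "")
    genome <- genome_sequence("cds_synthetic",
                              paste(c(pieces, tail_gap), collapse = ""))
    truth <- data.frame(gene_id = names(cds),
                        length = vapply(cds, function(x) x$length, numeric(1)),
                        strand = feats$strand,
                        positionIII_bias = spec$positionIII_bias,
                        positionI_bias = spec$positionI_bias,
                        positionII_bias = spec$positionII_bias,
                        row.names = NULL)
    list(cds = cds, genome = genome, features = feats, truth = truth)
  })
}

# Apply the phased position-I/III AT2 bias to a gene's character vector
# (start codon included, stop codon not yet appended). Positions are 1-based
# within the gene; codon position = ((q - 1) %% 3) + 1.
bias_gene <- function(chars, spec) {
  L <- length(chars)
  T0 <- spec$implant_period
  m <- spec$tract_length
  # phased tract windows along the gene, skipping the start codon
  anchors <- round(seq(4, L - m, by = T0) +
                     cumsum(rnorm(length(seq(4, L - m, by = T0)), 0,
                                  spec$phase_jitter)))
  for (a in anchors) {
    if (is.na(a) || a < 4L || a + m - 1L > L) next
    for (q in a:(a + m - 1L)) {
      cp <- (q - 1L) %% 3L + 1L
      pr <- if (cp == 3L) spec$positionIII_bias
            else if (cp == 1L) spec$positionI_bias
            else spec$positionII_bias
      if (pr > 0 && runif(1L) < pr)
        chars[q] <- if (q > 1L && chars[q - 1L] == "T") "T"
                    else sample(c("A", "T"), 1L)
    }
  }
  # repair any stop codon created by the bias, at the untouched position II
  for (c0 in seq(4L, L - 2L, by = 3L)) {
    cod <- paste(chars[c0:(c0 + 2L)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) chars[c0 + 1L] <- "C"
  }
  chars
}

#' Write a synthetic fixture to disk
#'
#' Emits the implant genome (`genome.fa`, truth intervals in
#' `implants.tsv`), the coding-sequence genome (`cds_genome.fa`,
#' `cds.gff3`) and the per-gene truth table (`genes.tsv`), all readable by
#' the package's own readers. Regeneration from the same spec is
#' byte-identical.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
emit_fixture <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(spec)
  cset <- generate_cds_set(spec)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             implants = file.path(out_dir, "implants.tsv"),
             cds_genome = file.path(out_dir, "cds_genome.fa"),
             gff = file.path(out_dir, "cds.gff3"),
             genes = file.path(out_dir, "genes.tsv"))
  write_fasta(list(gen$genome), paths["genome"])
  con <- file(paths["implants"], "w")
  writeLines(output_header(list(implant_period = spec$implant_period,
                                coverage = spec$coverage, seed = spec$seed)),
             con)
  suppressWarnings(write.table(gen$truth, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  write_fasta(list(cset$genome), paths["cds_genome"])
  write_gff3(cset$features,
             stats::setNames(cset$genome$length, cset$genome$id),
             paths["gff"])
  con <- file(paths["genes"], "w")
  writeLines(output_header(list(n_genes = spec$n_genes, seed = spec$seed)), con)
  suppressWarnings(write.table(cset$truth, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(paths)
}

#' Default benchmark fixture specification
#'
#' The standard end-to-end test conditions: a 100 kb genome with period-11
#' AT-tract arrays implanted in three 10 kb regions at 40% coverage, so
#' that localization can be scored against known truth with substantial
#' background sequence.
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
default_fixture_spec <- function(seed = 1L) {
  synthetic_spec(implant_regions = list(c(10000, 20000), c(40000, 50000),
                                        c(70000, 80000)),
                 seed = seed)
}

#' Precision/recall of a scan against truth implant intervals
#'
#' Window-level scores for truth-guided localization: a window is a truth
#' window if it overlaps any truth interval; precision is the fraction of
#' significant windows that are truth windows, recall the fraction of truth
#' windows that are significant.
#'
#' @param scan a `genome_scan` object.
#' @param truth feature data.frame of truth intervals (0-based half-open).
#' @param alpha significance threshold (defaults to the scan's own).
#' @param use selection rule, as in [build_segments()].
#' @return named numeric vector: `precision`, `recall`, `n_significant`,
#'   `n_truth_windows`.
#' @export
localization_scores <- function(scan, truth, alpha = scan$params$alpha,
                                use = c("raw", "window")) {
  use <- match.arg(use)
  w <- scan$windows
  pcol <- if (use == "window") w$p_window else w$p_min
  sig <- !is.na(pcol) & pcol < alpha
  wr <- IRanges::IRanges(w$start + 1L, w$end)
  tr <- as_iranges(truth)
  is_truth <- IRanges::overlapsAny(wr, tr)
  precision <- if (any(sig)) mean(is_truth[sig]) else NA_real_
  recall <- if (any(is_truth)) mean(sig[is_truth]) else NA_real_
  c(precision = precision, recall = recall,
    n_significant = sum(sig), n_truth_windows = sum(is_truth))
}
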