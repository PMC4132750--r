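#' Per-genome periodicity report
#'
#' For each genome: the signal-to-noise ratio Q*_SNR (10–12 bp band) of
#' every built-in motif (the 16 dinucleotides, WW and AT2), the full AT2
#' spectrum, and the AT2 peak period. With two or more genomes the
#' species-by-motif SNR matrix is clustered (Ward for genomes, complete
#' linkage for motifs).
#'
#' @param genomes list of `GenomeSequence` objects (e.g. [read_fasta()]).
#' @param out_dir output directory for TSV reports, or NULL to skip writing.
#' @param motifs motif names to profile.
#' @param k_species number of species clusters when clustering (default 4);
#'   used only with more genomes than `k_species`.
#' @inheritParams periodicity
#' @return invisibly, a list with `snr` (genome x motif matrix), `peaks`
#'   (named vector of AT2 peak periods), `species_clusters`,
#'   `motif_clusters`, `files`.
#' @export
run_genome_report <- function(genomes, out_dir = NULL,
                              motifs = builtin_motifs(), k_species = 4L,
                              k_min = 30L, k_max = 101L,
                              periods = default_period_grid(), smooth = 3L,
                              snr_band = c(10, 12)) {
  if (!length(genomes)) stop("no input genomes", call. = FALSE)
  if (inherits(genomes, "GenomeSequence")) genomes <- list(genomes)
  ids <- vapply(genomes, function(g) g$id, character(1))
  snr <- matrix(NA_real_, length(genomes), length(motifs),
                dimnames = list(ids, motifs))
  peaks <- stats::setNames(rep(NA_real_, length(genomes)), ids)
  files <- character()
  for (i in seq_along(genomes)) {
    for (m in motifs) {
      fit <- periodicity(genomes[[i]], m, k_min, k_max, periods, smooth,
                         snr_band)
      snr[i, m] <- fit$spectrum$snr
      if (m == "AT2") {
        peaks[i] <- fit$spectrum$peak_period
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, sprintf("%s_AT2_spectrum.tsv", ids[i]))
          write_tsv_report(data.frame(period = fit$spectrum$period,
                                      qstar = fit$spectrum$qstar), f,
                           list(genome = ids[i], motif = "AT2",
                                k_min = k_min, k_max = k_max))
          files <- c(files, f)
        }
      }
    }
  }
  species_clusters <- motif_clusters <- NULL
  if (length(genomes) > k_species) {
    species_clusters <- cluster_profiles(snr, "ward", k_species)
    motif_clusters <- cluster_profiles(t(snr), "complete",
                                       min(4L, length(motifs)))
  }
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "snr_matrix.tsv")
    write_tsv_report(data.frame(genome = rownames(snr), snr,
                                peak_AT2 = peaks, check.names = FALSE), f,
                     list(band = snr_band))
    files <- c(files, f)
  }
  invisible(list(snr = snr, peaks = peaks,
                 species_clusters = species_clusters,
                 motif_clusters = motif_clusters, files = files))
}

#' Full genome-to-enrichment pipeline
#'
#' Chains the package stages on one genome: (1) genome spectrum report,
#' (2) windowed permutation scan, (3) periodic segment building,
#' (4) Jaccard overlap tests of each segment set against CDS and intergenic
#' intervals, (5) codon-permutation Q' on the annotated CDS, (6) per-CDS
#' spectra, top-N selection and clustering — and, when gene-level label
#' sets are supplied, (7) hypergeometric enrichment of the CDS clusters.
#' Every stage's table is written to `out_dir` and listed in
#' `manifest.tsv` together with the parameters and seed.
#'
#' @param genome a `GenomeSequence`.
#' @param annotation list with `features` and `cds` as returned by
#'   [read_annotation()] (or by [generate_cds_set()]).
#' @param out_dir output directory.
#' @param labels optional named vector (gene id -> group) for enrichment.
#' @param motif motif name (default AT2).
#' @param width,n_perm,alpha,ranges scan parameters (see [scan_genome()]).
#' @param T_probe,n_reps Q' parameters (see [q_prime()]).
#' @param top_n,k_clusters CDS clustering parameters.
#' @param n_perm_jaccard relocations for the Jaccard tests.
#' @param seed master seed; stage seeds are derived from it.
#' @return invisibly, a list with the stage results and `manifest`.
#' @export
run_full_pipeline <- function(genome, annotation, out_dir, labels = NULL,
                              motif = "AT2", width = 200L, n_perm = 1000L,
                              alpha = 0.01, ranges = default_period_ranges(),
                              T_probe = 11.8, n_reps = 50L, top_n = 1000L,
                              k_clusters = 14L, n_perm_jaccard = 999L,
                              seed = 1L) {
  stopifnot(inherits(genome, "GenomeSequence"))
  if (!length(annotation$cds))
    stop("stage codon_permutation: no CDS in the annotation", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  log_stage <- function(stage, file, params) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(file),
      params = paste(names(params), unlist(params), sep = "=",
                     collapse = " "), stringsAsFactors = FALSE))
  }

  report <- run_genome_report(list(genome), out_dir, motifs = c(motif))
  log_stage("spectrum", "snr_matrix.tsv", list(motif = motif))

  scan <- scan_genome(genome, motif, width, n_perm, alpha, seed,
                      ranges = ranges)
  f <- file.path(out_dir, "windows.tsv")
  write_tsv_report(scan$windows, f,
                   list(width = width, n_perm = n_perm, seed = seed))
  log_stage("scan", f, list(width = width, n_perm = n_perm, seed = seed))

  f <- file.path(out_dir, "segments.bed")
  seg <- scan$segments
  write_bed(data.frame(seq_id = seg$seq_id, start = seg$start, end = seg$end,
                       id = seg$range_label), f, list(alpha = alpha))
  log_stage("segments", f, list(alpha = alpha))

  cdsf <- annotation$features[annotation$features$kind == "CDS", , drop = FALSE]
  inter <- intergenic_complement(annotation$features, genome$length,
                                 seq_id = genome$id)
  overlaps <- NULL
  for (lab in unique(seg$range_label)) {
    q <- seg[seg$range_label == lab, , drop = FALSE]
    for (ref_name in c("CDS", "intergenic")) {
      ref <- if (ref_name == "CDS") cdsf else inter
      jt <- jaccard_permutation_test(q, ref, genome$length,
                                     n_perm = n_perm_jaccard,
                                     seed = seed + 101L)
      overlaps <- rbind(overlaps, data.frame(
        range = lab, reference = ref_name, jaccard = jt$observed,
        p_value = jt$p_value, direction = jt$direction,
        stringsAsFactors = FALSE))
    }
  }
  f <- file.path(out_dir, "jaccard.tsv")
  write_tsv_report(overlaps, f, list(n_perm = n_perm_jaccard))
  log_stage("jaccard", f, list(n_perm = n_perm_jaccard))

  qp <- q_prime(annotation$cds, T_probe = T_probe, n_reps = n_reps,
                seed = seed + 202L, motif = motif)
  f <- file.path(out_dir, "qprime.tsv")
  write_tsv_report(qp$reps, f, list(T_probe = T_probe, n_reps = n_reps,
                                    seed = seed + 202L))
  log_stage("codon_permutation", f, list(T_probe = T_probe, n_reps = n_reps))

  spectra <- per_cds_spectra(annotation$cds, motif)
  clustered <- NULL
  if (nrow(spectra$mat) >= 2L) {
    top <- select_top_periodic(spectra, n = top_n)
    clustered <- cluster_cds_spectra(top, k = min(k_clusters, nrow(top$mat)))
    f <- file.path(out_dir, "cds_clusters.tsv")
    write_tsv_report(data.frame(gene_id = rownames(clustered$mat),
                                cluster = unname(clustered$cluster),
                                T_max = unname(clustered$T_max)),
                     f, list(top_n = top_n, k = k_clusters))
    log_stage("cds_cluster", f, list(top_n = top_n, k = k_clusters))
  } else {
    log_stage("cds_cluster", "skipped", list(reason = "fewer than 2 CDS rows"))
  }

  enrichment <- NULL
  if (!is.null(labels) && !is.null(clustered)) {
    universe <- vapply(annotation$cds, function(x) x$gene_id, character(1))
    enrichment <- hypergeom_enrichment(universe, clustered$cluster,
                                       labels[names(labels) %in% universe])
    f <- file.path(out_dir, "enrichment.tsv")
    write_tsv_report(enrichment, f, list())
    log_stage("enrichment", f, list())
  }

  f <- file.path(out_dir, "manifest.tsv")
  write_tsv_report(manifest, f, list(seed = seed))
  invisible(list(report = report, scan = scan, overlaps = overlaps,
                 qprime = qp, clusters = clustered, enrichment = enrichment,
                 manifest = manifest))
}

write_tsv_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}
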