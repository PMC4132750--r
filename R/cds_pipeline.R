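# Indicator track of a CDS concatenation: per-CDS tracks joined with a 0 at
# every junction, which is exactly the track of the concatenated sequence with
# junction-spanning dinucleotides masked (no spurious matches across genes).
concat_cds_track <- function(cds_list, motif = "AT2") {
  if (!length(cds_list)) stop("empty CDS list", call. = FALSE)
  tracks <- lapply(cds_list, function(cds)
    indicator_track(cds_string(cds), motif)$values)
  n <- length(tracks)
  if (n == 1L) return(new_track(tracks[[1L]]))
  joined <- vector("list", 2L * n - 1L)
  joined[seq(1L, 2L * n - 1L, by = 2L)] <- tracks
  joined[seq(2L, 2L * n - 2L, by = 2L)] <- list(0L)
  new_track(unlist(joined, use.names = FALSE))
}

#' Periodicity spectrum of concatenated coding sequences
#'
#' Concatenates the CDS (genome order, coding-strand orientation), masks
#' indicator positions spanning gene junctions, and computes the motif
#' periodicity spectrum over lags `k_min`..`k_max`.
#'
#' @param cds_list list of [cds_record()] objects (or plain CDS strings).
#' @inheritParams periodicity
#' @return a `periodicity` object (see [periodicity()]).
#' @export
concatenated_cds_spectrum <- function(cds_list, motif = "AT2", k_min = 30L,
                                      k_max = 101L,
                                      periods = default_period_grid(),
                                      smooth = 3L, snr_band = c(10, 12)) {
  track <- concat_cds_track(cds_list, motif)
  periodicity_from_track(track, motif, k_min, k_max, periods, smooth, snr_band)
}

# Unnormalized band power P(T) of a CDS concatenation at the probe periods.
# On the "covariance" scale the smoothed ACF is multiplied back by p_hat^2,
# i.e. the power of the raw motif co-occurrence rate: permutation schemes
# that change the motif density (synonymous replacement does) are then
# compared on a common absolute scale instead of being rescaled by their own
# density denominator.
concat_power_at <- function(cds_list, motif, T_probe, k_min, k_max, smooth,
                            scale = c("covariance", "density")) {
  scale <- match.arg(scale)
  track <- concat_cds_track(cds_list, motif)
  if (track$p_hat == 0) return(rep(0, length(T_probe)))
  acf <- smooth_acf(motif_acf(track, k_hi = k_max), smooth)
  cbar <- acf$smoothed[k_min:k_max]
  if (scale == "covariance") cbar <- cbar * track$p_hat^2
  spectrum_power(cbar, k_min, k_max, T_probe)
}

#' Q': codon-permutation attenuation of the coding periodicity signal
#'
#' Measures where in the codon the periodic signal is written: the
#' unnormalized band power P(T) of the concatenated CDS at the probe period
#' (default 11.8 bp) is computed before and after applying a codon
#' permutation scheme per CDS, and Q' = P_after / P_before is reported per
#' replicate (mean and range over `n_reps`, default 50). Unnormalized power
#' is used so genuine attenuation is not cancelled by the unit-mean
#' re-normalization of Q*; by default it is measured on the covariance
#' scale (the smoothed ACF multiplied back by the squared motif density),
#' so schemes that shift the motif density — synonymous replacement lowers
#' it — are compared on a common absolute scale rather than each rescaled
#' by its own density denominator (`scale = "density"` ratios the power of
#' the density-normalized ACF instead). A signal encoded at codon position
#' III collapses under codon-order shuffling and synonymous replacement but
#' survives position-II permutation.
#'
#' @param cds_list list of [cds_record()] objects.
#' @param schemes permutation schemes to evaluate (see
#'   [permutation_schemes()]); `"identity"` is allowed and yields Q' = 1.
#' @param T_probe probe period in bp (default 11.8; set near the species
#'   peak).
#' @param n_reps permutation replicates per scheme (default 50).
#' @param seed integer seed.
#' @param scale `"covariance"` (default) or `"density"`; see Details.
#' @inheritParams periodicity
#' @return object of class `qprime`: list with `T_probe`, `Q_before`,
#'   `reps` (data.frame scheme/rep/Q_after/Q_prime) and `summary`
#'   (data.frame scheme/mean/min/max).
#' @export
q_prime <- function(cds_list, schemes = permutation_schemes(),
                    T_probe = 11.8, n_reps = 50L, seed = 1L, motif = "AT2",
                    k_min = 30L, k_max = 101L, smooth = 3L,
                    scale = c("covariance", "density")) {
  scale <- match.arg(scale)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  before <- concat_power_at(cds_list, motif, T_probe, k_min, k_max, smooth,
                            scale)
  if (before < 1e-300)
    stop("degenerate concatenated spectrum at the probe period", call. = FALSE)
  rows <- NULL
  for (sc in schemes) {
    for (r in seq_len(n_reps)) {
      after <- if (sc == "identity") before else
        with_seed(seed + 7919L * match(sc, schemes) + r, {
          perm <- lapply(cds_list, apply_scheme, scheme = sc, seed = NULL)
          concat_power_at(perm, motif, T_probe, k_min, k_max, smooth, scale)
        })
      rows <- rbind(rows, data.frame(scheme = sc, rep = r, Q_after = after,
                                     Q_prime = after / before,
                                     stringsAsFactors = FALSE))
    }
  }
  summ <- do.call(rbind, lapply(split(rows, rows$scheme)[unique(rows$scheme)],
    function(d) data.frame(scheme = d$scheme[1L], mean = mean(d$Q_prime),
                           min = min(d$Q_prime), max = max(d$Q_prime),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(T_probe = T_probe, Q_before = before, reps = rows,
                 summary = summ[match(schemes, summ$scheme), , drop = FALSE],
                 n_reps = n_reps),
            class = "qprime")
}

#' @export
print.qprime <- function(x, ...) {
  cat(sprintf("Codon-permutation attenuation at T = %.1f bp (%d reps)\n",
              x$T_probe, x$n_reps))
  cat(sprintf("  P(T) before permutation: %.4g\n", x$Q_before))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-13s Q' = %.3f  [%.3f, %.3f]\n",
                s$scheme[i], s$mean[i], s$min[i], s$max[i]))
  invisible(x)
}

#' Per-CDS periodicity spectra
#'
#' One normalized spectrum row per coding sequence. CDS shorter than
#' `min_len` (default 300 bp; the ACF needs support out to lag 101) and CDS
#' with no motif match are excluded.
#'
#' @param cds_list list of [cds_record()] objects.
#' @inheritParams periodicity
#' @param min_len minimum CDS length in bp.
#' @return object of class `CdsSpectraMatrix`: list with `mat` (rows = CDS
#'   ids, cols = periods, values Q*), `period`, `T_max` (per-row peak
#'   period), `cluster` (NULL until [cluster_cds_spectra()]).
#' @export
per_cds_spectra <- function(cds_list, motif = "AT2", min_len = 300L,
                            k_min = 30L, k_max = 101L,
                            periods = default_period_grid(), smooth = 3L) {
  keep <- list()
  for (cds in cds_list) {
    s <- cds_string(cds)
    if (nchar(s) < min_len) next
    track <- indicator_track(s, motif)
    if (track$p_hat == 0 || length(track$values) <= k_max) next
    sp <- power_spectrum(smooth_acf(motif_acf(track, k_hi = k_max), smooth),
                         k_min, k_max, periods)
    if (sp$degenerate) next
    id <- if (inherits(cds, "CdsRecord")) cds$gene_id else
      sprintf("cds%d", length(keep) + 1L)
    keep[[id]] <- sp
  }
  if (!length(keep)) {
    message("no CDS passed the length/degeneracy filters")
    mat <- matrix(numeric(), 0L, length(periods))
  } else {
    mat <- do.call(rbind, lapply(keep, function(sp) sp$qstar))
    rownames(mat) <- names(keep)
  }
  colnames(mat) <- format(periods)
  structure(list(mat = mat, period = periods,
                 T_max = vapply(keep, function(sp) sp$peak_period, numeric(1)),
                 power_total = vapply(keep, function(sp) sum(sp$power),
                                      numeric(1)),
                 cluster = NULL, cluster_T_max = NULL),
            class = "CdsSpectraMatrix")
}

#' Select the most periodic coding sequences
#'
#' Ranks CDS by their maximal unnormalized band power within a period band
#' (default 9.5–13.5 bp) and keeps the top `n` (all, if fewer); exact ties
#' break by CDS id so the ranking is stable under row reordering. Absolute
#' power is used because the unit-mean normalization of Q* erases the
#' amplitude difference between a genuinely periodic CDS and a flat one
#' whose little power happens to concentrate at one period.
#'
#' @param x a `CdsSpectraMatrix` from [per_cds_spectra()].
#' @param n number of CDS to keep (default 1000).
#' @param band ranking band in bp.
#' @return the subsetted `CdsSpectraMatrix`, rows in rank order, with the
#'   ranking score attached as `score`.
#' @export
select_top_periodic <- function(x, n = 1000L, band = c(9.5, 13.5)) {
  stopifnot(inherits(x, "CdsSpectraMatrix"))
  sel <- x$period >= band[1] & x$period <= band[2]
  # max Q* in band times total power / grid size == max unnormalized P in band
  score <- apply(x$mat[, sel, drop = FALSE], 1L, max) *
    x$power_total / ncol(x$mat)
  ord <- order(-score, rownames(x$mat))
  keep <- ord[seq_len(min(n, length(ord)))]
  structure(list(mat = x$mat[keep, , drop = FALSE], period = x$period,
                 T_max = x$T_max[keep], power_total = x$power_total[keep],
                 cluster = NULL, cluster_T_max = NULL,
                 score = score[keep]),
            class = "CdsSpectraMatrix")
}

#' Cluster coding sequences by spectral shape
#'
#' Ward clustering (Euclidean distance on the Q* rows) of a per-CDS spectra
#' matrix into `k` clusters (default 14); each cluster is assigned a main
#' period `T_max` — the peak of its mean spectrum — so clusters can be
#' pooled into period ranges for downstream enrichment profiling.
#'
#' @param x a `CdsSpectraMatrix`.
#' @param k number of clusters.
#' @return the matrix object with `cluster` (named labels) and
#'   `cluster_T_max` (data.frame cluster/n/T_max) filled in.
#' @export
cluster_cds_spectra <- function(x, k = 14L) {
  stopifnot(inherits(x, "CdsSpectraMatrix"))
  labels <- cluster_profiles(x$mat, "ward", k_cut = k)
  x$cluster <- labels
  x$cluster_T_max <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    rows <- x$mat[labels == cl, , drop = FALSE]
    m <- colMeans(rows)
    data.frame(cluster = cl, n = nrow(rows),
               T_max = x$period[which.max(m)])
  }))
  x
}

#' @export
print.CdsSpectraMatrix <- function(x, ...) {
  cat(sprintf("Per-CDS periodicity spectra: %d CDS x %d periods (%.1f-%.1f bp)\n",
              nrow(x$mat), length(x$period), min(x$period), max(x$period)))
  if (!is.null(x$cluster)) {
    cat(sprintf("  clustered into %d groups; main periods:\n",
                length(unique(x$cluster))))
    print(x$cluster_T_max, row.names = FALSE)
  }
  invisible(x)
}
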