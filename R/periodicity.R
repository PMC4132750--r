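#' Motif indicator track
#'
#' Converts a nucleotide sequence into the binary occurrence process of a
#' dinucleotide motif set: `values[i]` is 1 iff the dinucleotide starting at
#' position i (1-based) belongs to the set. Any dinucleotide touching an N is
#' a non-match. This track is the input to all autocorrelation and spectral
#' statistics.
#'
#' @param seq a `GenomeSequence`, or a character scalar over \{A,C,G,T,N\}
#'   (lowercase and ambiguity codes are masked to N).
#' @param motif a [motif_set()] or motif name.
#' @return an object of class `IndicatorTrack`: list with `values` (integer
#'   0/1 vector of length `nchar(seq) - 1`), `n_matches`, and the match
#'   density `p_hat = n_matches / length(values)`.
#' @examples
#' indicator_track("AATG", "AT2")   # AA, AT match; TG does not
#' @export
indicator_track <- function(seq, motif = "AT2") {
  s <- as_seq_string(seq)
  if (nchar(s) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  codes <- encode_seq(s)
  mm <- motif_matrix(motif)
  v <- as.integer(mm[cbind(codes[-length(codes)] + 1L, codes[-1L] + 1L)])
  new_track(v)
}

new_track <- function(values) {
  structure(list(values = as.integer(values),
                 n_matches = sum(values),
                 p_hat = mean(values)),
            class = "IndicatorTrack")
}

#' Motif autocorrelation function
#'
#' The lag-k autocorrelation of a motif indicator track, normalized by the
#' squared motif density so that 1 is the no-correlation baseline:
#' \deqn{C(k) = \frac{1}{(M-k)\,\hat p^2} \sum_{i=1}^{M-k} x_i x_{i+k}}
#' with M the track length. Values above 1 indicate co-occurrence of motif
#' positions at spacing k beyond what composition alone predicts.
#'
#' @param track an `IndicatorTrack` (or a sequence, converted with the
#'   default AT2 motif).
#' @param k_hi largest lag in bp; must be smaller than the track length.
#' @param motif motif used when `track` is a raw sequence.
#' @return an `AcfProfile`: list with `lags` (1..k_hi), `raw` C(k),
#'   `smoothed` (NULL until [smooth_acf()]), and `p_hat`.
#' @export
motif_acf <- function(track, k_hi = 101L, motif = "AT2") {
  if (!inherits(track, "IndicatorTrack")) track <- indicator_track(track, motif)
  x <- track$values
  M <- length(x)
  if (M <= k_hi) stop("track length must exceed k_hi", call. = FALSE)
  if (track$p_hat == 0)
    stop("degenerate track: no motif matches (p_hat = 0)", call. = FALSE)
  raw <- acf_raw_cpp(as.numeric(x), as.integer(k_hi)) / track$p_hat^2
  structure(list(lags = seq_len(k_hi), raw = raw, smoothed = NULL,
                 p_hat = track$p_hat),
            class = "AcfProfile")
}

#' Smooth an autocorrelation profile
#'
#' Centered moving average of width `width` bp (default 3), suppressing the
#' strong 3 bp codon-frame contribution of coding regions; edges use the
#' truncated window.
#'
#' @param profile an `AcfProfile` from [motif_acf()].
#' @param width odd window width in bp.
#' @return the profile with `smoothed` filled in.
#' @export
smooth_acf <- function(profile, width = 3L) {
  stopifnot(inherits(profile, "AcfProfile"))
  if (width %% 2L != 1L) stop("smoothing width must be odd", call. = FALSE)
  profile$smoothed <- running_mean(profile$raw, width)
  profile
}

# centered moving average, truncated at the edges
running_mean <- function(x, width) {
  if (width == 1L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Normalized period power spectrum of a smoothed ACF
#'
#' Evaluates the power of the mean-subtracted smoothed ACF on a continuous
#' period grid (not DFT bins, so non-integer peak periods such as 11.4 bp are
#' resolvable): with \eqn{m} the mean of \eqn{\bar C(k)} over
#' \eqn{k \in [k_{min}, k_{max}]} and \eqn{n_k} the number of lags,
#' \deqn{P(T) = \frac{1}{n_k}\left|\sum_k (\bar C(k) - m)\, e^{2\pi i k / T}\right|^2}
#' and the normalized spectrum \eqn{Q^*(T) = P(T)\,|grid| / \sum_{T'} P(T')},
#' which has unit mean over the grid. Lags below `k_min` (default 30 bp) are
#' excluded to suppress short-range signals from amphipathic alpha-helices.
#' If the total power is below `eps` the spectrum is degenerate and
#' \eqn{Q^* \equiv 0}.
#'
#' @param profile an `AcfProfile`; smoothed in place with width 3 if needed.
#' @param k_min,k_max lag interval in bp over which the transform is taken.
#' @param periods period grid in bp.
#' @param snr_band period band (bp) for the signal-to-noise ratio.
#' @param eps degeneracy threshold on total unnormalized power.
#' @return a `PeriodSpectrum`: list with `period`, `power` (unnormalized P),
#'   `qstar`, `k_min`, `k_max`, `snr_band`, `snr`, `peak_period` (NA when
#'   degenerate) and `degenerate`.
#' @export
power_spectrum <- function(profile, k_min = 30L, k_max = 101L,
                           periods = default_period_grid(),
                           snr_band = c(10, 12), eps = 1e-12) {
  stopifnot(inherits(profile, "AcfProfile"))
  if (length(periods) == 0L) stop("empty period grid", call. = FALSE)
  if (max(profile$lags) < k_max)
    stop("ACF profile does not cover lags through k_max", call. = FALSE)
  if (is.null(profile$smoothed)) profile <- smooth_acf(profile, 3L)
  cbar <- profile$smoothed[k_min:k_max]
  P <- spectrum_power(cbar, k_min, k_max, periods)
  new_spectrum(periods, P, k_min, k_max, snr_band, eps)
}

# |sum_k (cbar - m) exp(2*pi*i*k/T)|^2 / n_k on an arbitrary period grid
spectrum_power <- function(cbar, k_min, k_max, periods) {
  k <- k_min:k_max
  y <- cbar - mean(cbar)
  ang <- outer(k, periods, function(k, T) 2 * pi * k / T)
  re <- as.vector(crossprod(y, cos(ang)))
  im <- as.vector(crossprod(y, sin(ang)))
  (re^2 + im^2) / length(k)
}

new_spectrum <- function(periods, P, k_min, k_max, snr_band, eps = 1e-12) {
  tot <- sum(P)
  if (!is.finite(tot) || tot < eps) {
    q <- rep(0, length(P))
    degenerate <- TRUE
  } else {
    q <- P * length(P) / tot
    degenerate <- FALSE
  }
  sp <- structure(list(period = periods, power = P, qstar = q,
                       k_min = k_min, k_max = k_max, snr_band = snr_band,
                       snr = NA_real_, peak_period = NA_real_,
                       degenerate = degenerate),
                  class = "PeriodSpectrum")
  sp$snr <- band_snr(sp, snr_band)
  if (!degenerate) sp$peak_period <- peak_period(sp)
  sp
}

#' @rdname power_spectrum
#' @export
default_period_grid <- function() seq(2, 15, by = 0.1)

#' Band signal-to-noise ratio of a period spectrum
#'
#' The maximum of the normalized spectrum within a period band (default
#' 10–12 bp, bracketing the DNA helical pitch). Because Q* has unit grid
#' mean, values well above 1 indicate power concentrated in the band; this
#' is the genome-wide periodicity-strength statistic tabulated across
#' species and motifs.
#'
#' @param spectrum a `PeriodSpectrum`.
#' @param band numeric length-2, period band in bp (inclusive).
#' @return dimensionless scalar; 0 for a degenerate spectrum.
#' @export
band_snr <- function(spectrum, band = c(10, 12)) {
  stopifnot(inherits(spectrum, "PeriodSpectrum"))
  sel <- spectrum$period >= band[1] & spectrum$period <= band[2]
  if (!any(sel)) stop("band outside the period grid", call. = FALSE)
  max(spectrum$qstar[sel])
}

#' Peak period of a spectrum
#'
#' The period maximizing Q* over a band (default: the whole grid); exact
#' ties break toward the smaller period. Degenerate (all-zero) spectra have
#' no peak and return NA with a warning.
#'
#' @param spectrum a `PeriodSpectrum`.
#' @param band optional length-2 period band in bp.
#' @return peak period in bp, or NA.
#' @export
peak_period <- function(spectrum, band = NULL) {
  stopifnot(inherits(spectrum, "PeriodSpectrum"))
  if (spectrum$degenerate) {
    warning("no peak: degenerate (flat or empty) spectrum", call. = FALSE)
    return(NA_real_)
  }
  sel <- if (is.null(band)) rep(TRUE, length(spectrum$period))
         else spectrum$period >= band[1] & spectrum$period <= band[2]
  q <- spectrum$qstar[sel]
  p <- spectrum$period[sel]
  p[which.max(q)]   # which.max takes the first maximum; grid is ascending
}

#' Periodicity spectrum of a sequence
#'
#' The central estimator: computes the motif indicator track, its
#' autocorrelation function over lags 1..`k_max`, the 3 bp smoothed ACF, and
#' the normalized period power spectrum, returning a single classed object
#' with `print`, `summary`, `plot` and `coef` methods.
#'
#' @param seq a `GenomeSequence` or character sequence.
#' @param motif a [motif_set()] or motif name (default `"AT2"`).
#' @param k_min,k_max lag window in bp for the spectrum (defaults 30 and 101).
#' @param periods period grid in bp (default 2–15 by 0.1).
#' @param smooth odd ACF smoothing width in bp (default 3).
#' @param snr_band band in bp for the signal-to-noise statistic (default
#'   10–12).
#' @return an object of class `periodicity` bundling the track summary, the
#'   `AcfProfile`, and the `PeriodSpectrum`.
#' @examples
#' g <- generate_genome(synthetic_spec(genome_length = 20000, seed = 1))
#' fit <- periodicity(g$genome)
#' fit
#' coef(fit)
#' @export
periodicity <- function(seq, motif = "AT2", k_min = 30L, k_max = 101L,
                        periods = default_period_grid(), smooth = 3L,
                        snr_band = c(10, 12)) {
  motif <- motif_set(motif)
  track <- if (inherits(seq, "IndicatorTrack")) seq
           else indicator_track(seq, motif)
  periodicity_from_track(track, motif, k_min, k_max, periods, smooth, snr_band)
}

# shared by periodicity() and the concatenated-CDS path (pre-built track)
periodicity_from_track <- function(track, motif, k_min = 30L, k_max = 101L,
                                   periods = default_period_grid(),
                                   smooth = 3L, snr_band = c(10, 12)) {
  acf <- smooth_acf(motif_acf(track, k_hi = k_max), smooth)
  sp <- power_spectrum(acf, k_min, k_max, periods, snr_band)
  structure(list(motif = motif_set(motif), track_length = length(track$values),
                 p_hat = track$p_hat, acf = acf, spectrum = sp,
                 call = sys.call(-1L)),
            class = "periodicity")
}

#' @export
print.periodicity <- function(x, ...) {
  cat(sprintf("Motif periodicity spectrum (motif %s)\n", x$motif$name))
  cat(sprintf("  track: %d positions, density p_hat = %.4f\n",
              x$track_length, x$p_hat))
  cat(sprintf("  lags %d-%d bp, periods %.1f-%.1f bp\n",
              x$spectrum$k_min, x$spectrum$k_max,
              min(x$spectrum$period), max(x$spectrum$period)))
  if (x$spectrum$degenerate) {
    cat("  degenerate spectrum (no power)\n")
  } else {
    cat(sprintf("  peak period: %.1f bp   Q*_SNR(%g-%g bp): %.2f\n",
                x$spectrum$peak_period, x$spectrum$snr_band[1],
                x$spectrum$snr_band[2], x$spectrum$snr))
  }
  invisible(x)
}

#' @export
summary.periodicity <- function(object, ...) {
  sp <- object$spectrum
  structure(list(motif = object$motif$name,
                 track_length = object$track_length, p_hat = object$p_hat,
                 peak_period = sp$peak_period, snr = sp$snr,
                 snr_band = sp$snr_band, degenerate = sp$degenerate,
                 top = utils::head(data.frame(period = sp$period,
                                              qstar = sp$qstar)[
                   order(-sp$qstar), , drop = FALSE], 5L)),
            class = "summary.periodicity")
}

#' @export
print.summary.periodicity <- function(x, ...) {
  cat(sprintf("Motif %s: peak %.1f bp, Q*_SNR = %.2f (band %g-%g bp)\n",
              x$motif, x$peak_period, x$snr, x$snr_band[1], x$snr_band[2]))
  cat("Top periods:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.periodicity <- function(object, ...) {
  c(peak_period = object$spectrum$peak_period, snr = object$spectrum$snr,
    p_hat = object$p_hat)
}

#' @export
plot.periodicity <- function(x, which = c("spectrum", "acf"), ...) {
  which <- match.arg(which)
  if (which == "acf") {
    plot(x$acf$lags, x$acf$raw, type = "l", col = "grey",
         xlab = "lag k (bp)", ylab = "C(k)",
         main = sprintf("Motif %s autocorrelation", x$motif$name), ...)
    graphics::lines(x$acf$lags, x$acf$smoothed, col = "black")
  } else {
    plot(x$spectrum$period, x$spectrum$qstar, type = "l",
         xlab = "period T (bp)", ylab = "Q*(T)",
         main = sprintf("Motif %s period spectrum", x$motif$name), ...)
    if (!x$spectrum$degenerate)
      graphics::abline(v = x$spectrum$peak_period, lty = 2)
  }
  invisible(x)
}
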