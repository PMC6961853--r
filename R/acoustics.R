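# Acoustic analysis: autocorrelation pitch tracking, LPC formants,
# harmonics-to-noise ratio, and energy-based pause detection. These are
# in-package implementations of the standard algorithms (normalized
# autocorrelation F0, autocorrelation-method LPC with root solving,
# autocorrelation HNR, RMS-energy VAD), validated against synthesized
# signals with known parameters.

# Slice a waveform into a (win x n_frames) matrix of frames.
frame_signal <- function(x, win, step) {
  n <- length(x)
  if (n < win) return(NULL)
  starts <- seq(1L, n - win + 1L, by = step)
  idx <- outer(seq_len(win) - 1L, starts, "+")
  matrix(x[idx], nrow = win)
}

# Normalized autocorrelation of each frame column via FFT, lags 0..max_lag.
frame_autocorr <- function(F, max_lag) {
  win <- nrow(F)
  nfft <- 2^ceiling(log2(2L * win))
  Fp <- rbind(F, matrix(0, nfft - win, ncol(F)))
  spec <- stats::mvfft(Fp)
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  ac[seq_len(max_lag + 1L), , drop = FALSE]
}

#' Estimate a fundamental-frequency track
#'
#' Framewise normalized autocorrelation (40 ms window, 10 ms step by
#' default): the highest autocorrelation peak within the candidate lag range
#' gives the frame's F0 (with parabolic interpolation of the peak); frames
#' whose peak correlation falls below the voicing threshold, or whose energy
#' is negligible relative to the utterance, are marked unvoiced.
#'
#' @param audio an \code{\link{audio_segment}}.
#' @param f0_min,f0_max F0 search range in Hz (defaults 75-500, telephone
#'   speech).
#' @param window_s,step_s analysis window and hop in seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return a list of class \code{f0_track}: \code{times}, \code{f0} (NA when
#'   unvoiced), \code{voiced}, \code{peak_corr}, \code{rms},
#'   \code{frame_step}, \code{search_range}.
#' @export
estimate_f0_track <- function(audio, f0_min = 75, f0_max = 500,
                              window_s = 0.040, step_s = 0.010,
                              voicing_threshold = 0.45) {
  sr <- audio$sample_rate
  stopifnot(f0_min < f0_max, f0_max < sr / 2)
  win <- round(window_s * sr); step <- round(step_s * sr)
  F <- frame_signal(audio$samples, win, step)
  empty <- structure(list(times = numeric(0), f0 = numeric(0),
                          voiced = logical(0), peak_corr = numeric(0),
                          rms = numeric(0), frame_step = step_s,
                          search_range = c(f0_min, f0_max)),
                     class = "f0_track")
  if (is.null(F)) return(empty)
  F <- sweep(F, 2, colMeans(F))
  rms <- sqrt(colMeans(F^2))
  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- min(win - 2L, ceiling(sr / f0_min))
  ac <- frame_autocorr(F, lag_max + 1L)
  ac0 <- ac[1L, ]
  ok_energy <- ac0 > 0 & rms > 1e-3 * max(rms, 1e-12) &
    rms > 0.02 * stats::quantile(rms, 0.95)
  r <- sweep(ac, 2, ifelse(ac0 > 0, ac0, 1), "/")
  # unbias: the FFT autocorrelation sums N-lag products but is normalized by
  # the N-term lag-0 energy, which deflates r by (1 - lag/N)
  lags <- seq_len(nrow(r)) - 1L
  r <- r * (win / pmax(1L, win - lags))
  cand <- r[(lag_min + 1L):(lag_max + 1L), , drop = FALSE]
  # Peak choice guards against octave-down errors twice: among local maxima
  # tying with the frame maximum the shortest lag wins, and a clearly
  # periodic local maximum near half the chosen lag (period halving) is
  # preferred — sampling jitter of one sample per period can make the
  # two-period lag correlate slightly better than the true period.
  peak_rel <- apply(cand, 2, function(v) {
    n <- length(v)
    is_loc <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                        v[2:(n - 1)] >= v[3:n], FALSE)
    loc <- which(is_loc & v >= max(v) - 0.02)
    idx <- if (length(loc)) loc[1] else which.max(v)
    repeat {
      lag <- idx + lag_min - 1L
      half <- lag / 2
      lo <- floor(half - 0.12 * half) - lag_min + 1L
      hi <- ceiling(half + 0.12 * half) - lag_min + 1L
      if (hi < 1L) break
      rng <- max(1L, lo):min(n, hi)
      cands <- rng[is_loc[rng]]
      if (!length(cands)) break
      best <- cands[which.max(v[cands])]
      if (v[best] >= v[idx] - 0.15 && v[best] >= voicing_threshold)
        idx <- best
      else break
    }
    idx
  })
  peak_lag <- peak_rel + lag_min - 1L
  peak_val <- cand[cbind(peak_rel, seq_len(ncol(cand)))]
  # parabolic interpolation around the peak lag
  l0 <- peak_lag + 1L
  rm1 <- r[cbind(l0 - 1L, seq_len(ncol(r)))]
  r0 <- r[cbind(l0, seq_len(ncol(r)))]
  rp1 <- r[cbind(l0 + 1L, seq_len(ncol(r)))]
  denom <- rm1 - 2 * r0 + rp1
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (rm1 - rp1) / denom, 0)
  delta <- clip(delta, -0.5, 0.5)
  f0 <- sr / (peak_lag + delta)
  # interpolated peak height (used for voicing and harmonicity)
  peak_val <- pmax(peak_val, r0 - 0.25 * (rm1 - rp1) * delta)
  voiced <- ok_energy & is.finite(peak_val) & peak_val >= voicing_threshold &
    f0 >= f0_min & f0 <= f0_max
  f0[!voiced] <- NA_real_
  n <- ncol(F)
  structure(list(times = (seq_len(n) - 1L) * step_s + window_s / 2,
                 f0 = f0, voiced = voiced,
                 peak_corr = ifelse(is.finite(peak_val), peak_val, 0),
                 rms = rms, frame_step = step_s,
                 search_range = c(f0_min, f0_max)),
            class = "f0_track")
}

#' Estimate vocal formants by linear prediction
#'
#' Per voiced frame: pre-emphasis (0.97), Hamming window, LPC of order
#' \code{2 + sample_rate/1000} by the autocorrelation method, roots of the
#' prediction polynomial, and resonances with bandwidth under 400 Hz within
#' \code{[90, sample_rate/2 - 50]} Hz, sorted ascending. The response-level
#' F1/F2 are means over analyzed voiced frames.
#'
#' @param audio an \code{\link{audio_segment}}.
#' @param track optional precomputed \code{f0_track} (avoids recomputation).
#' @param n_formants number of formants to return.
#' @param max_frames cap on the number of voiced frames analyzed (evenly
#'   subsampled) to bound cost on long responses.
#' @return numeric vector of length \code{n_formants} (mean formant
#'   frequencies in Hz, NA where not found).
#' @export
estimate_formants <- function(audio, track = NULL, n_formants = 2L,
                              max_frames = 40L) {
  sr <- audio$sample_rate
  if (is.null(track)) track <- estimate_f0_track(audio)
  out <- rep(NA_real_, n_formants)
  names(out) <- paste0("f", seq_len(n_formants), "_mean")
  vf <- which(track$voiced)
  if (!length(vf)) return(out)
  if (length(vf) > max_frames)
    vf <- vf[unique(round(seq(1, length(vf), length.out = max_frames)))]
  x <- audio$samples
  x <- c(x[1], x[-1] - 0.97 * x[-length(x)])
  win <- round(0.040 * sr); step <- round(0.010 * sr)
  h <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  p <- as.integer(2 + sr / 1000)
  f_lo <- 90; f_hi <- sr / 2 - 50
  per_frame <- matrix(NA_real_, nrow = length(vf), ncol = n_formants)
  for (i in seq_along(vf)) {
    s <- (vf[i] - 1L) * step + 1L
    if (s + win - 1L > length(x)) next
    fr <- x[s:(s + win - 1L)] * h
    fr <- fr - mean(fr)
    rvec <- vapply(0:p, function(k)
      sum(fr[seq_len(win - k)] * fr[(k + 1L):win]), 0)
    if (rvec[1] <= 0) next
    a <- tryCatch(solve(stats::toeplitz(rvec[1:p]), rvec[2:(p + 1)]),
                  error = function(e) NULL)
    if (is.null(a)) next
    rts <- polyroot(c(1, -a))          # roots in q = z^{-1}
    z <- 1 / rts
    keep <- Im(z) > 0 & Mod(z) < 1
    if (!any(keep)) next
    freq <- Arg(z[keep]) / (2 * pi) * sr
    bw <- -(sr / pi) * log(Mod(z[keep]))
    sel <- freq >= f_lo & freq <= f_hi & bw < 400
    freq <- sort(freq[sel])
    if (length(freq))
      per_frame[i, seq_len(min(n_formants, length(freq)))] <-
        freq[seq_len(min(n_formants, length(freq)))]
  }
  means <- colMeans(per_frame, na.rm = TRUE)
  means[!is.finite(means)] <- NA_real_
  out[] <- means
  out
}

#' Harmonics-to-noise ratio
#'
#' Per voiced frame, \code{HNR = 10 log10(r / (1 - r))} where \code{r} is
#' the normalized autocorrelation at the frame's F0 lag (clipped away from 0
#' and 1); the response value is the median over voiced frames.
#'
#' @param audio an \code{\link{audio_segment}}.
#' @param track optional precomputed \code{f0_track}.
#' @return median HNR in dB, or NA with no voiced frame.
#' @export
harmonicity <- function(audio, track = NULL) {
  if (is.null(track)) track <- estimate_f0_track(audio)
  r <- track$peak_corr[track$voiced]
  if (!length(r)) return(NA_real_)
  r <- clip(r, 1e-6, 1 - 1e-6)
  stats::median(10 * log10(r / (1 - r)))
}

#' Detect pauses by energy-based voice activity detection
#'
#' Framewise RMS energy (25 ms window, 10 ms hop); speech frames exceed
#' \code{threshold_frac} times the 95th-percentile frame energy. Pauses are
#' maximal non-speech runs of at least \code{min_pause_s} seconds occurring
#' strictly between speech segments (leading and trailing silence is not a
#' pause). The pause fraction is pause time over the speech-plus-pause span.
#'
#' @param audio an \code{\link{audio_segment}}.
#' @param threshold_frac VAD threshold as a fraction of the 95th-percentile
#'   frame RMS.
#' @param min_pause_s minimum pause duration in seconds.
#' @param window_s,step_s energy frame length and hop in seconds.
#' @return list with \code{pause_fraction}, \code{mean_pause_duration},
#'   \code{n_pauses}, \code{speech_present}, and \code{segments} (data frame
#'   of pause start/end times in seconds).
#' @export
detect_pauses <- function(audio, threshold_frac = 0.05, min_pause_s = 0.150,
                          window_s = 0.025, step_s = 0.010) {
  sr <- audio$sample_rate
  win <- round(window_s * sr); step <- round(step_s * sr)
  F <- frame_signal(audio$samples, win, step)
  none <- list(pause_fraction = 0, mean_pause_duration = 0, n_pauses = 0L,
               speech_present = FALSE,
               segments = data.frame(start = numeric(0), end = numeric(0)))
  if (is.null(F)) return(none)
  rms <- sqrt(colMeans(F^2))
  thr <- threshold_frac * stats::quantile(rms, 0.95)
  speech <- rms > thr & rms > 1e-6
  if (!any(speech)) return(none)
  first <- which(speech)[1]; last <- max(which(speech))
  inner <- speech[first:last]
  runs <- rle(!inner)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  min_frames <- ceiling(min_pause_s / step_s)
  is_pause <- runs$values & runs$lengths >= min_frames
  seg <- data.frame(
    start = (first - 1L + starts[is_pause] - 1L) * step_s,
    end = (first - 1L + ends[is_pause]) * step_s)
  pause_time <- sum(runs$lengths[is_pause]) * step_s
  span <- length(inner) * step_s
  list(pause_fraction = if (span > 0) pause_time / span else 0,
       mean_pause_duration = if (nrow(seg)) mean(seg$end - seg$start) else 0,
       n_pauses = nrow(seg), speech_present = TRUE, segments = seg)
}

#' Names of the nine per-response acoustic features
#' @return character vector of length 9.
#' @export
acoustic_feature_names <- function() {
  c("f0_mean", "f0_median", "f0_std", "f1_mean", "f2_mean", "hnr_median",
    "pause_fraction", "mean_pause_duration", "voiced_fraction")
}

#' The nine-feature acoustic summary of a response
#'
#' Composes the pitch track, formant, harmonicity and pause analyses into
#' the fixed nine-feature set: F0 mean/median/std (intonation variability),
#' mean F1 and F2, median HNR, pause fraction, mean pause duration, and
#' voiced-frame fraction. Sub-analyses that cannot run (e.g. silence) yield
#' missing values per their own contracts.
#'
#' @param audio an \code{\link{audio_segment}}.
#' @param f0_min,f0_max F0 search range in Hz.
#' @return named numeric vector of length 9.
#' @export
acoustic_feature_set <- function(audio, f0_min = 75, f0_max = 500) {
  out <- stats::setNames(rep(NA_real_, 9L), acoustic_feature_names())
  track <- estimate_f0_track(audio, f0_min = f0_min, f0_max = f0_max)
  f0 <- track$f0[track$voiced]
  if (length(f0)) {
    out["f0_mean"] <- mean(f0)
    out["f0_median"] <- stats::median(f0)
    out["f0_std"] <- pop_sd(f0)
  }
  fm <- estimate_formants(audio, track = track)
  out["f1_mean"] <- fm[["f1_mean"]]
  out["f2_mean"] <- fm[["f2_mean"]]
  out["hnr_median"] <- harmonicity(audio, track = track)
  p <- detect_pauses(audio)
  out["pause_fraction"] <- p$pause_fraction
  out["mean_pause_duration"] <- p$mean_pause_duration
  out["voiced_fraction"] <- if (length(track$voiced))
    mean(track$voiced) else NA_real_
  out
}
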