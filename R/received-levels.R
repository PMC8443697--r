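#' Construct a hydrophone recording object
#'
#' @param samples Pressure time series (linear units, e.g. micropascal).
#' @param fs Sampling rate in Hz; 10000 (analysis rate) or 200000 (raw rate).
#' @param start_time_s Epoch time of the first sample, seconds.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, start_time_s = 0) {
  if (!fs %in% c(10000, 200000)) stop("sampling rate must be 10 kHz or 200 kHz")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time_s = start_time_s),
            class = "recording")
}

#' Decimate a 200 kHz recording to the 10 kHz analysis rate
#'
#' Lowpass filters with an 8th-order Chebyshev Type I IIR filter (0.05 dB
#' passband ripple, cutoff at 0.8 of the target Nyquist) to prevent aliasing,
#' then keeps every 20th sample.
#'
#' @param rec A [recording()] at 200 kHz.
#' @return A `recording` at 10 kHz.
#' @export
decimate_recording <- function(rec) {
  if (rec$fs != 200000) stop("decimation expects a 200 kHz recording")
  y <- signal::decimate(rec$samples, q = 20, n = 8, ftype = "iir")
  recording(y, fs = 10000, start_time_s = rec$start_time_s)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Per-second power spectral density series
#'
#' Splits the recording into 1-s non-overlapping segments and computes, for
#' each, the one-sided power spectral density via an FFT of length `fs` with
#' a Hann window. The window is normalised by its noise power (sum of squared
#' coefficients) so broadband levels of noise-like signals are unbiased.
#' Levels are `10 * log10(PSD)` in dB re 1 uPa^2 (per 1-Hz bin) before
#' calibration. A trailing partial second is discarded.
#'
#' @param rec A [recording()] at 10 kHz (decimate 200 kHz input first) or
#'   200 kHz (1-Hz bins either way, at higher cost).
#' @param band Analysis band in Hz, default `c(5, 1000)` giving 996 bins.
#' @return An object of class `spectrum_series`: `times_s` (frame centres),
#'   `freq_hz` (integer bin centres), `levels_db` (frames x bins matrix),
#'   `fs`.
#' @export
psd_series <- function(rec, band = c(5, 1000)) {
  n <- rec$fs                      # 1-s frames; 1-Hz bins
  n_frames <- length(rec$samples) %/% n
  if (n_frames < 1) stop("recording shorter than 1 s")
  w <- hann_window(n)
  wpow <- sum(w^2)
  freq <- seq(band[1], band[2])
  idx <- freq + 1L                 # FFT bin k holds frequency k-1 Hz
  levels <- matrix(NA_real_, n_frames, length(freq))
  for (i in seq_len(n_frames)) {
    seg <- rec$samples[((i - 1) * n + 1):(i * n)]
    X <- stats::fft(seg * w)
    psd <- 2 * Mod(X[idx])^2 / (rec$fs * wpow)   # one-sided, per Hz
    levels[i, ] <- 10 * log10(psd)
  }
  structure(list(times_s = rec$start_time_s + seq_len(n_frames) - 0.5,
                 freq_hz = freq, levels_db = levels, fs = rec$fs),
            class = "spectrum_series")
}

#' Apply a frequency-dependent hydrophone calibration
#'
#' Adds the calibration offset, linearly interpolated in frequency, to every
#' bin of the spectrum series, yielding received levels in dB re 1 uPa^2.
#'
#' @param series A [psd_series()] result.
#' @param curve Data frame with columns `frequency_hz` (monotone) and
#'   `offset_db`, covering the full analysis band.
#' @return The calibrated `spectrum_series`.
#' @export
apply_calibration <- function(series, curve) {
  fr <- range(series$freq_hz)
  if (min(curve$frequency_hz) > fr[1] || max(curve$frequency_hz) < fr[2]) {
    stop("calibration curve does not cover the analysis band")
  }
  offs <- stats::approx(curve$frequency_hz, curve$offset_db,
                        xout = series$freq_hz)$y
  series$levels_db <- sweep(series$levels_db, 2, offs, `+`)
  series
}

#' Data window period
#'
#' The averaging window for received levels: the time the ship takes to
#' travel its own length at its CPA speed.
#'
#' @param length_m Ship length, metres (> 0).
#' @param sog_mps Speed over ground at CPA, m/s (> 0).
#' @return Window duration in seconds.
#' @examples
#' data_window_period(300, 7.5) # 40 s
#' @export
data_window_period <- function(length_m, sog_mps) {
  if (any(length_m <= 0)) stop("ship length must be positive")
  if (any(sog_mps <= 0)) stop("speed must be positive")
  length_m / sog_mps
}

#' Received level spectrum and broadband level at CPA
#'
#' Averages the calibrated spectrum over the data window period centred on
#' the CPA time. Averaging is done per bin in the linear power domain (dB
#' averaging would bias the result low); the broadband level is ten times the
#' base-10 log of the sum of linear bin powers across the band.
#'
#' @param series Calibrated `spectrum_series`.
#' @param cpa_time_s CPA time, seconds (same clock as the recording).
#' @param dwp_s Data window period from [data_window_period()], seconds.
#' @return List with `rl_spectrum_db` (one value per 1-Hz bin), `freq_hz`,
#'   `broadband_rl_db`, `n_frames`.
#' @export
received_level_at_cpa <- function(series, cpa_time_s, dwp_s) {
  lo <- cpa_time_s - dwp_s / 2
  hi <- cpa_time_s + dwp_s / 2
  if (lo < series$times_s[1] - 0.5 || hi > series$times_s[length(series$times_s)] + 0.5) {
    stop("data window extends outside the recording")
  }
  sel <- series$times_s >= lo & series$times_s <= hi
  if (!any(sel)) stop("data window contains no whole frames")
  lin <- 10^(series$levels_db[sel, , drop = FALSE] / 10)
  spec <- 10 * log10(colMeans(lin))
  list(rl_spectrum_db = spec, freq_hz = series$freq_hz,
       broadband_rl_db = 10 * log10(sum(10^(spec / 10))),
       n_frames = sum(sel))
}

#' Broadband level per frame
#'
#' @param series A `spectrum_series`.
#' @return Numeric vector: per-frame band-summed level in dB.
#' @export
broadband_series <- function(series) {
  10 * log10(rowSums(10^(series$levels_db / 10)))
}

#' Duration above background
#'
#' The exposure duration T: the length of the contiguous run of 1-s frames,
#' containing the CPA frame, whose broadband received level is at least
#' `delta_db` above the background level. If the CPA frame itself is below
#' the threshold the transit is too quiet to bound and T = 0 is returned with
#' a warning.
#'
#' @param times_s Frame centre times.
#' @param broadband_db Per-frame broadband levels (e.g. [broadband_series()]).
#' @param cpa_time_s CPA time, seconds.
#' @param background_db Background broadband level, dB.
#' @param delta_db Threshold above background, default 15 dB.
#' @return Duration T in seconds.
#' @export
above_background_duration <- function(times_s, broadband_db, cpa_time_s,
                                      background_db, delta_db = 15) {
  if (!is.finite(background_db)) stop("background level must be finite")
  above <- broadband_db >= background_db + delta_db
  i0 <- which.min(abs(times_s - cpa_time_s))
  if (!above[i0]) {
    warning("broadband level at CPA below background + delta; T = 0")
    return(0)
  }
  lo <- i0
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i0
  while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  (hi - lo + 1) * 1
}

#' Estimate the background broadband level
#'
#' Median of the per-frame broadband level over a reference window preceding
#' the transit's in-area interval (default the 10 preceding minutes).
#'
#' @param series Calibrated `spectrum_series`.
#' @param before_time_s End of the reference window (start of the in-area
#'   interval), seconds.
#' @param window_s Reference window length, default 600 s.
#' @return Background broadband level, dB.
#' @export
background_level <- function(series, before_time_s, window_s = 600) {
  sel <- series$times_s < before_time_s &
    series$times_s >= before_time_s - window_s
  if (!any(sel)) stop("no frames in the background reference window")
  stats::median(broadband_series(series)[sel])
}

#' Flag hydrophone cable strum contamination
#'
#' Heuristic data-quality check: cable strum concentrates energy at a few Hz,
#' so the recording is flagged when the mean power in the 1-10 Hz band
#' exceeds the mean power in the 10-100 Hz band by more than `margin_db`.
#'
#' @param rec A [recording()] of at least 10 s.
#' @param margin_db Flagging margin, default 20 dB.
#' @return `TRUE` when strum contamination is likely.
#' @export
strum_flag <- function(rec, margin_db = 20) {
  n <- rec$fs
  n_frames <- length(rec$samples) %/% n
  if (n_frames < 10) stop("strum check needs at least 10 s of data")
  w <- hann_window(n)
  wpow <- sum(w^2)
  p_low <- p_mid <- 0
  for (i in seq_len(n_frames)) {
    seg <- rec$samples[((i - 1) * n + 1):(i * n)]
    X <- stats::fft(seg * w)
    psd <- 2 * Mod(X)^2 / (rec$fs * wpow)
    p_low <- p_low + mean(psd[(1:10) + 1L])
    p_mid <- p_mid + mean(psd[(10:100) + 1L])
  }
  if (p_low == 0 && p_mid == 0) return(FALSE)   # silence
  10 * log10(p_low / p_mid) > margin_db
}
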