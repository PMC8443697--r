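#' Estimate per-transit levels from a recording and its AIS track
#'
#' The full signal chain for one ship passage: decimate to the 10 kHz
#' analysis rate if needed, compute calibrated 1-Hz received-level spectra in
#' 1-s frames, locate the closest point of approach from the AIS track,
#' average received levels over the data window period (the time the ship
#' takes to travel its own length), back-propagate to source levels with the
#' modified Lloyd's-mirror model, and integrate the modelled overhead passage
#' into a sound exposure level.
#'
#' @param rec A [recording()] (10 kHz, or 200 kHz which is decimated first).
#' @param ais AIS fix table: `time_s`, `x_m`, `y_m`, `sog_mps`, `draft_m`
#'   (receiver at the planar origin, same clock as the recording).
#' @param length_m Ship length, metres (registry metadata).
#' @param receiver_depth_m Receiver depth, metres.
#' @param sound_speed_mps Harmonic-mean sound speed, m/s (e.g. from
#'   [harmonic_mean_speed()] on the month's [select_profile()] result).
#' @param calibration Optional calibration curve for [apply_calibration()];
#'   `NULL` means already-calibrated (unit) response.
#' @param background_db Background broadband level, dB. `NULL` estimates it
#'   with [background_level()] from the 10 min preceding the track, which
#'   requires the recording to start before the ship enters.
#' @param prop_coef Propeller-diameter model coefficients, see
#'   [propeller_diameter()].
#' @param sel_dt_s SEL integration step, seconds (default 60).
#' @return List of class `level_estimate`: CPA info, `rl_spectrum_db`,
#'   `sl_spectrum_db`, `broadband_rl_db`, `broadband_sl_db`, `sel_db`,
#'   `duration_s`, `source_depth_m`, `f_star_hz`, `third_octave`,
#'   `dwp_s`, `background_db`.
#' @export
estimate_transit_levels <- function(rec, ais, length_m, receiver_depth_m = 580,
                                    sound_speed_mps = 1500, calibration = NULL,
                                    background_db = NULL,
                                    prop_coef = c(intercept = 0.5, slope = 0.03),
                                    sel_dt_s = 60) {
  if (rec$fs == 200000) rec <- decimate_recording(rec)
  series <- psd_series(rec)
  if (!is.null(calibration)) series <- apply_calibration(series, calibration)

  d_s <- effective_source_depth(ais$draft_m[1],
                                propeller_diameter(length_m, coef = prop_coef))
  cpa <- compute_cpa(ais, receiver_depth_m = receiver_depth_m,
                     source_depth_m = d_s)
  dwp <- data_window_period(length_m, cpa$sog_at_cpa_mps)
  rl <- received_level_at_cpa(series, cpa$time_s, dwp)
  sl <- source_level(rl$rl_spectrum_db, rl$freq_hz, d_s, receiver_depth_m,
                     cpa$slant_range_m, sound_speed_mps)
  if (is.null(background_db)) {
    background_db <- background_level(series, min(ais$time_s))
  }
  sel <- sound_exposure_level(sl$sl_spectrum_db, sl$freq_hz,
                              sog_mps = cpa$sog_at_cpa_mps,
                              source_depth_m = d_s,
                              receiver_depth_m = receiver_depth_m,
                              sound_speed_mps = sound_speed_mps,
                              background_db = background_db,
                              dt_s = sel_dt_s)
  structure(
    list(cpa = cpa,
         rl_spectrum_db = rl$rl_spectrum_db,
         sl_spectrum_db = sl$sl_spectrum_db,
         freq_hz = rl$freq_hz,
         broadband_rl_db = rl$broadband_rl_db,
         broadband_sl_db = sl$broadband_sl_db,
         sel_db = sel$sel_db,
         duration_s = sel$duration_s,
         source_depth_m = d_s,
         f_star_hz = sl$f_star_hz,
         third_octave = third_octave(sl$sl_spectrum_db, sl$freq_hz),
         dwp_s = dwp,
         background_db = background_db),
    class = "level_estimate"
  )
}

#' Flatten a level estimate into a per-transit results row
#'
#' @param est A `level_estimate` from [estimate_transit_levels()].
#' @param transit_id,category,group,tier,phase Optional labels carried into
#'   the row.
#' @return One-row tibble matching the per-transit results layout
#'   (`transit_id`, `category`, `group`, `tier`, `phase`, `sog_mps`, `rl_db`,
#'   `sl_db`, `sel_db`, `duration_s`, `source_depth_m`, `f_star_hz`).
#' @export
as_results_row <- function(est, transit_id = NA_character_,
                           category = NA_character_, group = NA_character_,
                           tier = NA_character_, phase = NA_character_) {
  tibble::tibble(
    transit_id = transit_id, category = category, group = group,
    tier = tier, phase = phase,
    sog_mps = est$cpa$sog_at_cpa_mps,
    rl_db = est$broadband_rl_db,
    sl_db = est$broadband_sl_db,
    sel_db = est$sel_db,
    duration_s = est$duration_s,
    source_depth_m = est$source_depth_m,
    f_star_hz = est$f_star_hz
  )
}
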