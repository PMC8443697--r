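#' Group specification for summary-level transit simulation
#'
#' Describes one analysis group (vessel type, program group, or award tier x
#' phase cell) by its transit count and the mean and standard deviation of
#' speed over ground, broadband source level and sound exposure level.
#'
#' @param label Group name.
#' @param n Number of transits (>= 1).
#' @param sog_mean,sog_sd SOG moments, m/s (`sog_mean` > 0, `sog_sd` >= 0).
#' @param sl_mean,sl_sd Broadband SL moments, dB re 1 uPa^2 @ 1 m.
#' @param sel_mean,sel_sd Broadband SEL moments, dB re 1 uPa^2 s.
#' @return One-row tibble; rows from several calls can be bound together.
#' @export
group_spec <- function(label, n, sog_mean, sog_sd, sl_mean = NA_real_,
                       sl_sd = NA_real_, sel_mean = NA_real_,
                       sel_sd = NA_real_) {
  if (n < 1) stop("group transit count must be at least 1")
  if (sog_mean <= 0) stop("mean SOG must be positive")
  sds <- c(sog_sd, sl_sd, sel_sd)
  if (any(sds < 0, na.rm = TRUE)) stop("standard deviations must be non-negative")
  tibble::tibble(label = label, n = as.integer(n),
                 sog_mean = sog_mean, sog_sd = sog_sd,
                 sl_mean = sl_mean, sl_sd = sl_sd,
                 sel_mean = sel_mean, sel_sd = sel_sd)
}

#' Linear speed-to-level law
#'
#' The generative relation `level = intercept + slope * SOG + e`,
#' `e ~ N(0, residual_sd)`. The residual spread may be given directly or
#' derived from a target coefficient of determination: for SOG spread
#' `sog_sd`, \deqn{\sigma_e = |slope| \cdot sog\_sd \cdot \sqrt{1/r^2 - 1},}
#' so a least-squares fit over law-generated data recovers `r_squared` in
#' expectation.
#'
#' @param slope dB per (m/s).
#' @param intercept dB. When omitted and group moments are available it can
#'   be derived as `level_mean - slope * sog_mean`.
#' @param residual_sd Residual standard deviation, dB (>= 0).
#' @param r_squared Target r-squared in (0, 1]; used with `sog_sd` to derive
#'   `residual_sd` when that is not given.
#' @param sog_sd SOG standard deviation, m/s, for the r-squared derivation.
#' @return List of class `speed_level_law`.
#' @examples
#' speed_level_law(2.0, 179.6, r_squared = 0.32, sog_sd = 1.9)
#' @export
speed_level_law <- function(slope, intercept, residual_sd = NULL,
                            r_squared = NULL, sog_sd = NULL) {
  if (is.null(residual_sd)) {
    if (is.null(r_squared) || is.null(sog_sd)) {
      stop("supply residual_sd, or r_squared together with sog_sd")
    }
    if (r_squared <= 0 || r_squared > 1) stop("r_squared must be in (0, 1]")
    residual_sd <- abs(slope) * sog_sd * sqrt(1 / r_squared - 1)
  }
  if (residual_sd < 0) stop("residual_sd must be non-negative")
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = residual_sd),
            class = "speed_level_law")
}

# inverse-CDF truncated normal: one uniform draw per variate, keeping the
# generator's RNG stream length independent of rejection luck
rnorm_trunc <- function(n, mean, sd, lower = 0.5) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a summary-level transit table
#'
#' Draws per-transit SOG, broadband SL and broadband SEL for each group. Two
#' modes:
#' * **law mode** (laws supplied): SOG is drawn from the group's truncated
#'   normal (lower bound 0.5 m/s to avoid degenerate stationary ships) and
#'   levels follow the [speed_level_law()] with Gaussian residuals, so
#'   regression analyses can recover slope and r-squared;
#' * **group-mean mode** (laws `NULL`): levels are drawn from the group's own
#'   normal moments, independent of the SOG draw, for group-comparison
#'   statistics.
#'
#' @param groups Tibble of group rows ([group_spec()] /
#'   [ship_type_specs()] and friends).
#' @param sl_law,sel_law Optional [speed_level_law()] objects for SL and SEL.
#' @param seed Integer RNG seed.
#' @return Tibble with `group`, `sog_mps`, `sl_db`, `sel_db`; one row per
#'   transit, `sum(groups$n)` rows in all.
#' @export
generate_summary_transits <- function(groups, sl_law = NULL, sel_law = NULL,
                                      seed = 1) {
  if (any(groups$n < 1)) stop("every group needs a positive transit count")
  set.seed(seed)
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sog <- rnorm_trunc(g$n, g$sog_mean, g$sog_sd)
    draw_level <- function(law, mean, sd) {
      if (!is.null(law)) {
        law$intercept + law$slope * sog + stats::rnorm(g$n, 0, law$residual_sd)
      } else if (is.na(mean)) {
        rep(NA_real_, g$n)          # group has no moments for this level
      } else {
        stats::rnorm(g$n, mean, sd)
      }
    }
    sl <- draw_level(sl_law, g$sl_mean, g$sl_sd)
    sel <- draw_level(sel_law, g$sel_mean, g$sel_sd)
    tibble::tibble(group = g$label, sog_mps = sog, sl_db = sl, sel_db = sel)
  })
  dplyr::bind_rows(out)
}

#' Study-condition group specifications
#'
#' Packaged summary statistics of the Santa Barbara Channel monitoring
#' conditions the generator emulates.
#'
#' * `ship_type_specs()`: the three analysed cargo categories and their
#'   pooled total (3778 transits), with the fitted SOG-to-SL and SOG-to-SEL
#'   slopes and r-squared values.
#' * `program_group_specs()`: the 2014-2017 transit-by-transit program's
#'   control (109 transits) and rewarded (43) groups.
#' * `fleet_tier_specs()`: the 2018 fleet-based program's five award tiers in
#'   both program phases.
#'
#' @return A tibble of group rows (plus slope/r-squared columns for
#'   `ship_type_specs()`, and `tier`/`phase` columns for
#'   `fleet_tier_specs()`).
#' @export
ship_type_specs <- function() {
  tibble::tribble(
    ~label, ~n, ~sog_mean, ~sog_sd, ~rl_mean, ~rl_sd, ~sl_mean, ~sl_sd,
    ~sel_mean, ~sel_sd, ~slope_sl, ~slope_sel, ~r2_sl, ~r2_sel,
    "all",             3778L, 7.3, 1.9, 110.0, 6.5, 194.2, 6.6, 158.1, 6.0, 2.0, 1.7, 0.32, 0.27,
    "container",       2677L, 7.6, 2.0, 110.3, 6.6, 194.7, 6.8, 158.4, 6.2, 2.1, 1.8, 0.37, 0.34,
    "vehicle_carrier",  485L, 7.3, 1.6, 108.5, 6.2, 193.1, 5.7, 156.8, 5.2, 1.7, 1.5, 0.21, 0.19,
    "bulker",           616L, 6.1, 0.8, 110.0, 6.2, 193.0, 6.4, 157.8, 6.0, 2.6, 2.2, 0.11, 0.09
  )
}

#' @rdname ship_type_specs
#' @export
program_group_specs <- function() {
  dplyr::bind_rows(
    group_spec("control",  109, 7.9, 2.0, 194.4, 6.5, 157.1, 5.7),
    group_spec("rewarded",  43, 5.4, 0.4, 189.2, 3.9, 152.4, 3.4)
  )
}

#' @rdname ship_type_specs
#' @export
fleet_tier_specs <- function() {
  sp <- tibble::tribble(
    ~tier, ~phase, ~n, ~sog_mean, ~sog_sd, ~sl_mean, ~sl_sd, ~sel_mean, ~sel_sd,
    "sapphire",      "active",    18L, 5.4, 1.2, 190.6, 5.0, 156.1, 4.9,
    "gold",          "active",    49L, 5.8, 1.4, 190.2, 5.1, 155.7, 4.7,
    "silver",        "active",    80L, 6.8, 2.3, 193.2, 8.1, 157.5, 7.5,
    "bronze",        "active",    89L, 7.8, 2.3, 195.6, 5.8, 160.1, 5.7,
    "non_compliant", "active",    18L, 9.9, 1.8, 197.7, 6.3, 161.4, 6.1,
    "sapphire",      "inactive",  32L, 5.9, 1.3, 193.6, 7.9, 159.6, 6.5,
    "gold",          "inactive",  64L, 6.7, 1.6, 193.9, 7.9, 159.8, 6.8,
    "silver",        "inactive", 100L, 7.5, 2.1, 194.2, 7.9, 159.5, 7.2,
    "bronze",        "inactive",  88L, 7.7, 2.2, 196.4, 7.1, 161.8, 6.2,
    "non_compliant", "inactive",  17L, 8.8, 2.1, 196.2, 7.6, 161.1, 7.1
  )
  dplyr::mutate(sp, label = paste(.data$tier, .data$phase, sep = "."))
}

#' Default ship source-level spectrum shape
#'
#' Flat from the band floor to 100 Hz, then rolling off at -10 dB per decade
#' to the band ceiling (cargo-ship radiated noise is dominated by propeller
#' cavitation below ~100 Hz), scaled so the power sum over 1-Hz bins equals
#' the requested broadband level.
#'
#' @param broadband_db Target broadband source level, dB re 1 uPa^2 @ 1 m.
#' @param freq_hz Bin centre frequencies, default 5-1000 Hz.
#' @return Numeric vector of per-bin levels.
#' @export
default_sl_spectrum <- function(broadband_db, freq_hz = 5:1000) {
  shape <- ifelse(freq_hz <= 100, 0, -10 * log10(freq_hz / 100))
  offset <- broadband_db - 10 * log10(sum(10^(shape / 10)))
  shape + offset
}

#' Define a single ship-passage scenario
#'
#' @param length_m Ship length, metres.
#' @param draft_m AIS-reported draft, metres (> 0).
#' @param sog_mps Speed over ground, m/s (> 0).
#' @param cpa_range_m Horizontal range at CPA, metres; the study geometry
#'   spans 600-4999 m.
#' @param broadband_sl_db Broadband source level used to scale the default
#'   spectrum (ignored when `sl_spectrum_db` is supplied).
#' @param sl_spectrum_db Optional explicit per-1-Hz-bin SL spectrum over
#'   `freq_hz`.
#' @param duration_s Track duration, seconds, centred on CPA.
#' @param freq_hz Spectrum bin centres; must span 5-1000 Hz.
#' @param vessel_id Vessel identifier string.
#' @return List of class `ship_scenario`.
#' @export
ship_scenario <- function(length_m, draft_m, sog_mps, cpa_range_m,
                          broadband_sl_db = 190, sl_spectrum_db = NULL,
                          duration_s = 600, freq_hz = 5:1000,
                          vessel_id = "SYNTH-0001") {
  if (cpa_range_m <= 0) stop("CPA range must be positive (zero range is undefined geometry)")
  if (draft_m <= 0 || sog_mps <= 0) stop("draft and SOG must be positive")
  if (min(freq_hz) > 5 || max(freq_hz) < 1000) {
    stop("spectrum bins must span 5-1000 Hz")
  }
  if (is.null(sl_spectrum_db)) {
    sl_spectrum_db <- default_sl_spectrum(broadband_sl_db, freq_hz)
  }
  structure(
    list(length_m = length_m, draft_m = draft_m, sog_mps = sog_mps,
         cpa_range_m = cpa_range_m, sl_spectrum_db = sl_spectrum_db,
         duration_s = duration_s, freq_hz = freq_hz, vessel_id = vessel_id),
    class = "ship_scenario"
  )
}

#' Render a ship passage as a pressure waveform with AIS fixes
#'
#' Inverts the propagation model: for each 1-s frame along a straight
#' constant-speed track, the received spectrum is the scenario's source-level
#' spectrum minus the modified Lloyd's-mirror transmission loss at that
#' instant's slant range. Each frame is synthesised by inverse spectral
#' shaping (one sinusoid per 1-Hz bin with independent random phase; phase
#' continuity across frames is not enforced because the analysis chain is
#' PSD-based and phase-blind), and Gaussian background noise with a flat
#' spectrum level is added in the time domain. AIS fixes are emitted every
#' 60 s plus the track endpoints.
#'
#' @param scenario A [ship_scenario()].
#' @param receiver_depth_m Receiver depth, metres.
#' @param sound_speed_mps Harmonic-mean sound speed, m/s.
#' @param background_psd_db Background spectrum level, dB re 1 uPa^2/Hz
#'   (flat).
#' @param fs Output sampling rate: 10000 or 200000 Hz.
#' @param seed Integer RNG seed.
#' @return List: `rec` (a [recording()]), `ais` (tibble `time_s`, `x_m`,
#'   `y_m`, `sog_mps`, `draft_m`, `vessel_id`), and `truth` (source depth,
#'   CPA time/slant range, broadband SL, spectrum) for round-trip checks.
#' @export
render_passage_waveform <- function(scenario, receiver_depth_m = 580,
                                    sound_speed_mps = 1500,
                                    background_psd_db = 60,
                                    fs = 10000, seed = 1) {
  if (!fs %in% c(10000, 200000)) stop("fs must be 10 kHz or 200 kHz")
  set.seed(seed)
  sc <- scenario
  d_s <- effective_source_depth(sc$draft_m,
                                propeller_diameter(sc$length_m))
  n_frames <- floor(sc$duration_s)
  t_cpa <- sc$duration_s / 2
  t_centers <- seq_len(n_frames) - 0.5
  freq <- sc$freq_hz
  idx <- freq + 1L
  samples <- numeric(n_frames * fs)
  bg_sd <- sqrt(10^(background_psd_db / 10) * fs / 2)
  for (i in seq_len(n_frames)) {
    x <- sc$sog_mps * (t_centers[i] - t_cpa)
    h <- sqrt(x^2 + sc$cpa_range_m^2)
    r <- sqrt(h^2 + (receiver_depth_m - d_s)^2)
    rl <- sc$sl_spectrum_db -
      modified_tl(freq, d_s, receiver_depth_m, r, sound_speed_mps)
    amp <- sqrt(2 * 10^(rl / 10))             # bin power -> sinusoid amplitude
    phase <- stats::runif(length(freq), 0, 2 * pi)
    z <- complex(length.out = fs)
    z[idx] <- (fs / 2) * amp * exp(1i * phase)
    z[fs - freq + 1L] <- Conj(z[idx])
    frame <- Re(stats::fft(z, inverse = TRUE)) / fs
    samples[((i - 1) * fs + 1):(i * fs)] <- frame
  }
  samples <- samples + stats::rnorm(length(samples), 0, bg_sd)
  ais_t <- unique(c(seq(0, sc$duration_s, by = 60), sc$duration_s))
  ais <- tibble::tibble(
    time_s = ais_t,
    x_m = sc$sog_mps * (ais_t - t_cpa),
    y_m = sc$cpa_range_m,
    sog_mps = sc$sog_mps,
    draft_m = sc$draft_m,
    vessel_id = sc$vessel_id
  )
  cpa_slant <- sqrt(sc$cpa_range_m^2 + (receiver_depth_m - d_s)^2)
  list(rec = recording(samples, fs, start_time_s = 0),
       ais = ais,
       truth = list(source_depth_m = d_s, cpa_time_s = t_cpa,
                    cpa_slant_range_m = cpa_slant,
                    broadband_sl_db = 10 * log10(sum(10^(sc$sl_spectrum_db / 10))),
                    sl_spectrum_db = sc$sl_spectrum_db,
                    background_bb_db = background_psd_db + 10 * log10(length(freq))))
}

#' Generate synthetic monthly sound-speed profiles
#'
#' Emulates an archive of oceanographic casts: profiles on the 15th of a
#' subset of the requested months (so the closest-date selection rule is
#' exercised by the uncovered months), with a seasonal surface signal
#' decaying toward a cooler bottom, all speeds within 1470-1530 m/s, down to
#' 580 m.
#'
#' @param months Character vector of `"YYYY-MM"` months.
#' @param n_profiles Number of months that receive a profile; must leave at
#'   least one month uncovered. Defaults to 30 profiles when 30 or more
#'   months are requested (the archive density the analysis assumes), else
#'   all but one month.
#' @param seed Integer RNG seed.
#' @return List of [sound_speed_profile()] objects, dated.
#' @export
generate_sound_speed_profiles <- function(months,
                                          n_profiles = min(30, length(months) - 1),
                                          seed = 1) {
  if (n_profiles >= length(months)) {
    stop("at least one month must lack a profile to exercise closest-date selection")
  }
  set.seed(seed)
  covered <- sort(sample(seq_along(months), n_profiles))
  depths <- seq(0, 580, by = 20)
  lapply(covered, function(i) {
    date <- as.Date(paste0(months[i], "-15"))
    month_num <- as.integer(format(date, "%m"))
    seasonal <- 8 * sin(2 * pi * (month_num - 3) / 12)
    sp <- 1500 - 20 * depths / 580 + seasonal * exp(-depths / 100) +
      stats::rnorm(length(depths), 0, 0.5)
    sp <- pmin(pmax(sp, 1470), 1530)
    sound_speed_profile(depths, sp, date)
  })
}
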