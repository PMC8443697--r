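#' Harmonic mean sound speed of a layered profile
#'
#' Reduces a layered sound-speed profile to the single effective speed used by
#' the transmission-loss model: total depth divided by the vertical travel
#' time through each constant-speed layer. The harmonic mean is always less
#' than or equal to the arithmetic mean of the layer speeds.
#'
#' @param profile A sound-speed profile as returned by
#'   [sound_speed_profile()], or any list with numeric `depth_m` (monotone
#'   increasing, starting at the surface) and `speed_mps` elements.
#' @return Harmonic mean sound speed in m/s.
#' @examples
#' prof <- sound_speed_profile(depth_m = c(0, 290, 580),
#'                             speed_mps = c(1500, 1480, 1480))
#' harmonic_mean_speed(prof)  # two equal-thickness layers at 1500 and 1480
#' @export
harmonic_mean_speed <- function(profile) {
  depth <- profile$depth_m
  speed <- profile$speed_mps
  stopifnot(length(depth) == length(speed), length(depth) >= 2)
  dz <- diff(depth)
  if (any(dz <= 0)) stop("profile depths must be strictly increasing (no zero-thickness layers)")
  # speed within layer i taken as the speed at the top of the layer
  c_layer <- speed[-length(speed)]
  sum(dz) / sum(dz / c_layer)
}

#' Construct a sound-speed profile
#'
#' @param depth_m Depths in metres, monotone increasing from the surface.
#' @param speed_mps Sound speed in m/s at each depth.
#' @param date Measurement date (`Date` or coercible); used by
#'   [select_profile()] for closest-date matching.
#' @return An object of class `sound_speed_profile`.
#' @export
sound_speed_profile <- function(depth_m, speed_mps, date = NA) {
  stopifnot(length(depth_m) == length(speed_mps), length(depth_m) >= 2)
  if (any(diff(depth_m) <= 0)) stop("depths must be strictly increasing")
  structure(
    list(depth_m = as.numeric(depth_m), speed_mps = as.numeric(speed_mps),
         date = if (is.na(date[1])) as.Date(NA) else as.Date(date)),
    class = "sound_speed_profile"
  )
}

#' Select the sound-speed profile closest in date to a given month
#'
#' Months without their own profile measurement are resolved to the profile
#' whose measurement date is closest to the midpoint (the 15th) of the month.
#' Ties are broken toward the earlier date, deterministically.
#'
#' @param profiles List of [sound_speed_profile()] objects with dates.
#' @param month Month as `"YYYY-MM"` string, or a `Date` within the month.
#' @return The selected `sound_speed_profile`.
#' @export
select_profile <- function(profiles, month) {
  if (length(profiles) == 0) stop("empty profile set")
  mid <- month_midpoint(month)
  dates <- as.Date(vapply(profiles, function(p) as.character(p$date), character(1)))
  if (anyNA(dates)) stop("all profiles must carry a measurement date")
  dist <- abs(as.numeric(dates - mid))
  best <- which(dist == min(dist))
  if (length(best) > 1) best <- best[which.min(as.numeric(dates[best]))]
  profiles[[best]]
}

month_midpoint <- function(month) {
  if (inherits(month, "Date")) {
    return(as.Date(format(month, "%Y-%m-15")))
  }
  as.Date(paste0(month, "-15"))
}

#' Propeller diameter from ship length
#'
#' Linear model relating propeller diameter to overall ship length, used to
#' place the effective acoustic source (propeller-tip cavitation) in depth.
#' The packaged default coefficients (`slope = 0.03` m per m of length,
#' `intercept = 0.5` m) are artifact defaults fitted to typical merchant-fleet
#' proportions, not measured values; supply fleet-specific coefficients or a
#' measured diameter where available.
#'
#' @param length_m Ship length in metres (> 0). Vectorised.
#' @param coef Named vector `c(intercept =, slope =)` overriding the default
#'   line.
#' @param measured_m Optional measured propeller diameter; when supplied it is
#'   returned unchanged, bypassing the model.
#' @return Propeller diameter in metres.
#' @examples
#' propeller_diameter(300) # 9.5 m with packaged defaults
#' @export
propeller_diameter <- function(length_m, coef = c(intercept = 0.5, slope = 0.03),
                               measured_m = NULL) {
  if (!is.null(measured_m)) return(measured_m)
  if (any(length_m <= 0)) stop("ship length must be positive")
  unname(coef[["intercept"]] + coef[["slope"]] * length_m)
}

#' Effective acoustic source depth
#'
#' The dominant noise source of a large ship is cavitation near the propeller
#' tip, so the effective source depth is the AIS-reported draft minus 85% of
#' the propeller diameter. Values are clamped below at `min_depth_m`
#' (default 0.3 m, the shallowest physically plausible source) with a warning.
#'
#' @param draft_m AIS-reported draft in metres (> 0). Vectorised.
#' @param prop_diameter_m Propeller diameter in metres, e.g. from
#'   [propeller_diameter()].
#' @param min_depth_m Lower clamp on source depth, metres.
#' @return Effective source depth in metres.
#' @examples
#' effective_source_depth(10, 7.4) # 3.71 m
#' @export
effective_source_depth <- function(draft_m, prop_diameter_m, min_depth_m = 0.3) {
  if (any(draft_m <= 0)) stop("draft must be positive")
  d <- draft_m - 0.85 * prop_diameter_m
  if (any(d < min_depth_m)) {
    warning(sprintf("%d source depth(s) clamped to %.1f m", sum(d < min_depth_m), min_depth_m))
    d <- pmax(d, min_depth_m)
  }
  d
}

#' Spherical spreading transmission loss
#'
#' @param range_m Slant range in metres (>= 1). Vectorised.
#' @return Transmission loss in dB: `20 * log10(range_m)`.
#' @export
spherical_tl <- function(range_m) {
  if (any(range_m < 1)) stop("range must be at least 1 m (source reference distance)")
  20 * log10(range_m)
}

#' Lloyd's-mirror (surface interference) transmission loss
#'
#' Two-ray image-source model of the interference between the direct path and
#' its sea-surface reflection. For a shallow source the surface image is in
#' antiphase, cancelling low frequencies and adding loss beyond spherical
#' spreading:
#' \deqn{TL = 20 \log_{10}\!\left(\frac{R}{2\,|\sin(k\, d_s d_r / R)|}\right),
#'       \quad k = 2\pi f / c .}
#' Near interference nulls (sine argument at multiples of pi) the loss is
#' clamped to `null_cap_db` above spherical so downstream energy integrals
#' stay finite.
#'
#' @param freq_hz Frequency in Hz (> 0). Vectorised.
#' @param source_depth_m Effective source depth \eqn{d_s}, metres.
#' @param receiver_depth_m Receiver depth \eqn{d_r}, metres (default 580).
#' @param slant_range_m Source-to-receiver slant range \eqn{R}, metres.
#' @param sound_speed_mps Harmonic-mean sound speed \eqn{c}, m/s.
#' @param null_cap_db Clamp, in dB above spherical loss, applied at
#'   interference nulls.
#' @return Transmission loss in dB.
#' @export
lloyd_tl <- function(freq_hz, source_depth_m, receiver_depth_m = 580,
                     slant_range_m, sound_speed_mps = 1500, null_cap_db = 40) {
  if (any(freq_hz <= 0)) stop("frequency must be positive")
  k <- 2 * pi * freq_hz / sound_speed_mps
  denom <- 2 * abs(sin(k * source_depth_m * receiver_depth_m / slant_range_m))
  sph <- spherical_tl(slant_range_m)
  tl <- ifelse(denom > 0, 20 * log10(slant_range_m / denom), Inf)
  pmin(tl, sph + null_cap_db)
}

#' Intersection frequency of the Lloyd's-mirror and spherical models
#'
#' The smallest frequency at which the two-ray surface-interference loss
#' equals spherical spreading, i.e. where \eqn{2|\sin(k d_s d_r / R)| = 1}.
#' The first crossing is at \eqn{k d_s d_r / R = \pi/6}, giving the closed
#' form \deqn{f^* = \frac{c\,R}{12\, d_s d_r}.}
#' Below \eqn{f^*} the interference adds loss; above it the piecewise model
#' switches to spherical spreading.
#'
#' @inheritParams lloyd_tl
#' @param min_freq_hz Lower edge of the analysis band (default 5 Hz). When
#'   \eqn{f^*} falls below it (deep source / long range) the model is
#'   spherical everywhere in band and `NA` is returned with a warning.
#' @return Intersection frequency in Hz, or `NA` for the degenerate case.
#' @examples
#' intersection_frequency(3.7, 580, 3000, 1500) # 174.7 Hz
#' @export
intersection_frequency <- function(source_depth_m, receiver_depth_m = 580,
                                   slant_range_m, sound_speed_mps = 1500,
                                   min_freq_hz = 5) {
  f_star <- sound_speed_mps * slant_range_m / (12 * source_depth_m * receiver_depth_m)
  if (f_star < min_freq_hz) {
    warning("intersection frequency below band; spherical spreading used throughout")
    return(NA_real_)
  }
  f_star
}

#' Modified Lloyd's-mirror transmission loss
#'
#' The piecewise propagation model used for all source-level and exposure
#' estimates: Lloyd's-mirror interference loss from the bottom of the band up
#' to the intersection frequency \eqn{f^*}, spherical spreading from
#' \eqn{f^*} to the top of the band. The two branches are equal at \eqn{f^*}
#' by construction, so the curve is continuous.
#'
#' @inheritParams lloyd_tl
#' @param band Analysis band limits in Hz, default `c(5, 1000)`; `freq_hz`
#'   must lie within it.
#' @return Transmission loss in dB, same length as `freq_hz`.
#' @export
modified_tl <- function(freq_hz, source_depth_m, receiver_depth_m = 580,
                        slant_range_m, sound_speed_mps = 1500,
                        band = c(5, 1000), null_cap_db = 40) {
  if (any(freq_hz < band[1] | freq_hz > band[2])) {
    stop(sprintf("frequency outside the %g-%g Hz analysis band", band[1], band[2]))
  }
  f_star <- suppressWarnings(
    intersection_frequency(source_depth_m, receiver_depth_m, slant_range_m,
                           sound_speed_mps, min_freq_hz = band[1])
  )
  sph <- spherical_tl(slant_range_m)
  if (is.na(f_star)) return(rep(sph, length(freq_hz)))
  ifelse(freq_hz < f_star,
         lloyd_tl(freq_hz, source_depth_m, receiver_depth_m, slant_range_m,
                  sound_speed_mps, null_cap_db),
         sph)
}
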