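#' Convert knots to metres per second
#'
#' One international knot is exactly 0.514444 m/s (1852 m per hour) for the
#' purposes of this package, matching the convention of vessel-speed-reduction
#' program target speeds (10 knots = 5.14 m/s, 12 knots = 6.17 m/s).
#'
#' @param knots Speed in knots (>= 0). Vectorised.
#' @return Speed in m/s.
#' @export
knots_to_mps <- function(knots) {
  if (any(knots < 0)) stop("speed must be non-negative")
  knots * 0.514444
}

#' @rdname knots_to_mps
#' @param mps Speed in m/s (>= 0).
#' @export
mps_to_knots <- function(mps) {
  if (any(mps < 0)) stop("speed must be non-negative")
  mps / 0.514444
}

#' Categorise a vessel type string
#'
#' Maps free-text AIS/registry vessel type descriptions onto the three
#' analysed cargo categories: container ships (including reefers), bulkers
#' (bulk carriers, general cargo, wood chip / timber carriers and other dry
#' cargo), and vehicle carriers (including roll-on roll-offs). Tankers were
#' never targeted by the speed-reduction program and map to `"excluded"`, as
#' does any unrecognised type.
#'
#' @param type_string Character vector of free-text vessel types.
#' @return Character vector with levels `container`, `bulker`,
#'   `vehicle_carrier`, `excluded`.
#' @examples
#' categorize_vessel(c("Reefer", "roll-on roll-off", "Crude Oil Tanker"))
#' @export
categorize_vessel <- function(type_string) {
  s <- tolower(trimws(type_string))
  out <- rep("excluded", length(s))
  out[grepl("container|reefer", s)] <- "container"
  out[grepl("bulk|general cargo|wood chip|timber|cargo", s) &
        !grepl("container|tanker", s)] <- "bulker"
  out[grepl("vehicle|roll-?on|ro-?ro|car carrier", s)] <- "vehicle_carrier"
  out[grepl("tanker", s)] <- "excluded"
  out
}

#' Closest point of approach of an AIS track to the receiver
#'
#' Positions are linearly interpolated between fixes at 1-s resolution in a
#' local planar frame centred on the receiver; the CPA is the minimum
#' horizontal range over the interpolated track. Speed over ground at CPA is
#' linearly interpolated between the bracketing fixes. The slant range adds
#' the vertical separation between the (near-surface) source and the receiver
#' once the effective source depth is known.
#'
#' @param fixes Data frame of AIS fixes with columns `time_s` (strictly
#'   increasing), `x_m`, `y_m` (receiver at the origin), `sog_mps`.
#' @param receiver_depth_m Receiver depth in metres (default 580).
#' @param source_depth_m Effective source depth in metres; `NA` leaves the
#'   slant range computed for a surface source.
#' @return A list of class `cpa_info`: `time_s`, `horizontal_range_m`,
#'   `slant_range_m`, `sog_at_cpa_mps`.
#' @export
compute_cpa <- function(fixes, receiver_depth_m = 580, source_depth_m = 0) {
  if (nrow(fixes) < 2) stop("CPA requires at least two AIS fixes")
  if (any(diff(fixes$time_s) <= 0)) stop("fix times must be strictly increasing")
  tt <- seq(ceiling(fixes$time_s[1]), floor(fixes$time_s[nrow(fixes)]), by = 1)
  x <- stats::approx(fixes$time_s, fixes$x_m, xout = tt)$y
  y <- stats::approx(fixes$time_s, fixes$y_m, xout = tt)$y
  r <- sqrt(x^2 + y^2)
  i <- which.min(r)
  sog <- stats::approx(fixes$time_s, fixes$sog_mps, xout = tt[i])$y
  ds <- if (is.na(source_depth_m)) 0 else source_depth_m
  structure(
    list(time_s = tt[i],
         horizontal_range_m = r[i],
         slant_range_m = sqrt(r[i]^2 + (receiver_depth_m - ds)^2),
         sog_at_cpa_mps = sog),
    class = "cpa_info"
  )
}

#' Restrict a track to the monitoring area
#'
#' Keeps the fixes whose horizontal range from the receiver is within the
#' monitoring radius (boundary inclusive). An optional lane mask excludes
#' whole tracks on a non-monitored shipping lane (e.g. the southbound lane of
#' a traffic separation scheme): a predicate receiving the fix table and
#' returning `TRUE` when the track should be dropped.
#'
#' @param fixes AIS fix data frame (`time_s`, `x_m`, `y_m`, ...).
#' @param radius_m Monitoring radius in metres, default 6000.
#' @param lane_mask Optional `function(fixes) -> logical(1)`; `TRUE` drops
#'   the track entirely.
#' @return The in-area subset of `fixes` (possibly zero rows).
#' @export
filter_monitoring_area <- function(fixes, radius_m = 6000, lane_mask = NULL) {
  if (!is.null(lane_mask) && isTRUE(lane_mask(fixes))) {
    return(fixes[0, , drop = FALSE])
  }
  r <- sqrt(fixes$x_m^2 + fixes$y_m^2)
  fixes[r <= radius_m, , drop = FALSE]
}

transit_interval <- function(transit) {
  t <- transit$fixes$time_s
  c(start = min(t), end = max(t))
}

#' Acoustic isolation filter
#'
#' Removes every transit whose in-area interval comes within `window_s`
#' (default one hour) of another transit's interval, so that each retained
#' passage is acoustically isolated. Both members of a violating pair are
#' removed (the contamination is mutual). Overlapping intervals count as a
#' zero gap.
#'
#' Isolation is a property of the complete traffic picture: a neighbouring
#' vessel contaminates the recording even if its own transit is later
#' discarded by another quality filter. Gaps are therefore assessed against
#' `inventory`, which should be the full set of in-area transits; it
#' defaults to `transits` itself. Anchoring to the full inventory also makes
#' the quality filters order-independent.
#'
#' @param transits List of transit objects (each with a `fixes` table of
#'   in-area fixes).
#' @param window_s Minimum required gap between in-area intervals, seconds.
#' @param inventory Full list of in-area transits against which isolation is
#'   judged; defaults to `transits`.
#' @return The retained subset of `transits`.
#' @export
isolation_filter <- function(transits, window_s = 3600, inventory = transits) {
  n <- length(transits)
  if (n == 0) return(transits)
  iv <- t(vapply(transits, transit_interval, numeric(2)))
  inv <- t(vapply(inventory, transit_interval, numeric(2)))
  tr_key <- function(t, iv_row) {
    paste(iv_row["start"], iv_row["end"],
          if (is.null(t$vessel)) "" else t$vessel$id)
  }
  keys <- vapply(seq_len(n), function(i) tr_key(transits[[i]], iv[i, ]), "")
  inv_keys <- vapply(seq_along(inventory),
                     function(j) tr_key(inventory[[j]], inv[j, ]), "")
  bad <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(inv))) {
      if (keys[i] == inv_keys[j]) next
      gap <- max(iv[i, "start"], inv[j, "start"]) -
        min(iv[i, "end"], inv[j, "end"])
      if (gap < window_s) {
        bad[i] <- TRUE
        break
      }
    }
  }
  transits[!bad]
}

#' Wind-speed filter
#'
#' Drops transits whose wind speed at CPA time (nearest sample in the wind
#' series) strictly exceeds the threshold; high wind raises ambient noise
#' beyond the measurement standard's environmental limits. A transit whose
#' CPA time is not covered by the wind series (nearest sample further than
#' `max_gap_s` away) is flagged via warning and retained with
#' `wind_missing = TRUE` rather than silently passed.
#'
#' @param transits List of transits, each carrying a `cpa` element from
#'   [compute_cpa()].
#' @param wind Data frame with columns `time_s`, `speed_mps`.
#' @param threshold_mps Wind threshold, default 10.28 m/s (20 knots); strict
#'   inequality, so exactly 10.28 m/s is kept.
#' @param max_gap_s Maximum tolerated distance to the nearest wind sample.
#' @return Retained transits; each gains `wind_mps` and `wind_missing`.
#' @export
wind_filter <- function(transits, wind, threshold_mps = 10.28, max_gap_s = 3600) {
  keep <- logical(length(transits))
  for (i in seq_along(transits)) {
    tr <- transits[[i]]
    gaps <- abs(wind$time_s - tr$cpa$time_s)
    j <- which.min(gaps)
    if (gaps[j] > max_gap_s) {
      warning(sprintf("transit %d: no wind sample within %.0f s of CPA; flagged", i, max_gap_s))
      tr$wind_mps <- NA_real_
      tr$wind_missing <- TRUE
      keep[i] <- TRUE
    } else {
      tr$wind_mps <- wind$speed_mps[j]
      tr$wind_missing <- FALSE
      keep[i] <- !(tr$wind_mps > threshold_mps)
    }
    transits[[i]] <- tr
  }
  transits[keep]
}

#' Label transits against a transit-by-transit reward list
#'
#' Matches each transit to the program-supplied reward list by vessel
#' identifier (IMO) and time: a transit is `rewarded` when its in-area
#' interval overlaps a reward entry for the same vessel, `control` when the
#' vessel participates in the program but this transit has no matching reward
#' entry, and unlabelled (`NA`) for non-participating vessels. A transit
#' overlapping more than one reward entry is ambiguous and raises an error.
#'
#' @param transits List of transits, each with `vessel$id` and a `fixes`
#'   table.
#' @param reward_list Data frame with columns `imo`, `start_s`, `end_s`
#'   giving the rewarded transit intervals.
#' @return `transits`, each gaining a `group` element of `"rewarded"`,
#'   `"control"` or `NA`.
#' @export
label_transit_by_transit <- function(transits, reward_list) {
  participants <- unique(reward_list$imo)
  for (i in seq_along(transits)) {
    tr <- transits[[i]]
    iv <- transit_interval(tr)
    hits <- which(reward_list$imo == tr$vessel$id &
                    reward_list$start_s <= iv["end"] &
                    reward_list$end_s >= iv["start"])
    if (length(hits) > 1) {
      stop(sprintf("transit of vessel %s matches %d reward entries (ambiguous)",
                   tr$vessel$id, length(hits)))
    }
    tr$group <- if (length(hits) == 1) {
      "rewarded"
    } else if (tr$vessel$id %in% participants) {
      "control"
    } else {
      NA_character_
    }
    transits[[i]] <- tr
  }
  transits
}

#' Award tier from fleet percent cooperation
#'
#' Bins a fleet's percent of cooperating (slowed) transit miles into the
#' program's award tiers: sapphire 75-100%, gold 50-74%, silver 25-49%,
#' bronze 10-24%, non-compliant 0-9%. Fractional percentages are floored to
#' the printed integer bands.
#'
#' @param percent Percent cooperation in `[0, 100]`. Vectorised.
#' @return Character vector of tiers.
#' @examples
#' cooperation_tier(c(80, 25, 9.5))
#' @export
cooperation_tier <- function(percent) {
  if (any(percent < 0 | percent > 100)) stop("percent cooperation must be in [0, 100]")
  p <- floor(percent)
  cut(p, breaks = c(-1, 9, 24, 49, 74, 100),
      labels = c("non_compliant", "bronze", "silver", "gold", "sapphire")) |>
    as.character()
}

#' Is a date inside the program-active window?
#'
#' The speed-reduction program runs each year from July 1 through November 15
#' inclusive; the remaining months serve as the program-inactive baseline.
#'
#' @param date `Date` vector.
#' @return Logical vector.
#' @export
program_active <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  (m >= 7 & m <= 10) | (m == 11 & d <= 15)
}
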