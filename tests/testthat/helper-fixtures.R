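# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# Straight constant-speed AIS track along x at perpendicular offset y0,
# receiver at the origin.
straight_track <- function(y0 = 3000, sog = 10, t_span = c(0, 1000),
                           fix_dt = 100, draft = 10) {
  tt <- seq(t_span[1], t_span[2], by = fix_dt)
  t_mid <- mean(t_span)
  tibble::tibble(time_s = tt, x_m = sog * (tt - t_mid), y_m = y0,
                 sog_mps = sog, draft_m = draft, vessel_id = "T-0001")
}

# Minimal transit object as consumed by the filter functions.
make_transit <- function(t_start, t_end, id = "IMO0000001", cpa_time = NULL) {
  tr <- list(
    fixes = tibble::tibble(time_s = c(t_start, t_end),
                           x_m = c(-100, 100), y_m = 3000,
                           sog_mps = 10, draft_m = 10),
    vessel = list(id = id)
  )
  if (!is.null(cpa_time)) {
    tr$cpa <- list(time_s = cpa_time)
  }
  tr
}

# Hand-built spectrum_series with constant levels, for closed-form checks.
flat_series <- function(level_db, n_frames = 10, freq = 5:1000) {
  structure(list(times_s = seq_len(n_frames) - 0.5, freq_hz = freq,
                 levels_db = matrix(level_db, n_frames, length(freq)),
                 fs = 10000),
            class = "spectrum_series")
}
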