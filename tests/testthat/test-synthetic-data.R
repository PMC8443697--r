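test_that("speed-level law derives residual spread from a target r-squared", {
  law <- speed_level_law(2.0, 179.6, r_squared = 0.32, sog_sd = 1.9)
  expect_equal(law$residual_sd, 2.0 * 1.9 * sqrt(1 / 0.32 - 1))  # ~5.54 dB
  expect_error(speed_level_law(2, 180, r_squared = 0, sog_sd = 1.9),
               "r_squared")
  expect_error(speed_level_law(2, 180, r_squared = 1.2, sog_sd = 1.9),
               "r_squared")
  expect_error(speed_level_law(2, 180), "residual_sd")
})

test_that("zero-noise law with fixed SOG is exactly linear", {
  g <- group_spec("fixed", 50, sog_mean = 7.3, sog_sd = 0)
  law <- speed_level_law(2.0, 179.6, residual_sd = 0)
  tr <- generate_summary_transits(g, sl_law = law, sel_law = law, seed = 5)
  expect_equal(nrow(tr), 50)
  expect_equal(tr$sog_mps, rep(7.3, 50))
  expect_equal(tr$sl_db, rep(179.6 + 14.6, 50))
})

test_that("group-mean mode recovers the specified moments at large n", {
  big <- dplyr::mutate(program_group_specs(), n = 1000000L)
  tr <- generate_summary_transits(big, seed = 20)
  s <- summarize_groups(tr)
  ctrl <- s[s$group == "control", ]
  rew <- s[s$group == "rewarded", ]
  expect_equal(ctrl$sl_db_mean, 194.4, tolerance = 0.02 / 194.4)
  expect_equal(rew$sl_db_mean, 189.2, tolerance = 0.02 / 189.2)
  expect_equal(ctrl$sl_db_sd, 6.5, tolerance = 0.01)
  expect_equal(rew$sel_db_mean, 152.4, tolerance = 0.02 / 152.4)
  # SOG is truncated at 0.5 m/s but far enough from the mean to be unbiased
  expect_equal(ctrl$sog_mps_mean, 7.9, tolerance = 0.01)
  expect_true(all(tr$sog_mps >= 0.5))
})

test_that("law mode reproduces the requested r-squared", {
  g <- group_spec("all", 100000, sog_mean = 7.3, sog_sd = 1.9)
  law <- speed_level_law(2.0, 179.6, r_squared = 0.32, sog_sd = 1.9)
  tr <- generate_summary_transits(g, sl_law = law, seed = 8)
  fit <- speed_level_regression(tr, "sl_db")
  expect_equal(fit$r_squared, 0.32, tolerance = 0.02)
  expect_equal(fit$slope, 2.0, tolerance = 0.05)
})

test_that("summary generation is deterministic in the seed", {
  g <- program_group_specs()
  a <- generate_summary_transits(g, seed = 33)
  b <- generate_summary_transits(g, seed = 33)
  c3 <- generate_summary_transits(g, seed = 34)
  expect_identical(a, b)
  expect_false(identical(a, c3))
  expect_error(generate_summary_transits(dplyr::mutate(g, n = 0L)), "positive")
})

test_that("packaged study-condition specs have the documented structure", {
  st <- ship_type_specs()
  expect_equal(sum(st$n[st$label != "all"]), st$n[st$label == "all"])
  pg <- program_group_specs()
  expect_equal(pg$n, c(109L, 43L))
  ft <- fleet_tier_specs()
  expect_equal(nrow(ft), 10)
  expect_equal(sort(unique(ft$phase)), c("active", "inactive"))
})

test_that("rendered background-only recording matches the configured level", {
  sc <- ship_scenario(250, 10, 8, 2000, broadband_sl_db = 30, duration_s = 20)
  pw <- render_passage_waveform(sc, background_psd_db = 60, seed = 3)
  bb <- mean(broadband_series(psd_series(pw$rec)))
  expect_equal(bb, 60 + 10 * log10(996), tolerance = 0.5)
})

test_that("rendered passages round-trip through the full pipeline", {
  sc <- ship_scenario(length_m = 250, draft_m = 10, sog_mps = 8,
                      cpa_range_m = 2000, broadband_sl_db = 192,
                      duration_s = 180)
  pw <- render_passage_waveform(sc, background_psd_db = 60, seed = 7)
  expect_true(all(diff(pw$ais$time_s) <= 60))
  expect_equal(range(pw$ais$time_s), c(0, 180))
  est <- estimate_transit_levels(pw$rec, pw$ais, length_m = 250,
                                 background_db = pw$truth$background_bb_db)
  expect_lt(abs(est$broadband_sl_db - pw$truth$broadband_sl_db), 1.0)
  expect_equal(est$source_depth_m, pw$truth$source_depth_m)
  expect_lt(abs(est$cpa$slant_range_m - pw$truth$cpa_slant_range_m), 5)
  # identical seed gives an identical waveform
  pw2 <- render_passage_waveform(sc, background_psd_db = 60, seed = 7)
  expect_identical(pw$rec$samples, pw2$rec$samples)
  expect_error(ship_scenario(250, 10, 8, 0), "undefined geometry")
  expect_error(ship_scenario(250, 10, 8, 2000, freq_hz = 50:500), "span")
})

test_that("a law-driven SOG pair round-trips the slope through the pipeline", {
  law <- speed_level_law(2.0, 179.6, residual_sd = 0)
  ests <- lapply(c(5, 10), function(v) {
    sc <- ship_scenario(200, 10, v, 1500,
                        broadband_sl_db = law$intercept + law$slope * v,
                        duration_s = 120)
    pw <- render_passage_waveform(sc, background_psd_db = 55, seed = 13)
    estimate_transit_levels(pw$rec, pw$ais, 200,
                            background_db = pw$truth$background_bb_db)
  })
  diff_est <- ests[[2]]$broadband_sl_db - ests[[1]]$broadband_sl_db
  expect_lt(abs(diff_est - 2.0 * 5), 1.0)
})

test_that("synthetic profile archive exercises closest-date selection", {
  months <- format(seq(as.Date("2014-01-15"), by = "month", length.out = 49),
                   "%Y-%m")
  profs <- generate_sound_speed_profiles(months, n_profiles = 30, seed = 2)
  expect_length(profs, 30)
  covered <- vapply(profs, function(p) format(p$date, "%Y-%m"), "")
  expect_equal(sum(!months %in% covered), 19)
  for (p in profs) {
    expect_true(all(p$speed_mps >= 1470 & p$speed_mps <= 1530))
    expect_equal(max(p$depth_m), 580)
    expect_true(all(diff(p$depth_m) > 0))
  }
  # every month resolves to some profile; covered months resolve to their own
  own <- select_profile(profs, covered[1])
  expect_equal(format(own$date, "%Y-%m"), covered[1])
  expect_error(generate_sound_speed_profiles(months, n_profiles = 49), "lack")
  expect_identical(
    generate_sound_speed_profiles(months, seed = 5)[[1]]$speed_mps,
    generate_sound_speed_profiles(months, seed = 5)[[1]]$speed_mps)
})

test_that("scenario YAML and tabular CSVs round-trip", {
  sc <- ship_scenario(220, 9, 7, 1800, broadband_sl_db = 190, duration_s = 60)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, p)
  sc2 <- read_scenario_yaml(p)
  expect_equal(sc2$sl_spectrum_db, sc$sl_spectrum_db, tolerance = 1e-9)
  expect_equal(sc2$cpa_range_m, sc$cpa_range_m)

  ais <- straight_track()
  pa <- withr::local_tempfile(fileext = ".csv")
  write_ais_csv(ais, pa)
  expect_equal(read_ais_csv(pa)$x_m, ais$x_m)

  profs <- generate_sound_speed_profiles(c("2015-01", "2015-02", "2015-03"),
                                         n_profiles = 2, seed = 1)
  pp <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(profs, pp)
  back <- read_profiles_csv(pp)
  expect_length(back, 2)
  expect_equal(sort(vapply(back, function(p) as.character(p$date), "")),
               sort(vapply(profs, function(p) as.character(p$date), "")))
})
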