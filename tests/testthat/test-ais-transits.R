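test_that("knot conversion matches program target speeds and round-trips", {
  expect_equal(round(knots_to_mps(10), 2), 5.14)
  expect_equal(round(knots_to_mps(12), 2), 6.17)
  expect_equal(knots_to_mps(0), 0)
  expect_equal(mps_to_knots(knots_to_mps(c(1, 7.3, 20))), c(1, 7.3, 20))
  expect_error(knots_to_mps(-1), "non-negative")
})

test_that("vessel type strings map to the three analysed categories", {
  expect_equal(categorize_vessel("reefer"), "container")
  expect_equal(categorize_vessel("Container Ship"), "container")
  expect_equal(categorize_vessel("roll-on roll-off"), "vehicle_carrier")
  expect_equal(categorize_vessel("Vehicle Carrier"), "vehicle_carrier")
  expect_equal(categorize_vessel(c("bulk carrier", "general cargo",
                                   "wood chip carrier", "timber carrier")),
               rep("bulker", 4))
  expect_equal(categorize_vessel("Crude Oil Tanker"), "excluded")
  expect_equal(categorize_vessel("research vessel"), "excluded")
})

test_that("CPA of a straight track matches perpendicular-foot geometry", {
  fixes <- straight_track(y0 = 3000, sog = 10, t_span = c(0, 1000))
  cpa <- compute_cpa(fixes, receiver_depth_m = 580, source_depth_m = 0)
  # analytic oracle: minimum distance of the line y = 3000 to the origin
  expect_lt(abs(cpa$horizontal_range_m - 3000), 1)
  expect_equal(cpa$time_s, 500, tolerance = 1)
  expect_equal(cpa$sog_at_cpa_mps, 10)
  expect_equal(cpa$slant_range_m,
               sqrt(cpa$horizontal_range_m^2 + 580^2))
})

test_that("track through the origin gives slant range equal to receiver depth", {
  fixes <- straight_track(y0 = 0, sog = 8, t_span = c(0, 600))
  cpa <- compute_cpa(fixes, receiver_depth_m = 580, source_depth_m = 0)
  expect_lt(cpa$horizontal_range_m, 4)      # 1-s grid quantisation
  expect_equal(cpa$slant_range_m, sqrt(cpa$horizontal_range_m^2 + 580^2))
  expect_lt(abs(cpa$slant_range_m - 580), 0.02)
})

test_that("CPA on a polyline equals a segment-wise analytic minimum", {
  fixes <- tibble::tibble(
    time_s = c(0, 400, 900),
    x_m = c(-4000, -500, 3500),
    y_m = c(3500, 2500, 3200),
    sog_mps = c(9, 9, 9)
  )
  cpa <- compute_cpa(fixes)
  # oracle: per-segment point-to-origin minimum via projection
  seg_min <- function(p1, p2) {
    d <- p2 - p1
    t <- max(0, min(1, -sum(p1 * d) / sum(d * d)))
    sqrt(sum((p1 + t * d)^2))
  }
  oracle <- min(seg_min(c(-4000, 3500), c(-500, 2500)),
                seg_min(c(-500, 2500), c(3500, 3200)))
  expect_lt(abs(cpa$horizontal_range_m - oracle), 1)
  expect_error(compute_cpa(fixes[1, ]), "two")
})

test_that("monitoring-area filter is boundary-inclusive and clips tracks", {
  fixes <- tibble::tibble(time_s = 1:5,
                          x_m = c(-8000, -6001, -6000, 0, 7000),
                          y_m = 0, sog_mps = 10)
  kept <- filter_monitoring_area(fixes)
  expect_equal(kept$x_m, c(-6000, 0))       # 6001 m dropped, 6000 m kept
  # lane mask drops the whole track
  masked <- filter_monitoring_area(fixes, lane_mask = function(f) all(f$y_m >= 0))
  expect_equal(nrow(masked), 0)
})

test_that("isolation filter removes both members of close pairs", {
  a <- make_transit(0, 600)
  b <- make_transit(1800, 2400)             # 30 min after a: both go
  c3 <- make_transit(7200, 7800)            # 2 h: gap from b is 4800 s, kept
  expect_length(isolation_filter(list(a)), 1)
  expect_length(isolation_filter(list(a, b)), 0)
  kept <- isolation_filter(list(a, b, c3))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$fixes$time_s[1], 7200)
  # exactly one hour of separation is acceptable
  d <- make_transit(600 + 3600, 600 + 4200)
  expect_length(isolation_filter(list(a, d)), 2)
})

test_that("wind filter uses a strict threshold at the CPA-nearest sample", {
  wind <- tibble::tibble(time_s = c(0, 1000, 2000),
                         speed_mps = c(5, 10.29, 10.28))
  t_ok <- make_transit(1900, 2100, cpa_time = 2000)    # wind 10.28: kept
  t_hi <- make_transit(900, 1100, cpa_time = 1000)     # wind 10.29: dropped
  t_lo <- make_transit(-100, 100, cpa_time = 0)
  kept <- wind_filter(list(t_ok, t_hi, t_lo), wind)
  expect_length(kept, 2)
  expect_equal(sort(vapply(kept, function(t) t$wind_mps, numeric(1))),
               c(5, 10.28))
  # missing coverage: flagged and retained with a warning, never silent
  t_far <- make_transit(99000, 99200, cpa_time = 99100)
  expect_warning(kept2 <- wind_filter(list(t_far), wind), "flagged")
  expect_true(kept2[[1]]$wind_missing)
})

test_that("reward-list labelling distinguishes rewarded, control, unlabelled", {
  rewards <- tibble::tibble(imo = c("IMO1", "IMO1", "IMO2"),
                            start_s = c(0, 10000, 0),
                            end_s = c(1000, 11000, 1000))
  tr_match <- make_transit(500, 900, id = "IMO1")
  tr_ctrl <- make_transit(5000, 5400, id = "IMO1")
  tr_unknown <- make_transit(500, 900, id = "IMO9")
  out <- label_transit_by_transit(list(tr_match, tr_ctrl, tr_unknown), rewards)
  expect_equal(vapply(out, function(t) t$group, character(1)),
               c("rewarded", "control", NA))
  # overlapping reward entries for the same vessel are ambiguous
  dup <- tibble::tibble(imo = "IMO1", start_s = c(0, 500), end_s = c(1000, 1500))
  expect_error(label_transit_by_transit(list(tr_match), dup), "ambiguous")
})

test_that("cooperation percentages bin into the printed award tiers", {
  expect_equal(cooperation_tier(c(80, 75, 100)), rep("sapphire", 3))
  expect_equal(cooperation_tier(c(50, 74)), rep("gold", 2))
  expect_equal(cooperation_tier(c(25, 49)), rep("silver", 2))
  expect_equal(cooperation_tier(c(10, 24)), rep("bronze", 2))
  expect_equal(cooperation_tier(c(0, 9, 9.5)), rep("non_compliant", 3))
  expect_equal(cooperation_tier(74.9), "gold")   # floored to integer bands
  expect_error(cooperation_tier(101), "\\[0, 100\\]")
})

test_that("program calendar covers July 1 through November 15 inclusive", {
  expect_true(all(program_active(as.Date(c("2018-07-01", "2018-09-10",
                                           "2018-11-15")))))
  expect_false(any(program_active(as.Date(c("2018-06-30", "2018-11-16",
                                            "2018-01-05")))))
})

test_that("isolation and wind filters commute", {
  wt <- seq(0, 51000, by = 500)
  wind <- tibble::tibble(time_s = wt,
                         speed_mps = ifelse((wt / 500) %% 2 == 0, 4, 12))
  # mix of isolation violations (0/1800, 50000/50500) and windy CPAs
  starts <- c(0, 1800, 9000, 15300, 24000, 30300, 40000, 50000, 50500)
  transits <- lapply(starts, function(s) {
    make_transit(s, s + 400, cpa_time = s + 200)
  })
  # isolation judged against the full inventory in both orders
  ids_a <- vapply(wind_filter(isolation_filter(transits), wind),
                  function(t) t$cpa$time_s, numeric(1))
  ids_b <- vapply(isolation_filter(wind_filter(transits, wind),
                                   inventory = transits),
                  function(t) t$cpa$time_s, numeric(1))
  expect_equal(sort(ids_a), sort(ids_b))
  expect_equal(sort(ids_a), c(9200, 24200, 40200))
})
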