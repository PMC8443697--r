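# vsrnoise

Underwater radiated noise from commercial shipping is the dominant source of
low-frequency (5–1000 Hz) sound in coastal shipping corridors, and a ship's
radiated noise rises steeply with its speed. `vsrnoise` is an R package for
quantifying that relationship and for evaluating incentive-based
**vessel speed reduction (VSR)** programs: it estimates per-transit ship
**source levels (SL)** and **sound exposure levels (SEL)** from single-channel
deep-water hydrophone recordings paired with AIS vessel tracks, and compares
noise across program participation groups (rewarded vs. control transits, and
fleet award tiers binned by percent cooperation).

It is written for bioacousticians and marine resource managers who need a
tested, reproducible version of this analysis chain — and, because the archival
recordings such studies use are rarely deposited, it ships a synthetic-data
module that generates both summary transit tables and full passage waveforms
with the statistical and physical structure the analysis assumes, so every
stage is verifiable end to end.

## The model

Source levels are estimated from received levels by compensating the
transmission loss at the closest point of approach (CPA):

    SL(f) = RL(f) + TL(f)

* **RL(f)** — calibrated power spectral density in 1-Hz bins (1-s Hann
  frames, no overlap), averaged in linear power over the *data window
  period* (the time the ship takes to travel its own length), with
  broadband values power-summed over 5–1000 Hz.
* **TL(f)** — a *modified Lloyd's-mirror* model. Below the crossover
  frequency f\*, the sea-surface image source interferes with the direct
  path:

      TL_LM = 20·log10( R / (2·|sin(k·d_s·d_r / R)|) ),   k = 2πf/c

  with effective source depth d\_s = draft − 0.85·(propeller diameter),
  receiver depth d\_r, slant range R, and harmonic-mean sound speed c from
  the closest-dated sound-speed profile. From f\* = c·R/(12·d\_s·d\_r) up to
  1 kHz, spherical spreading 20·log10(R) applies; the two branches meet
  continuously at f\*.
* **SEL** — the passage energy integrated as if the ship transited directly
  overhead:

      SEL = 10·log10 ∫₀ᵀ Σ_f 10^((SL(f) − TL(f,t))/10) dt

  where T is the contiguous span around CPA with modelled broadband RL at
  least 15 dB above background, evaluated at 1-min steps.

Group effects are tested with a Welch t-test (transit-by-transit program) and
with Kruskal–Wallis plus Dunn's post-hoc z-tests under Benjamini–Hochberg
adjustment (fleet award tiers by program phase).

## Worked example

Render a synthetic container-ship passage (250 m, 10 m draft, 8 m/s, 2 km
CPA, 192 dB broadband SL) and push it through the full pipeline:

```r
library(vsrnoise)

sc <- ship_scenario(length_m = 250, draft_m = 10, sog_mps = 8,
                    cpa_range_m = 2000, broadband_sl_db = 192, duration_s = 180)
pw  <- render_passage_waveform(sc, background_psd_db = 60, seed = 7)
est <- estimate_transit_levels(pw$rec, pw$ais, length_m = 250,
                               background_db = pw$truth$background_bb_db)
as_results_row(est, transit_id = "demo-01", category = "container")
#>   transit_id category  sog_mps rl_db sl_db sel_db duration_s source_depth_m f_star_hz
#> 1 demo-01    container       8  124.  192.   159.       2820            3.2      140.
```

The recovered broadband SL (192.0 dB re 1 μPa² @ 1 m) matches the rendered
truth to within 0.03 dB; the effective source depth (3.2 m = 10 − 0.85·8)
puts the Lloyd's-mirror/spherical crossover at 140 Hz for this geometry.

Simulate the transit-by-transit program groups and test the effect:

```r
tr <- generate_summary_transits(program_group_specs(), seed = 1)
summarize_groups(tr)
#>   group        n sog_mps_mean sl_db_mean sl_db_sd sel_db_mean
#> 1 control    109         8.03       194.     6.05        157.
#> 2 rewarded    43         5.42       190.     3.60        152.

transit_by_transit_test(tr$sl_db[tr$group == "control"],
                        tr$sl_db[tr$group == "rewarded"])
#> Welch t = 5.02, df = 126.5, p = 1.7e-06, mean diff = 4.01 dB
```

A single 152-transit draw already shows the rewarded fleet ~4 dB quieter at
high significance; averaging over many replicates converges to the 5.2 dB SL
reduction the group specifications encode.

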