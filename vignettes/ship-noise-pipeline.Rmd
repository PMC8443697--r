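---
title: "Estimating ship source levels and speed-reduction noise benefits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ship source levels and speed-reduction noise benefits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsrnoise)
```

## The problem

Voluntary vessel-speed-reduction (VSR) programs ask commercial ships to slow
to 10–12 knots through sensitive habitat, originally to cut ship-strike risk
and air emissions. Because radiated noise rises with speed, slowing ships
should also quiet them — but demonstrating that requires estimating each
transit's **source level** (SL, dB re 1 μPa² @ 1 m) and **sound exposure
level** (SEL, dB re 1 μPa²·s) from a fixed hydrophone, then comparing
participating and non-participating traffic. `vsrnoise` implements that
chain: AIS track processing, calibrated spectral received levels, a
surface-interference propagation model, exposure integration, and the group
statistics.

## Propagation model and its assumptions

The receiver sits deep (default 580 m) while ship noise originates within
metres of the surface, so the direct path and its surface reflection arrive
nearly superimposed. For a shallow source the reflection is phase-inverted,
cancelling low frequencies — the Lloyd's-mirror effect. We model transmission
loss piecewise:

$$TL(f) = \begin{cases}
20\log_{10}\dfrac{R}{2\,\lvert\sin(k d_s d_r / R)\rvert}, & f < f^\*\\[4pt]
20\log_{10} R, & f \ge f^\*
\end{cases}
\qquad k = \frac{2\pi f}{c}$$

The crossover is the first frequency where the two branches are equal;
because $2\sin x = 1$ at $x = \pi/6$ exactly,

$$f^\* = \frac{c\,R}{12\, d_s d_r}.$$

Assumptions worth keeping in mind:

* **Straight-ray, range-independent sound speed.** The layered profile is
  collapsed to its harmonic mean (total depth over summed per-layer travel
  time). No refraction: the model fits best when the water column is close
  to homogeneous (spring mixed-layer conditions) and degrades under strong
  fall stratification.
* **Image-source interference only below $f^\*$.** Above the crossover the
  interference pattern oscillates rapidly and averages out in 1-Hz bins, so
  plain spherical spreading is used. Below it, the first interference lobe
  dominates and only *adds* loss relative to spherical — an invariant the
  test suite checks across the whole band.
* **Effective source depth** is draft minus 85% of the propeller diameter
  (cavitation concentrates at the propeller tip). Propeller diameter comes
  from a linear length model with packaged coefficients (0.5 m + 0.03·L);
  these are artifact defaults representative of merchant-fleet proportions,
  not fitted to any published measurement set — override them (or supply a
  measured diameter) where real fleet data exist.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| receiver depth | 580 | m | deep seafloor package next to a shipping lane |
| analysis band | 5–1000 | Hz | band where ships dominate the soundscape; 996 one-Hz bins inclusive |
| monitoring radius | 6000 | m | boundary inclusive |
| isolation window | 3600 | s | both members of a violating pair removed |
| wind threshold | 10.28 | m/s | strict inequality (exactly 10.28 is kept) |
| above-background threshold | 15 | dB | exposure-duration definition |
| SEL time step | 60 | s | rectangle rule; 1-s oracle bounds the error < 0.2 dB |
| source-depth clamp | 0.3 | m | shallowest physically plausible source |
| interference-null cap | +40 | dB over spherical | keeps energy integrals finite at nulls |
| decimation filter | Chebyshev I, order 8, 0.05 dB ripple, 0.8× target Nyquist | — | standard anti-alias practice |

## Numerical choices

* **Window scaling.** The 1-s Hann frames are normalised by the window's
  noise power ($\sum w^2$), so broadband levels of noise-like signals are
  unbiased; a pure tone's power is spread over ±1 bin but its band sum is
  exact. Averaging over the data window period happens in linear power,
  never in dB.
* **Band edges.** 5 and 1000 Hz inclusive → 996 bins; one definition used
  everywhere (a flat spectrum's broadband is exactly $L + 10\log_{10}996$).
* **Data window alignment.** Centred on the CPA time; frames whose centres
  fall inside the window are averaged.
* **CPA.** Positions interpolated linearly at 1-s resolution between fixes;
  CPA is the minimum horizontal range; SOG interpolated between bracketing
  fixes. The planar receiver-centred frame is adequate below ~6 km, where
  projection error is under a metre.
* **Isolation anchoring.** The 1-h isolation rule is judged against the
  complete transit inventory, not the survivors of other filters — a
  neighbouring vessel contaminates the recording even if its own transit is
  later discarded. This also makes the quality filters commute.
* **Closest-date profiles.** Months without a sound-speed cast use the
  nearest-dated profile (month midpoints); exact ties resolve to the earlier
  date, deterministically.
* **Degenerate crossovers.** If $f^\*$ falls below the band (deep source,
  short range), spherical spreading is used throughout and the case is
  flagged.
* **Exposure duration T** is measured on the *modelled* overhead RL series
  (the measured-series estimator `above_background_duration()` is also
  exported); if even the overhead frame is below background + 15 dB the SEL
  is reported as undefined rather than extrapolated.

## What the synthetic generator emulates — and what it does not

The generator has two tiers, because statistical targets need thousands of
transits while waveform rendering is only needed to exercise the signal
chain:

1. **Summary tier** (`generate_summary_transits()`): draws per-transit SOG,
   SL and SEL either from group moments (for group-comparison statistics) or
   from a linear speed–level law with Gaussian residuals. The packaged group
   specifications (`ship_type_specs()`, `program_group_specs()`,
   `fleet_tier_specs()`) encode the monitored Santa Barbara Channel fleet:
   3778 analysed transits across container ships, bulkers and vehicle
   carriers; a 109-control / 43-rewarded transit-by-transit program; and
   five fleet award tiers in two program phases. The law's residual SD is
   derived from the target $r^2$ as
   $\sigma_e = |b|\,\sigma_{SOG}\sqrt{1/r^2 - 1}$, and its intercept — which
   group summaries alone do not pin down — as
   $a = \overline{SL} - b\,\overline{SOG}$ from the pooled fleet row. SOG
   draws are truncated below 0.5 m/s to avoid degenerate stationary ships.
2. **Waveform tier** (`render_passage_waveform()`): inverts the propagation
   model frame by frame along a straight constant-speed track, synthesising
   each 1-s frame by inverse spectral shaping with independent random phase
   (the analysis chain is PSD-based, so phase continuity across frames is
   deliberately not enforced), plus Gaussian background noise at a flat
   spectrum level. The default source spectrum is flat to 100 Hz with a
   −10 dB/decade roll-off above — the low-frequency, cavitation-dominated
   shape of cargo-ship noise — scaled to the requested broadband level.

Passing tests on this generator demonstrate that the pipeline is
*self-consistent* (it recovers what the model radiates, to within ±1 dB
broadband round-trip) and that the statistical machinery recovers calibrated
group contrasts. They do **not** validate the propagation physics against
sea-truth: real passages carry tonal signatures, directivity, multipath from
bathymetry, and non-Gaussian ambient noise that the generator deliberately
omits.

## Problem sizes

The test suite and the acceptance script use: one 3778-transit law-mode
simulation for slope recovery; 500 replicates of the 152-transit and
555-transit group simulations for the program contrasts; 180-s rendered
passages at 10 kHz (plus a short 200 kHz case to exercise decimation); and
a 1-s-step SEL oracle against the 60-s production step. These sizes give
sampling errors comfortably below the tolerances being checked while keeping
the default run in the tens of seconds.

## Statistical design choices

* **Welch, not pooled, t-test** for the transit-by-transit contrast: the
  groups' spreads differ by nearly a factor of two, making equal-variance
  pooling indefensible.
* **Dunn's post-hoc z-tests** (tie-corrected rank variance) follow the
  omnibus Kruskal–Wallis test. The comparison family is every tier pair
  within a phase plus each tier across phases — the within-tier
  active-vs-inactive contrasts are adjusted inside the same
  Benjamini–Hochberg family, one family per response variable (SOG, SL, SEL
  adjusted separately).
* Significance stars follow p < 0.05 / 0.01 / 0.001 on the adjusted values.

## Known limitations

* No bottom interaction, refraction or full-wave propagation; TL is
  two-ray + spherical only.
* The propeller-diameter defaults are package artifacts; source-depth errors
  propagate directly into $f^\*$ and low-frequency SL.
* Ambient background is a single broadband number per transit; real
  soundscapes vary within a passage.
* Cumulative multi-ship exposure budgets are out of scope; the unit of
  analysis is the isolated transit.
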