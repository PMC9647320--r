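---
title: "Methods: GC-IMS air profiling with airims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC-IMS air profiling with airims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airims)
```

## The measurement and its model

A gas chromatography - ion mobility spectrometry (GC-IMS) measurement of an
air sample produces a two-dimensional intensity field: analytes first elute
from the GC column at a compound-specific *retention time* $r_t$ (seconds),
then their protonated product ions traverse the IMS drift tube in a
compound-specific *drift time* $t_d$ (milliseconds). Intensity (volts) at a
grid cell reflects the abundance of the ion arriving with those two
coordinates. Reactant ions — the charge reservoir that ionises the analytes —
arrive at a fixed drift time at every retention time and form the *reactant
ion peak* (RIP), a ridge across the whole spectrum; on the device modelled
here it sits at 4.889 ms. A single compound may appear several times: at high
concentration, product ions clustering two or three analyte molecules
(dimers, trimers) arrive later in drift time at the same retention time.

Two physical quantities summarise drift behaviour. The drift velocity is
$v_d = L / t_d$ for a drift region of length $L$, and the ion mobility
constant is

$$K = \frac{v_d}{E} = \frac{L}{E\, t_d},$$

for field strength $E$. Because $K$ depends on gas density it is reduced to
standard conditions ($P_0$ = 760 Torr, $T_0$ = 273.15 K):

$$K_0 = K \cdot \frac{P}{P_0} \cdot \frac{T_0}{T}.$$

`drift_velocity()`, `mobility_constant()` and `normalize_mobility()`
implement exactly these ratios; `ion_mobility()` chains them for a
`device_config()`. At standard conditions $K_0 = K$ identically, which the
test suite asserts as a property over random $K$.

For identification the package uses the *RIP-relative drift time*
$t_d / t_{d,\mathrm{RIP}}$ rather than the absolute drift time: slow
instrumental drift moves the whole drift axis, RIP included, so the ratio is
the stable coordinate. The packaged reference library stores drift
coordinates in this relative form (values 1.012-1.333); absolute times are
reconstructed as ratio x 4.889 ms when needed. The device table we follow
lists both a 500 V/cm field and 5 kV across 9.8 cm (which implies about
510 V/cm); the package takes 500 V/cm as authoritative for mobility
computations and keeps the voltage as metadata, enforcing only a 10%
consistency bound between the two.

## The reference library

`default_library()` ships 31 product-ion signals in 20 compound groups
observed in a 16-location air-sampling campaign: 23 entries carry one of 13
distinct compound names (ethanol through 2-hexanone), and 8 are unidentified
("N.I."). Two transcription caveats are preserved deliberately: the
propanoic acid rows carry a CAS number identical to propanal's, flagged
`printed_as_is` rather than corrected; and N.I. rows, which the source table
leaves without a form, are assigned forms by within-group drift order purely
to satisfy the schema — identification never consults them.

A library is usable for matching only if no two entries sit within the
matching tolerances of each other. The full 31-row table violates this at
the default tolerances in two places (an N.I. signal 1 s / 0.006 from the
acetic acid dimer, and another 3 s / 0.002 from the acetone trimer), so
*matching is restricted to the named subset*, which is collision-free at the
defaults. The N.I. rows still participate in simulation and in
group-assignment for profiling, where one-to-one greedy assignment resolves
the ambiguity by distance instead of refusing it.

## Synthetic spectra and campaigns

No raw spectra from the original campaign are public, so the package
includes a generator that reproduces the *statistical structure* the
analysis relies on, and every downstream stage is tested against it.

A simulated spectrum is: a RIP ridge (Gaussian drift profile, constant along
retention) + one separable 2D Gaussian per analyte signal + i.i.d. Gaussian
noise. Defaults, with reasons:

* **Grid**: drift 4-7 ms at 0.001 ms, retention 0-300 s at 1 s, with the
  drift axis anchored so 4.889 ms is a grid point (`default_grid()`).
  Coarser steps (e.g. 0.004 ms / 1-2 s) are used for full-campaign runs;
  coverage never shrinks, only sampling density.
* **Peak widths**: sigma 0.010 ms in drift, 1.0 s in retention. These are
  the package's own choice, made once so that all 31 library signals remain
  distinct local maxima: the two closest pairs of library coordinates are
  then separated by about 3.1 combined sigma, leaving a saddle roughly 40%
  deep. Wider settings (e.g. 0.015 ms / 2 s) merge those pairs — their
  saddle depth falls below noise — and the composite spectrum would only
  ever show 29-30 maxima.
* **Amplitudes and noise**: analyte apexes default to 1 V, the RIP to 5 V
  (it is the dominant feature of a real spectrum), noise SD to 0.005 V.
  Nothing in the pipeline depends on these absolute scales; profiles are
  ratios.
* **Replicate variation**: a campaign (`study_design()`) defaults to 16
  locations (15 indoor + outdoor) x 31 replicates = 496 spectra. The
  amplitude of group $g$ at location $l$, replicate $r$ is
  $A_g \cdot f_{l,g} \cdot m$, with $f$ the designed fold versus outdoor
  (outdoor folds all 1) and $m$ a unit-mean lognormal multiplier with
  coefficient of variation `replicate_cv` (default 0.2; the source analysis
  shows replicate scatter graphically but never quantifies it, so this is a
  free parameter chosen to look like the plotted scatter). The multiplier
  is drawn per (seed, location, replicate, group) from its own deterministic
  stream, so any subset of the campaign is reproducible in isolation;
  all forms of a group share the replicate multiplier.

What the generator deliberately does not model: charge competition (RIP
depletion by analytes), humidity effects, column band broadening, peak
tailing, baseline drift. A green test therefore establishes that the
*pipeline logic* is correct under the stated statistical structure, not that
the detector would perform identically on vendor instrument data.

## Peak detection

`detect_peaks()` replaces the manual peak marking used with vendor software.
A cell is an analyte peak if it is the strict maximum of a neighborhood
(default ±0.02 ms x ±2 s), reaches the intensity threshold, and lies outside
the RIP exclusion band. Numerical choices:

* **Threshold**: 5 x a robust noise scale (MAD of the whole field, which
  off-peak cells dominate), floored at 1 nV so that a noise-free field does
  not admit zero plateaus. At ~10^6 grid cells a 5-sigma threshold still
  lets through an isolated noise maximum in roughly a quarter of spectra;
  replicate consensus (below) is what removes those.
* **Neighborhood**: the retention halfwidth (2 s) must stay below 3 s, the
  closest retention spacing of distinct library signals sharing a drift
  region, and at least one retention grid step, or shoulder rows of a peak
  would re-detect on coarse grids. The drift halfwidth (0.02 ms) stays
  below the 0.029 ms drift gap of the closest library pair.
* **RIP exclusion**: halfwidth 0.04 ms (relative drift below about 1.008),
  keeping the acetone monomer at 1.012 detectable. The apex of the excluded
  band is returned once as the RIP (`is_rip = TRUE`).
* **Ties**: exact plateau ties resolve to the lowest drift time, then
  lowest retention time.

`consensus_peaks()` pools replicate peak lists and clusters them by single
linkage within (0.02 ms, 2 s); each consensus peak carries mean coordinates,
mean intensity over the replicates where it occurred, an occurrence count,
and the full per-replicate intensity series. The pipeline keeps consensus
peaks occurring in more than half the replicates, which suppresses the
isolated noise detections mentioned above.

## Identification

`match_peaks()` cross-checks each detected peak's (retention time, relative
drift time) against the named library within tolerances (defaults 3 s and
0.01, roughly half the smallest inter-entry gaps; the source does not state
its tolerances, so these are configurable). Among admissible entries the
scaled Euclidean distance decides, and assignment is greedy one-to-one by
ascending distance: an entry can be claimed by only one peak. One-to-one
matters in practice — two unidentified signals sit within tolerance of named
entries, and greedy assignment lets the peak that sits *on* an entry claim
it first, leaving the interloper correctly unidentified. Whether the
original analysis matched one-to-one or independently is not stated; this is
a documented package choice.

## Profiles and stability

Per location, mean intensities per (group, form) are compared against the
outdoor baseline: fold $= \bar I_{\mathrm{indoor}} / \bar I_{\mathrm{outdoor}}$.
The displayed score is zero-centred and signed,

$$s(f) = \begin{cases} f - 1 & f \ge 1 \\ -(1/f - 1) & f < 1,\end{cases}$$

so outdoor level plots at 0 and the score is odd under $f \to 1/f$. The
source describes the outdoor level both as "the zero value" and as the unit
of "4 times higher", which no single mapping satisfies; the package adopts
the zero-centred convention for display and reports folds alongside, so
either reading is recoverable, and quantitative checks target folds. Form
scores of a group are summed (monomer + dimer + trimer), matching the stated
aggregation; the group fold is the intensity-weighted ratio of summed means.
Groups undetected at a location report fold 1 / score 0; groups detected
indoors but not outdoors are normalized against a configurable floor
(default 1 mV) and flagged `censored`, since a ratio to zero is undefined.

`stability_report()` computes, per (location, group, form), the replicate
intensity series and its coefficient of variation (sample SD over mean),
ranks locations by median CV (name order breaks ties), and names the most
and least stable sites.

## Known limitations

* Overlapping peaks are not deconvolved; signals closer than about 2
  combined sigma merge into one maximum by construction.
* The detector's false-positive behaviour is controlled by consensus
  occurrence, not by the single-spectrum threshold; single-spectrum runs at
  default noise occasionally report a spurious low-intensity peak.
* The replicate CV, peak widths and absolute amplitudes are package
  choices, not measured values; conclusions that depend on their exact
  magnitudes should be re-checked against instrument data.
* Quantitative concentration calibration is out of scope; profiles are
  relative by design.
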