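---
title: "Models and methods behind pulsefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulsefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsefate)
```

# The scientific setting

A single clinically scaled pulse of cisplatin (2 h at peak plasma
concentration) does not kill a lung-adenocarcinoma culture outright. Most
cells arrest in S/G2, enlarge two- to sixfold, and senesce; a small
sub-population — enriched among cells that were in late G1 or early S phase
at the moment of exposure — keeps proliferating and repopulates the culture
over the following weeks. `pulsefate` packages the quantification machinery
such a study needs: RGB lentiviral clonal-colour analysis, FUCCI-based
single-cell fate classification, 53BP1/PCNA focus quantification, and
control-calibrated size gating, together with a synthetic-data engine that
generates all of these data types with known ground truth so every analysis
stage can be tested at desk scale, with no external data.

Everything random in the package flows from one explicit integer seed
through `derive_seed()`, which hashes a seed plus a stream label into a
child seed; no function touches the global RNG state (scoped seeding via
`withr`). Identical seeds and configurations give byte-identical outputs.

# The cell-cycle model

Cell cycles are phase-structured: G1 → S → G2 → M, with durations drawn
from lognormal distributions with a common coefficient of variation
(`duration_cv`, default 0.15). The FUCCI reporter semantics are: red-only
in G1; red and green together (yellow) during a 2 h overlap window at the
start of S while the G1 reporter decays; green-only through S, G2 and
mitosis; a single colourless frame after anaphase before the daughter's red
signal returns. Mitotic length is the NEBD-to-anaphase interval (default
30 min); division is recorded at anaphase.

Default mean durations are G1 22 h, S 7 h, G2 3 h, M 1 h (33 h cycle).
Under balanced exponential growth, the steady-state age density is
$f(a) = (2\ln 2/T)\,2^{-a/T}$, so the red (G1-only) fraction is
$2\,(1 - 2^{-g_1/T}) \approx 0.74$ with these defaults — inside the
0.70–0.80 band reported for untreated populations of these lines both in
culture and in tumours. This occupancy constraint, not a direct duration
measurement, is what fixes the long default G1: shorter textbook G1
durations put the red fraction near 0.5 and are inconsistent with the
observed colour distribution. The implied occupancy is exposed as
`steady_state_red_fraction()` and checked (with a warning) at parameter
construction.

Arrested cells enlarge at `enlargement_rate` fold per 24 h (default 1.6,
i.e. about threefold 48 h into an arrest), saturating at sixfold — the
upper end of the observed range; unbounded exponential enlargement over a
week of simulated time would be unphysical.

# The fate ontology and its generator

Eight fates cover the observed single-cell outcomes over a 72 h movie:

* `PROLIF` — two or more divisions;
* `SINGLE_DIV` — exactly one division, with the daughter re-entering S/G2;
* `G2_EXIT` — a prolonged S/G2 arrest (green ≥ 20 h) resolving into a
  G1-like red state without mitosis;
* `G1_ABM` / `G1_AAM` — G1 arrest before / after a mitosis;
* `DBM` / `DAM` — death before / after a mitosis;
* `SG2_ARREST` — still green, without exit, at the end of the movie.

`make_fucci_cohort()` realises a `fate_allocation()` — exact counts or
probabilities per fate for a given exposure phase — as intensity tracks
sampled every 30 min over 72 h. Count allocations are honoured exactly and
shuffled deterministically by the seed. The exposure phase fixes the
starting position in the cycle: a G1 (CDK4/6-inhibitor release) exposure
sits 6 h before S entry, matching the release-to-G1/S interval of the
synchronisation protocol; G1/S sits at S entry; late S sits 2 h before S
exit. Proliferative tracks are rejection-sampled so that the promised
number of divisions genuinely lands inside the horizon.

`fig_fate_allocations()` carries the default cohort allocations for the
four synchronised exposure conditions (n = 50 each). The headline counts
are fixed — 7/50 single divisions and no proliferative cells after G1
exposure, 13/50 and 16/50 proliferative after CDK4/6-inhibitor- and
thymidine-synchronised G1/S exposure, 4/50 proliferative after late-S
exposure. The within-remainder splits (e.g. 40 G2-exit / 3 S-G2 arrest for
the G1 cohort) are not individually reported anywhere; the defaults follow
the narrated dominant outcomes (majority G2-exit after G1 exposure; almost
universal single-division-then-arrest after late-S exposure) and are
ordinary arguments, not constants.

Ground-truth per-frame phase labels are defined operationally: the
noiseless intensities are passed through the same threshold-and-hysteresis
rule the phase caller uses. This makes "a noiseless track is recovered
exactly" a designed identity rather than a coincidence, and keeps the
generator and the classifier honest about where the information actually
lives (the intensities, not hidden labels).

## Classification

`call_phase_track()` thresholds the two reporters (default 20 on a
full-signal scale of 100) and merges coloured runs shorter than `min_run`
frames into their flanking phase; colourless (GAP) runs are preserved
because the one-frame post-anaphase gap is a real reporter state.
`classify_fate()` applies a fixed decision order — death, then ≥2
divisions, then single division, then G2-exit, then G1 arrest, then S/G2
arrest — over events inside the closed 72 h horizon. Two points deserve
mention:

* The decision order alone cannot separate `SINGLE_DIV` from `G1_AAM`
  (both have one division). The implemented rule is: one division counts
  as `SINGLE_DIV` only if green frames (S/G2 re-entry) follow it;
  a red-only tail is G1 arrest after mitosis.
* The G2-exit criterion (minimum green run, default 20 h) is exposed as a
  parameter; lowering it can only add G2-exit calls, a monotonicity the
  tests assert.

Division events come from NEBD/anaphase annotations when present (anaphase
must follow NEBD by 15 min–3 h, else the event is flagged and dropped); in
their absence a morphology proxy is used — a ≥40% single-frame nuclear-area
drop coinciding with a green reset.

# The population simulator

`simulate_population()` advances a population at the frame cadence.
Untreated cells simply cycle and divide. Under `treatment = "pulse"` each
cell is assigned a fate at time zero from a per-phase probability map
(`default_phase_fate_map()`), after which proliferative lineages keep
cycling — slowed by `treated_slowdown` (default 1.8×, reflecting lengthened
interphases after damage) — while the other fates follow analytic
piecewise timelines (arrest, G2-exit into red, division then death, and so
on). With functional p53, green-arrested cells convert to a red G1-like
state after roughly the G2-exit arrest time (sustained arrest twice that
for cells labelled `SG2_ARREST` in the 72 h ontology — the label means the
exit was not seen within a movie, not that it never happens). Dead cells
leave the population. The proliferative probabilities in the default map
are taken from the synchronised-cohort fractions (0 for G1, 0.26/0.32 for
G1/S and early S, 0.08 for late S); with these defaults the simulated
culture shows the characteristic early S/G2 (green) accumulation followed
by a collapse into >90% red by day 7 — for the p53-wild-type
parameterisation — while the p53-null map keeps more cells cycling
aberrantly.

Default problem sizes (2 000 starting cells, 5–7 simulated days, three
seeds for reported fractions) keep a full calibration run under a minute
while leaving binomial noise on a 2 000-cell fraction near 1%.

# Clonal colour analysis

The analysis chain mirrors the classic RGB (LeGO-style) marking workflow:

1. **Background subtraction** (`subtract_background()`): greyscale opening
   with a paraboloid-of-revolution structuring element ("rolling ball",
   default radius 250 px). The paraboloid's additive separability makes
   the 2-D opening exact as two passes of 1-D erosions/dilations; its
   depth is tied to the channel's dynamic range so that features narrower
   than the radius are excluded from the background while gradients at
   scale ≥ radius survive. A flat-disc opening fallback agrees within a
   few percent on smooth scenes (asserted in tests).
2. **Smoothing** (`smooth_mean()`): disc mean filter, radius 5, with
   edge-clipped normalisation so constant images are unchanged everywhere.
3. **Cell detection** (`detect_cells()`): regional maxima of the channel
   sum with prominence above `noise_tolerance`, via an h-maxima transform
   (geodesic reconstruction of image-minus-tolerance under the image);
   each prominent maximum contributes one plateau centroid.
4. **ROI sampling** (`sample_roi_rgb()`): circular ROIs of radius 5 px
   applied to the *raw* image; means over the clipped disc at borders.
5. **Extreme-value filtering** (`filter_rgb_extremes()`): a record is
   dropped iff any channel leaves its per-channel 1%–99% quantile band
   (absolute bounds available); every rejection is logged with a reason.
   Clone fractions are computed after this filter.
6. **Quantisation** (`quantise_colours()`): 8 equal bins per channel over
   the fixed 16-bit range, 512 classes, class = 64·binR + 8·binG + binB.
   Fixed-range binning (rather than per-dataset min–max) keeps class
   identities comparable across images and runs.
7. **Top-64 reduction and clone calling** (`top_k_reduction()`,
   `call_clones()`): the 64 most frequent classes (ties broken by
   ascending class index) are analysed; a clone is positive iff it holds
   strictly more than 0.1% of *all* detected cells, UNASSIGNED included.
8. **Diversity** (`clone_diversity()`): richness, Shannon index and Pielou
   evenness over positive clones.

The default colour-mixing model (`lenti_mix_model()`) gives every founder
Poisson per-channel vector copies (mean 1.5) with lognormal
per-integration expression; founders are resampled if colourless, and — by
default — until their colour codes occupy distinct quantisation classes.
With 64 equally weighted founders this emulates the empirical detection
ceiling of the assay (up to 64 distinguishable colours in the reduced set)
and yields, on a 10 000-cell control, exactly 64 positive clones with
full top-64 coverage. These defaults were fixed from the assay's reported
behaviour before the acceptance checks were run, and they are ordinary
arguments: more founders than distinguishable classes, skewed clone sizes
and collision-prone colour draws are all available by configuration.

# Focus analysis

Foci are detected on 2-D maximum-intensity projections
(`max_project()`), inside nucleus masks from `segment_nuclei()` (Otsu or
absolute threshold, 20 µm² minimum area). The focus threshold is robust
and per-nucleus: median + 3·MAD of in-mask intensity. Because median and
MAD are affine-equivariant, rescaling intensities by any positive constant
leaves counts unchanged — asserted as a property test. Components above
threshold with area ≥ 0.08 µm² (about 2 px at 0.2 µm/px, excluding
sub-resolution specks) are reported with centroids, areas in µm² and mean
intensities. `foci_classes()` bins per-cell counts at the <5 / 5–15 / >15
boundaries (strict outer bounds, inclusive middle).

PCNA S-phase sub-staging (`classify_s_stage()`) follows the standard
pattern convention — many small dispersed interior foci in early S, a
perinucleolar ring in mid S, few large peripheral clusters in late S —
operationalised as thresholds on focus count, mean area, and the median
and spread of radial positions (in units of the equivalent nucleus
radius). The exact cutoffs are this package's contract, matched to its own
pattern generator (`make_pcna_pattern()`) and verified by
rendering-and-recovery tests; on real data they are starting points, not
measurements.

The kinetics generator (`make_foci_series()`) encodes the three observed
regimes: controls stay below 20 replication-associated foci and show a few
large (≤5 µm²) G1 nuclear bodies; G1-exposed cells burst to ~100 foci on S
entry and arrest without dividing, the burst resolving slowly as focus
size grows; early-S-exposed lineages burst during the first replication
and resolve across generations, their G1 bodies growing from daughter to
grand-daughter — the footprint of damage being corralled into nuclear
bodies for repair in later cycles. The ~100 and <20 scales are declared
generator targets (`s_burst_count`, `baseline_count`), verified by
averaging peak counts over seeds.

Rendered focus frames place Gaussian spots on a bright nuclear disc; the
spot width is calibrated so that the above-threshold footprint under the
default detection settings matches the nominal focus area (a 5 µm² focus
is measured within ±15%).

# Morphometrics

`measure_areas()` converts label masks to areas (pixel count × pixel
size²). `gate_stable_enlarged()` reproduces the control-calibrated gating
logic of a size sort: the threshold is a quantile (default 0.975) of the
*untreated control* areas only, so adding treated cells never moves the
gate; treated cells above it are ENLARGED. The 0.975 default mirrors a
conventional two-parameter control gate in the absence of any reported
instrument settings; this package gates on imaged nuclear area rather than
flow scatter, and does not model doublet exclusion. `fold_change()`
reports the ratio of means with a seeded bootstrap interval; on synthetic
cohorts the arrested cells at 72 h are ≥2-fold enlarged over cycling
controls, and the default gate recovers ≥95% of truth-arrested cells.

# What the synthetic data do and do not show

The generators emulate the *structure* of the real data — heritable colour
codes, phase-dependent fate mixtures, FUCCI trace shapes, focus-count
regimes, arrest-linked enlargement — with simple noise models (Gaussian
intensity noise, lognormal durations, Poisson counts). They do not emulate
segmentation errors, tracking failures, photobleaching, drift,
out-of-focus light, colour bleed-through between channels, or in vivo
imaging artefacts. Green-fluorescence tests passing here therefore
demonstrate that the analysis logic is correct and self-consistent, not
that it is robust to every imaging pathology; parameters exposed on each
function are the intended adjustment points for real data. RNA-seq,
immunohistochemistry, flow-cytometry file parsing and in vivo quantities
are out of scope.

# Numerical choices and degenerate inputs

* Tolerances: colour fractions sum to 1 within 1e-9; probability
  allocations are validated at 1e-9; the reconstruction in `detect_cells()`
  iterates geodesic dilation to a 1e-9 fixed point.
* Tie-breaks: top-k ranking and clone ordering break count ties by
  ascending colour-class index; the classifier's decision order makes fate
  ties impossible by construction.
* Degenerate inputs error early and descriptively: colourless mixing
  models, fate counts not summing to the cohort size, empty nucleus masks,
  all-records-rejected filters, out-of-range synchronisation offsets.
  Empty *data* (an empty population to render, an empty point list to
  sample, an empty labelling to measure) flows through as empty tables,
  not errors.
* Events exactly at the 72 h horizon are included (closed interval).
* The imaging cadence is stated ambiguously in live-cell protocols
  (10–20 min vs 30 min); the default is 30 min, configurable via
  `frame_interval_minutes`.

# A worked desk-scale run

```{r example, eval = FALSE}
library(pulsefate)

# clones: simulate a marked control population and call clones
model <- lenti_mix_model(seed = 1)
pop <- make_lenti_population(model, 10000)
rec <- data.frame(cell_id = pop$cell_id, mean_r = pop$r,
                  mean_g = pop$g, mean_b = pop$b)
clones <- call_clones(top_k_reduction(quantise_colours(rec), 64))
attr(clones, "n_positive") # 64
clone_diversity(clones)$shannon

# fates: classify the G1-exposure cohort
co <- make_fucci_cohort(fig_fate_allocations()$cis_G1, seed = 1)
calls <- lapply(co, classify_fate)
aggregate_cohort(calls, "cis at G1")$fate_table

# population: colour dynamics after a pulse
sim <- simulate_population(treatment = "pulse", n0 = 2000,
                           duration_days = 7, seed = 1)
tail(sim[, c("time_h", "frac_red", "frac_yellow", "frac_green")], 1)
```
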