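# pulsefate

Quantification toolkit for single-cell studies of cell cycle-dependent
responses to pulsed platinum chemotherapy in lung adenocarcinoma cultures.

After a single clinically scaled cisplatin pulse (2 h at peak plasma
concentration), most cells arrest in S/G2, enlarge two- to sixfold and
senesce, while a small sub-population — enriched among cells that were in
late G1/early S phase at exposure — keeps dividing and repopulates the
culture. `pulsefate` implements the measurement machinery such experiments
rely on, for imaging scientists and computational biologists analysing
time-lapse FUCCI movies, RGB clonal-marking images and DNA-damage focus
data:

* **Clonal colour analysis** (RGB/LeGO-style marking): rolling-ball
  (sliding-paraboloid) background subtraction, disc mean filtering,
  prominence-based cell detection, circular-ROI sampling of raw images,
  per-channel extreme-value filtering, fixed-range quantisation into
  8×8×8 = 512 colour classes (class = 64·binR + 8·binG + binB), reduction
  to the 64 most represented colours, positive-clone calling at the strict
  >0.1% population threshold, and diversity summaries (richness, Shannon
  H′ = −Σ pᵢ ln pᵢ, Pielou evenness).
* **Single-cell fate tracking** (FUCCI): phase calling (red = G1,
  red+green = G1/S, green = S/G2/M, with hysteresis), NEBD/anaphase
  division events (mitotic length = NEBD→anaphase), and an eight-label
  fate ontology — proliferative (≥2 divisions), single division, G2-exit
  (green ≥ 20 h resolving to red without mitosis), G1 arrest before/after
  mitosis, death before/after mitosis, S/G2 arrest — with cohort
  aggregation and phase-fraction time series.
* **Focus analysis** (53BP1/PCNA): maximum-intensity projection, nucleus
  segmentation, per-nucleus median + 3·MAD thresholding (scale-invariant),
  areas in µm², <5 / 5–15 / >15 foci-per-cell classes, PCNA-pattern
  S-phase sub-staging (early/mid/late), and per-generation lineage
  summaries.
* **Morphometrics**: nuclear-area measurement and stable/enlarged gating
  calibrated on untreated controls (threshold = control area quantile,
  default 0.975), with bootstrap fold-change intervals.
* **Synthetic-data engine**: a lentiviral three-vector colour-mixing model
  (Poisson integrations × lognormal expression), a phase-structured FUCCI
  track generator realising exact fate allocations over 72 h at 30-min
  cadence, a population simulator whose untreated steady state puts
  2(1 − 2^(−g1/T)) ≈ 74% of cells in G1 (red), and a focus-kinetics
  generator (~100-focus S-phase bursts after G1 exposure, <20-focus
  controls, G1 nuclear bodies up to 5 µm²). Every generator is
  deterministic given a seed and emits ground truth, so each analysis
  stage is testable without any external data.

## Worked example

```r
library(pulsefate)

# --- clones: a 10,000-cell synthetic untreated control -------------------
model <- lenti_mix_model(seed = 1)          # 64 founders, distinct codes
pop <- make_lenti_population(model, 10000)
rec <- data.frame(cell_id = pop$cell_id, mean_r = pop$r,
                  mean_g = pop$g, mean_b = pop$b)
red <- top_k_reduction(quantise_colours(rec), 64)
clones <- call_clones(red)
attr(clones, "n_positive")                  # 64
attr(red, "coverage")                       # 1
clone_diversity(clones)$shannon             # 4.156 (ln 64 = 4.159)
head(clones, 3)
#>   reduced_class colour_class count fraction is_positive_clone
#> 1             0            2   181   0.0181              TRUE
#> 2             1          139   176   0.0176              TRUE
#> 3             2            1   174   0.0174              TRUE

# --- fates: the G1-exposure cohort (n = 50) ------------------------------
co <- make_fucci_cohort(fig_fate_allocations()$cis_G1, seed = 1)
calls <- lapply(co, classify_fate)
ft <- aggregate_cohort(calls, "cis at G1")$fate_table
ft[ft$count > 0, ]
#>   condition       fate count fraction
#> 2 cis at G1 SINGLE_DIV     7     0.14
#> 3 cis at G1    G2_EXIT    40     0.80
#> 8 cis at G1 SG2_ARREST     3     0.06

# --- population: FUCCI colour dynamics over 7 days post pulse ------------
sim <- simulate_population(treatment = "pulse", n0 = 2000,
                           duration_days = 7, seed = 1)
tail(sim[, c("time_h", "frac_red", "frac_yellow", "frac_green")], 1)
#>     time_h frac_red frac_yellow frac_green
#> 337    168   0.9146      0.0283      0.057
```

Reading the numbers: the calibrated control resolves exactly 64 positive
clonal colours with the whole population inside the top-64 set, and clone
sizes are near-even (H′ ≈ ln 64). Of 50 cells pulsed in G1, 7 complete a
single division, none proliferate, and the rest undergo a prolonged S/G2
arrest ending (mostly) in G2-exit. At the population level the pulse
first drives an S/G2 (green) accumulation, which collapses into >90%
G1-like red cells by day 7 under the p53-wild-type parameterisation.

The methods vignette (`vignettes/pulsefate-methods.Rmd`) documents the
models, defaults and design decisions in detail.

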