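# musctrack

Quantitative analysis of time-lapse muscle stem cell (MuSC / satellite
cell) behaviour on myofibres: rigid drift correction of cell tracks,
migration statistics with mobile/static stratification, lineage
reconstruction with division-mode and orientation classification, fate
indexes, and sister co-migration — plus a synthetic-scene generator with
calibrated wild-type and dystrophic (*mdx*) presets that provides ground
truth for every pipeline stage.

## The analysis in brief

Fibres drift and rotate during imaging, so raw tracks mix cell and
substrate motion. Per-frame rigid transforms are estimated from landmark
series (least-squares Kabsch fit) or segmented-fibre masks (image-moment
alignment), chained frame-to-previous and accumulated
(C_t = C_{t-1} ∘ T_t), and applied to every track point, expressing motion
relative to the immobilised fibre.

For a corrected segment with step distances d_i, the pipeline reports the
total distance Σd_i, net distance D, straightness D/Σd_i ∈ [0,1], average
speed Σd_i/duration (μm/h), and turning angles α_i ∈ [0°,180°] between
consecutive displacements. Cells are stratified into **mobile** and
**static** at a migration-speed threshold (default 0.41 μm/min; or derived
as the median of pooled log step speeds of a reference group) because the
static fraction otherwise dominates population averages.

Divisions are classified from the daughters' MYOG status — SCDp (both
negative), SCDd (both positive), ACD (one of each) — and oriented planar or
perpendicular from fibre contact at mitosis. The differentiation index is
the MYOG-positive fraction of surviving cells; the proliferation index a
cell-count ratio N(t_end)/N(t_ref). Sister co-migration asks, per division,
whether the vectors from the mitosis site to each daughter 30–60 min later
point the same way (positive dot product).

## Worked example

Simulate a wild-type lineage movie, correct it, and analyse fates:

```r
library(musctrack)

scene <- simulate_lineages(muscle_preset("wt"), n_founders = 100, seed = 1)
reg   <- register_landmarks(scene$landmarks)
ts    <- correct_tracks(scene$tracks_observed, reg$correction)

division_mode_fractions(division_records(ts, fate_mode = "endpoint"))
#> # A tibble: 3 x 3
#>   mode      n fraction
#> 1 ACD      83    0.160
#> 2 SCDd    150    0.289
#> 3 SCDp    286    0.551

differentiation_index(ts)$index        # 0.38
proliferation_index(ts)$index          # 4.12
mean_cycle_durations(cell_cycle_durations(ts))[, c("generation_group", "n", "mean_h")]
#>   generation_group   n mean_h
#> 1 >=2              241   8.6
#> 2 1                100  48.1
```

The wild-type preset is calibrated so the pipeline recovers a first
division around 47.3 h, later cycles around 8.5 h, mostly symmetric
proliferative divisions and a differentiation index near 0.38; the `mdx`
preset gives a SCDd-dominated mode spectrum, slower later cycles, a lower
mobile fraction (≈0.19 vs ≈0.52) and a higher differentiation index
(≈0.76). The numbered drivers under `analysis/` run the whole workflow
(simulate → register → motility → lineage → group report) and write tidy
tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`run_pipeline(pipeline_config(...))` does the same end-to-end for a single
scene or an imported track bundle (TrackMate-dialect XML or the tracks CSV
format), writing metrics, divisions, indexes and co-migration tables plus a
YAML manifest that records the seed, threshold provenance and every
dropped/flagged entity.

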