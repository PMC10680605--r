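# sepaldyn

Quantitative morphodynamics of growing plant organs from cell-resolution
time-lapse data, with a synthetic growing-tissue simulator so the whole
analysis runs without microscopy data.

Developing sepals reach remarkably reproducible sizes and shapes even
though the growth of their individual epidermal cells is strongly
heterogeneous. The key to this robustness is *spatiotemporal averaging*:
when cell-level growth fluctuations are spatially fine-grained and
resampled over time they cancel out of cumulative organ growth, whereas
spatially coarse, temporally persistent fluctuations accumulate into
patchy, variable organs. `sepaldyn` provides the full quantitative toolkit
used to study this process on segmented, lineage-tracked tissue time
series, for researchers analysing live-imaged epidermis (MorphoGraphX-style
`Label,Value` heat-map and `Label,Parent` lineage CSVs) or studying the
averaging mechanism itself.

## What it computes

* **Lineage algebra** — composition of per-interval parent maps into
  multi-day maps (`compose_parent_maps()`), daughter counts per lineage
  (`daughter_counts()`), non-divider counts, shrunken-cell flags and
  division outlines.
* **Growth quantification** — per-lineage areal growth ratios G =
  (descendant area) / (ancestor area) over any span (`growth_map()`), and
  per-lineage deformation tensors from matched wall junctions
  (`fit_deformation()`): least-squares F in `p_late ≈ F p_early + t`,
  principal stretches s₁ ≥ s₂ from C = FᵀF, principal direction of growth
  θ_max, anisotropy s₁/s₂.
* **Growth direction vs organ axis** — graph distance fields from tip
  cells (`cell_distance_field()`), smoothed proximal–distal axis fields
  (`axis_from_distance()`), and the PD/ML growth ratio
  √(aᵀCa)/√(a⊥ᵀCa⊥) (`pd_growth_ratio()`, `pd_ratio_map()`).
* **Shape robustness** — contour tracing from binary masks,
  size-and-pose normalisation, aligned mean shapes, the shape-variability
  statistic S₂ (mean squared deviation from the aligned mean of unit-area
  contours) and within-flower SDs of sepal area.
* **Statistics** — exact 1-d Wasserstein distances between growth or
  area distributions, PCoA of the distance matrix, tie-corrected Kendall
  τ_b, and one-way ANOVA with Tukey HSD compact letter groups.
* **Simulator** — `simulate_series()` generates six 24-h snapshots of a
  jittered polygonal tissue with a basipetal band of fast growth,
  log-normal growth noise of controllable spatial correlation length and
  AR(1) temporal persistence (resampled = wild-type-like, persistent =
  *ftsh4*-like), threshold divisions modulated by a rate factor κ
  (LGO-dosage-like), and never-dividing giant cells.

## Worked example

```r
library(sepaldyn)

ser <- simulate_series(sim_config(seed = 1))
ser
#> <tissue_series> 6 snapshots at t = { 0, 24, 48, 72, 96, 120 } h; cells: 120 -> 132 -> 155 -> 202 -> 250 -> 312

counts <- daughter_counts(compose_parent_maps(ser$intervals))
mean(counts$value)          # daughters per lineage over 120 h
#> [1] 2.6
count_nondividing(counts)   # cells that never divided (incl. giants)
#> [1] 73

# cumulative growth and principal directions over 24-96 h
tens <- growth_tensors(ser, 24, 96)
dplyr::summarise(tens, mean_anisotropy = mean(anisotropy))
#> # A tibble: 1 × 1
#>   mean_anisotropy
#>             <dbl>
#> 1            1.97

# wild-type-like vs ftsh4-like cumulative growth heterogeneity,
# paired seeds
rats <- sapply(1:5, function(s) {
  wt <- growth_heterogeneity_sd(simulate_series(sim_config(seed = s)))
  ft <- growth_heterogeneity_sd(simulate_series(
          sim_config(seed = s, persistence = 0.95, corr_len = 4)))
  ft / wt
})
round(rats, 2)
#> [1] 1.14 2.07 2.28 3.11 2.26
median(rats)
#> [1] 2.263745
```

That is the averaging result in miniature: with the same seeds,
persistent coarse-grained noise typically leaves more than twice the
cumulative growth heterogeneity at fixed band position than resampled
fine-grained noise does.

`run_pipeline(sim_config(seed = 1), "out/")` chains every stage
(simulate → track → growth → axis → stats) and writes each result as CSV
plus optional PNG heat-map renders with the standard display ranges
(`render_spec()`).

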