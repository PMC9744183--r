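# spatspike

Cell-type classification from the spatiotemporal structure of extracellular
spikes.

Extracellular recordings with multi-site silicon probes sample every spike at
several spatial locations at once. Pyramidal cells (PYR) and
parvalbumin-immunoreactive (PV) interneurons have long been separated by
single-channel waveform width or by firing statistics; `spatspike` asks a
sharper question: does the *purely spatial* distribution of the spike across
channels carry class information of its own? The package is written for
electrophysiologists who have sorted, labeled units (e.g. from optogenetic
tagging) and want a tested, reproducible pipeline from raw multichannel spike
snippets to cross-validated cell-type classifiers — and for methodologists who
want to probe the spatial-information question on synthetic ground truth.

## What it computes

For every unit (n_spikes × n_channels × 32 samples at 20 kHz) the package
extracts 34 features in three modalities:

* **Waveform (8)** — from the scaled, eightfold Fourier-interpolated mean
  waveform of the main channel (the channel with the largest trough-to-peak
  magnitude): trough-to-peak (TTP) duration and magnitude, FWHM, rise
  coefficient, maximum speed, and three second-derivative window sums
  (break measure, smile-cry, acceleration).
* **Spike timing (8)** — from the ±1 s autocorrelation histogram (0.5 ms bins,
  symmetrized, eightfold polyphase-upsampled): uniform-distance, D_KL and rise
  time on the 0–50 ms window; jump index and D_KL on 50–1000 ms; PSD centroid
  and PSD-derivative centroid; firing rate.
* **Spatial (18)** — after an event-based **δ-transformation** that strips all
  single-channel waveform information. Three events are detected per channel —
  first median crossing (FMC), maximal negativity (NEG), second median
  crossing (SMC) — and each channel is replaced by a single impulse at its
  event time, scaled by the global minimum and shifted so the main channel's
  event sits at the 129th sample. From the 3 × 8 event points come time-based
  features (mean squared offset, offset SD per event), graph-based features
  (average edge weight and heaviest/lightest path through the "transmission
  speed" event graph, in mm/s), and value-based spatial-dispersion (SPD)
  features.

Classification uses stratified, unit-disjoint 80:20 partitions, a five-fold
grid search over random-forest hyperparameters, inverse-frequency class
weights, and the unit-level ROC AUC. **Chunking** augments the data: a unit's
spikes are split at random into ⌊N/C⌋ chunks (C ∈ {25, …, 1600}), features are
extracted per chunk, five chunk statistics (mean, SD, quartiles) expand the
feature count sixfold, and test predictions are pooled per unit by majority
vote. Shuffled-training-label runs provide the empirical chance baseline;
TreeSHAP attributions with a permutation null rank the features; and a
cross-region analysis quantifies generalization error between hippocampal CA1
and neocortex as (AUC_train-region − AUC_other-region) / AUC_train-region.

A synthetic-population generator produces ground-truth-labeled PYR-like and
PV-like units whose waveform widths, firing statistics, and per-channel
event-time dispersions emulate the recorded medians, so every stage of the
pipeline is testable without any data download.

## Worked example

```r
library(spatspike)

geometry <- linear_probe_geometry()          # 8 sites, 20 um pitch
pop <- generate_population(population_spec(n_pyr = 40, n_pv = 10,
                                           duration_s = 120, seed = 42))
tab <- feature_table(pop, geometry, modalities = "spatial")
chunked <- chunk_feature_table(pop, C = 25, geometry,
                               modalities = "spatial", seed = 42)

aggregate(tab[, c("fmc_time_lag_sd", "neg_time_lag_sd")],
          list(label = tab$label), median)
#>   label fmc_time_lag_sd neg_time_lag_sd
#> 1    PV            39.6            7.72
#> 2   PYR            17.1           11.59

ex <- run_experiment(tab, chunked, n_partitions = 20, seed = 42)
ex
#> <experiment_result: 20 partitions, unit AUC median [IQR] 1.000 [1.000-1.000]>

aw <- a_w(tab$fmc_time_lag_sd[tab$label == "PV"],
          tab$fmc_time_lag_sd[tab$label == "PYR"])
sprintf("FMC time-lag-SD effect size A_w = %.2f (p = %.2g)", aw$a_w, aw$p_value)
#> "FMC time-lag-SD effect size A_w = 1.00 (p = 1.3e-06)"
```

The median FMC offset SD is smaller for PYR than for PV units (PYR spikes are
spatially more synchronous at the start of the spike) while the NEG ordering
reverses, and a forest trained only on these purely spatial features —
with 25-spike chunking and vote pooling — separates the classes essentially
perfectly on this synthetic population.

Reading recorded data instead of synthesizing it:

```r
units <- read_neurosuite("session.spk.1", "session.res.1", "session.clu.1",
                         n_channels = 8)        # labels assigned separately
units <- read_units("dataset.txt", geometry)    # native container
write_feature_table(tab, "features.csv")
```

## Limitations

The synthetic generator is a phenomenological emulator, not a biophysical
model: it reproduces the class contrasts the features measure (widths, rates,
burstiness, event-time dispersions, intraunit drift) but not spike collisions,
electrode drift, or realistic background activity. Performance numbers on
synthetic populations therefore validate the pipeline's mechanics and
orderings, not expected accuracy on any particular recording. See the methods
vignette (`vignettes/spatspike-methods.Rmd`) for the full model description
and design rationale.
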