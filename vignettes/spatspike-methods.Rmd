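---
title: "Methods: spatial cell-type classification from extracellular spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial cell-type classification from extracellular spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatspike)
```

This vignette documents the models and procedures implemented in `spatspike`,
the assumptions behind them, the numerical choices that matter, and the design
decisions that were genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The problem

Multi-site extracellular probes record every spike of a sorted unit on several
channels simultaneously. Pyramidal cells (PYR) and parvalbumin-immunoreactive
(PV) interneurons differ in morphology, connectivity, and ion-channel
distributions, and those differences could in principle leave a signature in
the *spatial* distribution of the extracellular potential — independent of the
single-channel waveform shape and of firing statistics. Testing that claim
requires (a) feature sets that provably isolate each information source, and
(b) a classifier harness whose baseline behavior is verifiable. `spatspike`
implements both, plus a synthetic ground-truth generator so the entire chain
is testable without recordings.

## Waveform preprocessing

Raw snippets are 32 samples per channel at 20 kHz (1.6 ms). Per channel, the
mean over the selected spikes is interpolated eightfold in the frequency
domain (zero-padding the spectrum, Nyquist bin split), giving 256 samples at
6.25 µs. Both steps are linear, so their order is irrelevant; the test suite
checks commutation to 1e-9. The *main channel* is the one with the largest
trough-to-peak (max − min) magnitude, ties to the lowest index (the tie rule
is an implementation decision; exact ties essentially never occur on real
data). If the main channel's maximal positivity exceeds its maximal
negativity in absolute value, the whole multichannel waveform is inverted —
the decision is made once, on the main channel, and applied jointly so
inter-channel sign relations survive. All channels are then divided by the
absolute main-channel minimum, mapping the main channel into [−1, 1] with the
trough at exactly −1.

### The eight waveform features

All are computed from the scaled main channel; sample spacing dt = 6.25 µs.
Derivatives are adjacent-sample differences (the second derivative is the
twice-applied difference, no smoothing), matching the convention that the
feature definitions assume.

* **TTP duration / magnitude** — trough to the *ensuing* maximal positivity.
  If no positive sample follows the trough, the post-trough global maximum is
  used regardless of sign (documented degenerate case). Magnitude is measured
  after scaling, which is what puts it on the 1.3–1.5 AU scale.
* **FWHM** — width of the contiguous interval around the trough where the
  value is ≤ −0.5. The "at most −0.5" reading was chosen because −0.5 is half
  the trough depth and the sub-threshold duration is the one on the 0.15–0.25
  ms scale that typical narrow and broad spikes produce.
* **Rise coefficient** — a line connects the trough to the last sample; the
  feature is the time from the trough to the point of maximal absolute
  deviation from that line.
* **Maximum speed** — length of the longest contiguous post-trough stretch on
  which the first derivative stays within 5% (configurable `speed_tol`) of its
  post-trough maximum. "Maintains the same change rate" admits several
  readings; a tolerance band around the peak derivative is the one we fixed,
  and the tolerance is exposed rather than hidden.
* **Break measure / smile-cry / acceleration** — second-derivative window
  sums: 0.3–0.08 ms before the trough, 0.26–0.76 ms after, and (squared)
  0.08–0.25 ms after, reported in 1e-1, 1e-2, and 1e-6 AU. Window boundaries
  snap to the 6.25 µs grid toward the trough and are closed on the side
  nearer the trough, half-open on the far side; the d²-sample at index *i* is
  aligned with waveform sample *i + 1*.

Scale invariance (any positive multiple, and inversion, leave all eight
features unchanged) is a tested property.

## Spike-timing features

The autocorrelation histogram (ACH) counts all spike-pair lags up to ±1000 ms
in 0.5 ms bins, excluding zero-lag self-pairs. Because for the full pairwise
histogram the negative side mirrors the positive side exactly, homolog
averaging equals the single-sided pairwise count; for chunk ACHs (built by
summing single-spike ACHs, each the two-sided lag histogram around one
reference spike) the two sides differ and are averaged explicitly. The
single-sided histogram is upsampled eightfold by polyphase filtering
(`signal::resample`), to 16 000 bins of 62.5 µs. Polyphase filtering can
produce small negative values; they are clamped to zero before any
normalization.

High-frequency features use the 0–50 ms window normalized to a PDF;
low-frequency features the 50–1000 ms window; both report the mean absolute
CDF distance to uniform and the Kullback–Leibler divergence to uniform
(nats, 0·log 0 = 0; per-window normalization — the whole-ACH alternative is a
different, unstated convention). *Rise time* is the time at which the window
CDF first exceeds 1/e: an exactly uniform window then yields 50/e ≈ 18.4 ms,
which is the anchor that fixed this reading over "duration above 1/e"
(≈ 31.6 ms for the same input). PSD features use the squared FFT of the full
upsampled histogram on a 1 Hz grid; the DC bin is excluded from the centroid
(it otherwise dominates and collapses all centroids toward 0), and the
derivative centroid uses the absolute adjacent-difference of the PSD (a
signed derivative integrates to ≈ 0 and makes the centroid ill-posed). The
firing rate is spike count over train span; in chunk mode it is the mean over
the chunk's spikes of the per-spike rate, itself the mean of the inverse
pre- and post-ISIs (boundary spikes use their single ISI).

## The δ-transformation and spatial features

To isolate spatial information, each channel of the mean waveform is reduced
to three *events*: NEG, the sample of maximal negativity; FMC and SMC, the
nearest samples before/after NEG lying strictly above the *global median*
(the median over all channels × all 256 samples — the only reading that
yields one crossing level for every channel). A channel that never recrosses
the median has the event set to the window edge and is flagged; flagged
channels are excluded from time- and graph-based features for that event.
Each channel is then replaced by a single impulse at its event time carrying
the channel's maximal negativity divided by the absolute global minimum, and
all channels are shifted together so the main channel's event lands on the
129th sample. That centralization removes the event-timing information a
single channel could still carry; residual variability can remain when the
max-TTP channel is not the max-negativity channel, and no correction is
applied for it. On units where the two channels coincide, the transformed
main channel is *identical* across units, so a classifier fed waveform
features of transformed spikes must sit at AUC 0.5 — the package's central
negative control, exercised by the test suite and the acceptance script.

Channels whose trough-to-peak magnitude is below 25% of the maximum over
channels are masked out of the time/graph features (≥ comparison, tie kept;
the main channel always passes). The 18 spatial features are:

* **Time-based (per event)**: offsets of unmasked non-main channels relative
  to the main channel, in µs; mean squared offset (reported in 10³ µs²) and
  the *population* SD of the offsets. The main channel's own offset is
  identically zero and is excluded; population rather than sample SD is used
  (both choices configurable in principle, one is fixed and documented).
* **Graph-based (per event)**: a complete DAG over distinct event times;
  edge weight = electrode distance (mm) / time difference (s), i.e. a
  transmission speed in mm/s. Features: mean edge weight, and the heaviest
  and lightest path sums. Path termini are constrained to earliest-event →
  latest-event nodes: with positive weights an unconstrained lightest "path"
  degenerates to the single lightest edge, which is retained behind
  `constrained = FALSE` but is not the default. The dynamic program is tested
  against exhaustive path enumeration on all DAGs up to 6 nodes.
* **Value-based (SPD)**: all channels, no mask; per-channel |maximal
  negativity| scaled by the global maximum gives v ∈ [0, 1]; the features are
  the count of v ≥ 0.5, the population SD of v, and the area under the
  count-versus-threshold curve, which equals Σv exactly (tested as an
  identity).

Degenerate cases (fewer than two usable channels, all events simultaneous)
propagate as missing values; the model pipeline imputes them with
training-set medians, because the forest implementation rejects missing
cells.

## Chunking

A unit with N spikes and chunk size C is split at random into ⌊N/C⌋ chunks
with sizes in [C, 2C − 1], equal up to one spike; units with N < C contribute
a single chunk of N spikes rather than being dropped, which keeps label
balance stable. Chunk waveforms are within-chunk means; chunk ACHs are sums
of single-spike ACHs. For every base feature, the mean, SD, and 25/50/75%
quantiles across the unit's chunks are appended ("chunk statistics"),
expanding the feature count sixfold; they are identical for all chunks of a
unit, and they are computed for the no-chunking table too (from its single
chunk, SD = 0) so chunked and unchunked tables share one layout. Feature
extraction is nonlinear, so the mean-over-chunks of a feature is not the
no-chunking feature — a property the tests demonstrate by construction. At
test time every chunk is scored independently and same-unit votes are pooled:
majority label with ties toward PV, and the PV-vote fraction as the unit's
continuous score for ROC analysis (the vote-fraction score is this package's
choice; the summary statistic a binary-vote AUC should use is not otherwise
pinned down).

## Classification procedure

Each experiment repeats over (by default) 50 stratified unit-level 80:20
partitions: per class, ⌊0.8 n⌋ units train, the rest test, so 411 PYR + 101
PV units always split 328/80 and 83/21. Chunks never straddle the split.
Class weights are total/(n_classes × class count). Hyperparameters come from
a five-fold grid search on the training units maximizing mean held-out AUC,
ties to the first grid member in declaration order; chunked runs reuse the
hyperparameters of the no-chunking search on the same partition. The four
grid dimensions are the forest size, tree depth, minimum samples to split,
and minimum samples per leaf (`ranger`'s num.trees, max.depth, min.node.size,
min.bucket); the reference values are not pinned down anywhere, so
`default_param_grid()` ships a broad 144-point grid and
`compact_param_grid()` an 8-point subset used for desk-scale runs. Shuffled
baselines permute *training-set* labels at the unit level and leave test
labels untouched. The cross-region analysis trains on ~80% of one region's
units, evaluates on the held-out same-region test set and on all units of the
other region, selects hyperparameters on a development/evaluation split of
the training chunks (development capped at 5000 chunks), and reports
(AUC_same − AUC_other)/AUC_same.

All per-partition seeds derive deterministically from one master seed
(`derive_seed`), so 50-run medians are reproducible bit-exactly.

## Explainability and statistics

Feature attributions are Shapley additive explanations for tree ensembles,
computed by the path-dependent polynomial-time algorithm with node covers
taken from each tree's in-bag training counts. Per sample, attributions plus
the cover-weighted base value equal the tree-traversal prediction exactly
(local accuracy, tested to 1e-6 and in practice exact to machine precision).
Attributions of chunk-statistic columns are folded into their base feature by
summation, giving 34 importance values; significance is one-tailed against
attributions from shuffled-label (chance-level) models. The full null
regenerates partitions 1000 times; a reduced default ships for runtime, with
the count exposed.

Supporting statistics: the nonparametric common-language effect size A_w
(pair counting with half-weight ties, folded to [0.5, 1]; two-sided
Mann–Whitney p via the normal approximation), plug-in mutual information on
10 equal-count bins (naturally discrete variables keep their categories;
equal-count binning makes MI(x, x) hit the log₂10 = 3.3-bit cap exactly and
renders the estimate invariant under monotone transforms, consistent with the
rank-based framing of the rest of the analysis; equal-width binning would be
a different, non-invariant choice), permutation tests for differences of
correlation-coefficient group medians, and the usual rank tests
(Mann–Whitney, Wilcoxon signed-rank, Kruskal–Wallis with Tukey HSD on ranks
for the pairwise follow-up — a rank-based Tukey was chosen over Dunn-type
variants; the alternative would change only the correction, not the
omnibus).

## The synthetic generator

The generator is a phenomenological emulator with one job: produce labeled
populations whose *measured* features reproduce the class contrasts the
pipeline is meant to detect, under full ground-truth control.

* **Spike trains** — interspike intervals follow a two-state mixture: with
  probability `burst_fraction` an intra-burst interval uniform in 3–8 ms,
  otherwise refractory period (1.5 ms) plus an exponential whose mean is
  solved so the overall rate matches `rate_hz` exactly. PYR-like defaults
  (0.69 spikes/s, burst fraction 0.3) give the short-latency ACH excess of a
  bursty cell; PV-like defaults (8.95 spikes/s, burst fraction 0.02) give a
  near-renewal train.
* **Templates** — smooth triphasic shapes (hence well band-limited at 20 kHz
  sampling): a pronounced narrow initial positivity, a Gaussian trough whose
  FWHM is the class's trough width (0.21 / 0.16 ms), and a Gaussian
  after-potential one TTP duration (0.77 / 0.29 ms) later. Amplitude decays
  exponentially with distance from a randomly placed soma channel
  (0.022 /µm), which makes the 25% mask remove a 2–5 channel median, as on
  recorded probes.
* **Event offsets** — per channel, systematic FMC/NEG/SMC offsets are drawn
  from the class jitters (FMC 15.9 vs 40.6 µs, NEG 13.5 vs 9.4 µs, SMC 26 vs
  24.1 µs) and realized by a smooth time warp: the trough center rides the
  NEG offset while the leading and trailing flanks are warped toward the FMC
  and SMC offsets, so the three events are controllable separately. Draws are
  truncated at 3 SD to keep the warp monotone. Because the downstream
  time-lag-SD statistic is a population SD over the few unmasked channels, it
  under-reports a Gaussian SD by the classical factor √((k−1)/k)·c₄(k); the
  generator scales its draws by the inverse so that the *recovered* medians —
  the quantities the class parameters are specified in terms of — center on
  the configured values while the natural inter-unit spread is preserved.
* **Intraunit drift** — a per-channel AR(1) wander of spike timing across the
  unit's spikes (SD 8 µs PYR, 25 µs PV), centered per channel so it shapes
  across-chunk variability without perturbing unit-level offsets. This is
  what makes across-chunk feature SDs larger for PV units, so chunk
  statistics are informative on synthetic data.
* **Noise** — additive white noise per sample (SD 0.025 of the soma trough
  depth).

The `"null"` preset gives both classes identical parameters; only labels
differ, so any downstream model must sit at chance — the generator's own
negative control. What the generator does *not* emulate: overlapping-spike
collisions, electrode drift, correlated background activity, non-stationary
rates, or any biophysics. Passing tests on synthetic populations therefore
validate mechanics and orderings, not field performance.

## Problem sizes and numerical choices

Reference-scale test populations use 80 PYR + 20 PV units (preserving the
~80/20 imbalance of tagged datasets) at 300 s duration with spike counts
capped at 4000 per unit; model experiments use 50 partitions with the compact
8-point grid; permutation nulls in tests run at reduced counts (the full
counts are arguments). These sizes were chosen so the whole validation runs
comfortably on a laptop while every statistical check retains power; all of
them are parameters, not constants. Binning at exact bin edges tolerates
1e-9 relative float noise; event detection requires crossings to be strictly
on the far side of the median; and all container floats are written with 17
significant digits so round trips are bit-exact.

## I/O formats

The native dataset container is a single plain-text file (header with
sampling rate, channel count and unit count, then one block per unit). A
plain-text single file was chosen over a hierarchical binary container so
fixtures are diffable, portable, and exactly reproducible; the cost —
file size — is irrelevant at fixture scale and acceptable at session scale.
Readers for the classic Neurosuite `.spk`/`.res`/`.clu` family are included
(cluster ids 0 and 1 treated as noise/artifact by convention; labels must be
supplied separately, since these files carry none). Feature tables are plain
CSV; configuration is YAML with keys `channels`, `coords_um`,
`sampling_rate`, `chunk_size`, `seed`, `n_partitions`, `grids`. The exported
functions are the package's interface; no command-line wrapper is shipped
because every workflow step is a one-liner in R.

## Known limitations

* Spatial features assume a fixed probe layout with tens-of-µm pitch; other
  geometries work mechanically but the 25% mask and the event-graph weights
  may need re-examination.
* The 1.6 ms snippet bounds what waveform and spatial features can see; slow
  after-potentials are truncated.
* TreeSHAP is implemented in R; it is exact but not fast. Attribution runs
  should cap explained samples (the pipeline's default cap is 1000).
* The unit-level score after majority voting is the PV-vote fraction, which
  is coarse for units with few chunks; AUCs on small test sets are
  correspondingly quantized.
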