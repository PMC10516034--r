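---
title: "Triple correlation, motif classes, and the 4D entropy of spike rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple correlation, motif classes, and the 4D entropy of spike rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricorr)
```

## The model

A spike raster is a binary matrix $r(n, t)$: channel $n$, time bin $t$,
entry 1 when the channel fired in that bin. Pairwise tools (auto- and
cross-correlation) describe such a raster up to second order; the triple
correlation

$$ c_3(n_1, t_1, n_2, t_2) \;=\; \sum_{n,t} r(n,t)\, r(n+n_1, t+t_1)\,
   r(n+n_2, t+t_2) $$

relates a reference spike to up to two other spikes separated by two
spatial lags $(n_1, n_2)$ and two temporal lags $(t_1, t_2)$, and captures
third-order structure that pairwise statistics cannot. Accumulating the
contributions over a bounded window $|n_i| \le S$, $|t_i| \le T$ yields a
4D spatiotemporal lag distribution — `triple_correlation()` returns it as a
`lag_tensor`. Normalizing the tensor by its total gives a probability
distribution over lag quadruples (`estimate_pdf()`), and its Shannon
entropy in bits,

$$ H = -\sum_i p_i \log_2 p_i, $$

summarizes how concentrated or dispersed the network's spatiotemporal
structure is (`shannon_entropy()`). Structured activity concentrates mass
on few lag cells (low $H$); unstructured activity of the same spike rate
spreads it (high $H$).

Each lag quadruple also has a qualitative shape: the pair of weak orders of
the three node times $(0, t_1, t_2)$ and channels $(0, n_1, n_2)$. Thirteen
weak orders of three items per axis give $13 \times 13 = 169$
configurations, which collapse into 14 motif classes — spike rate (0),
autocorrelation (I), synchrony (III–IV), cross-correlation (V), feedback
(IX), divergence (XI), convergence (XII), feedforward (XIII), and mixed
two-channel forms (II, VI–VIII, X). `motif_spectrum()` sums the tensor
within classes; the spectrum conserves the tensor total, and the class-0
entry always equals the spike count (the zero-lag cell is the only member
of class 0).

### Assumptions

* The raster is binary; multiple events per channel/bin clip to 1.
* Channel ordering is arbitrary: every channel may interact with every
  other within the spatial lag bound. The classification is therefore
  invariant to spatial reflection. This assumption suits multielectrode
  cultures; it would not suit data where electrode geometry fixes an
  ordering.
* Temporal direction is meaningful and is *not* collapsed: time reversal
  exchanges divergence with convergence (XI–XII), and likewise VI–VII and
  VIII–X, while all other classes are self-symmetric. The test suite
  enforces exactly this involution.

## The classification table

The 169-row configuration-to-class table ships as a plain CSV
(`inst/extdata/motif_configurations.csv`, regenerated by
`data-raw/motif_table.R`) and is validated at load: 169 unique
configurations, 14 classes, class 0 a singleton. Classes named by the
taxonomy (0, I, III, IV, V, IX, XI, XII, XIII) are pinned by geometric
predicates in the tests. For the remaining labels the package uses a fixed
convention: II is the three-spike single-channel pattern (the third-order
analogue of autocorrelation); VI/VII are the two-channel two-time L-shapes,
distinguished by whether the synchronous moment comes first (VI) or last
(VII); VIII/X are the two-channel three-time shapes with the lone-channel
spike first (VIII) or last (X), bracketing feedback (IX), where the lone
spike falls between the doubled channel's two spikes.

## Numerical choices

* **Sums, not averages.** The definition can be read with an averaging
  bracket over $(n, t)$; the package stores raw sums, which keeps the
  zero-lag identity `c3(0,0,0,0) == spike count` exact in integers. The
  averaged form is available (`average = TRUE`) and differs by the constant
  $1/(N T_{\mathrm{total}})$, which cancels in the PDF — entropy is
  identical either way (tested).
* **Zero padding.** Factors outside the raster are 0 and every cell serves
  as a reference position. This preserves the zero-lag identity exactly.
  `boundary = "valid"` restricts references to the interior instead; it is
  not the default.
* **Plug-in entropy, no smoothing.** The PDF is the maximum-likelihood
  histogram; no pseudocounts, no bias correction (Miller–Madow, NSB are out
  of scope), and the support is the full window — structurally impossible
  cells are kept at probability 0, since trimming would change $H$.
* **Degenerate inputs.** An all-zero tensor has no PDF; `estimate_pdf()`
  raises a typed error rather than returning NaN. Silent epochs inside the
  pipeline are logged in the diagnostics table, not fatal. Chance
  expectations of 0 make the normalized prevalence undefined; it is
  returned as `NA`, never infinity.

## Surrogates and normalized prevalence

The chance reference is the spike-rate-matched shuffle: spike positions
resampled uniformly without replacement over all cells, preserving shape,
spike count and binariness exactly (`shuffle_raster()`). An ensemble
(`surrogate_ensemble()`, default $n = 100$) runs the full
tensor → spectrum → PDF → entropy chain per shuffle; its per-class mean
$\mu$ is the empirical chance expectation, and the normalized prevalence
$M/\mu - 1$ is positive where the observed class exceeds chance.
`normalized_prevalence()` also accepts any per-class expectation table, the
hook for analytic expectations conditioned on lower-order classes, which
this package does not compute. Each ensemble runs under one seeded RNG
state; identical seeds reproduce it bit for bit.

## What the synthetic generator emulates

`generate_feedforward_raster()` builds the canonical worked example: 16
isolated three-spike feedforward motifs (48 spikes) in a 26-channel ×
96-bin raster at 1 ms bins, analyzed with spatial lags −5..5 and temporal
lags −4..4. The default template offsets are (0,0), (+1,+1), (+2,+3):
three distinct channels, strictly increasing times, and three *distinct*
pairwise lag vectors, so the 48 zero-lag contributions split as 48/3 = 16
into each of the three positive pairwise-lag cells of the
$(n_2,t_2)=(0,0)$ slice, mirrored at negated lags. A uniform chain such as
(0,0),(1,1),(2,2) would fold two spike pairs onto one lag cell (a 32/16
split) and is deliberately not the default.

Isolation means no two spikes of different motifs are simultaneously
within the margin (5 channels, 4 bins — the analysis window) of each
other, so every triple-correlation contribution involves one motif only
and the motif-spectrum support is exactly {0, V, XIII}; the tests certify
this. Placement is a seeded random draw from the maximal
isolation-respecting slot grid (`placement = "spaced"`). Pure rejection
sampling is also implemented (`placement = "random"`, erroring after a
bounded number of attempts), but random sequential packing jams below 16
motifs at this raster size, so the slot draw is the default. The raster
size itself was chosen once so that the 48 shuffled spikes are dense
enough (≈ 0.02 spikes/cell) for surrogate lag mass to spread over many
cells, making the entropy ordering (raster below every surrogate) a
stable property rather than a marginal one.

`n_background > 0` adds unstructured spikes around the motifs — the
device used to build longitudinal cohorts in which the *fraction* of
activity organized into motifs varies while the spike budget stays fixed.
That matters because $M/\mu - 1$ normalizes by chance: chance triplet
counts grow superlinearly with spike count, so comparing prevalence across
ages is only meaningful at comparable rates.

What the generator does **not** emulate: refractoriness, bursting,
per-channel rate heterogeneity, jitter in motif timing, or any biophysics
(no integrate-and-fire dynamics). Passing tests therefore certify the
computational chain on idealized patterns, not robustness to the noise
structure of real recordings.

## The epoch and cohort pipeline

`analyze_recording()` cuts a recording into epochs (the longitudinal
convention is 60 one-second epochs; placement evenly spaced, contiguous,
or listed — the convention does not fix it, so it is configurable and
recorded in the report), computes one lag tensor per epoch, and **sums**
tensors before normalizing once into a single PDF and entropy per
recording. Summing weights epochs by their activity and is additive:
per-epoch tensors of epochs separated by silent margins wider than $T$
reproduce the unsplit tensor exactly (tested). A per-epoch entropy option
exists for diagnostics. Pipeline surrogates shuffle within each epoch,
matching the observed computation epoch for epoch.

`aggregate_cohort()` summarizes reports across wells per age: quartiles
and range of $M/\mu - 1$ per class, and of entropy. A well contributes at
an age when its tensor total is nonzero; the median trace is reported only
when contributing wells exceed 7 (strictly), else marked suppressed.

## Problem sizes and limitations

The shipped tests run the worked example (48 spikes, 9,801-cell window),
100-surrogate ensembles on it, oracle comparisons on 50 random rasters up
to 8 × 20 cells with $S, T \le 2$, and a 24-report synthetic cohort —
small enough to verify every identity exactly while exercising each module
end to end. Cost scales as the number of spikes times the squared mean
in-window neighborhood, so dense long recordings at large windows are the
expensive case; `lag_window_ms()` converts millisecond bounds to bins when
planning realistic windows (e.g. ±50 ms at 1 ms bins, $T = 50$).

Known limitations: the entropy is the plug-in estimate and inherits its
small-sample bias; chance expectations are empirical means over finite
ensembles, so prevalence carries Monte-Carlo error of order
$1/\sqrt{n_{\mathrm{surrogates}}}$; and no numeric entropy values are
available for external reference at the worked-example scale — orderings
(structured below shuffled), identities and conservation laws are the
verifiable quantities.
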