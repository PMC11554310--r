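---
title: "Models and methods behind pisascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pisascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisascreen)
```

## The measurement model

A proteome integral solubility alteration (PISA) experiment estimates the
area under a protein's melting curve in a single multiplexed measurement:
aliquots of one treated sample are heated at a gradient of temperatures,
the soluble fractions are pooled in equal volumes, and one TMT reporter
channel quantifies the pooled soluble protein. `pisascreen` models the
per-protein melting curve as a two-state logistic with an optional
non-denaturing plateau,

$$f(T) \;=\; c + \frac{1 - c}{1 + \exp\!\big((T - T_m)/b\big)},$$

where $T_m$ is the melting temperature, $b > 0$ the transition scale in
degrees Celsius, and $c \in [0, 0.3]$ the plateau. The two-state logistic
is the standard working model in thermal proteome profiling; it is
analytically tractable, strictly decreasing in temperature, and satisfies
$f(T_m) = c + (1-c)/2$. Equal-volume pooling over $n$ equally spaced
gradient temperatures spanning the thermal window $[w_0, w_1]$ (endpoints
included) gives the integrated soluble signal

$$S_M = \frac{1}{n}\sum_{i=1}^{n} f(T_i),$$

and a ligand-induced shift $\Delta T_m$ is read out as
$\Delta S_M = \log_2 S_M(T_m + \Delta T_m) - \log_2 S_M(T_m)$
(`expected_log2fc()`). Because $S_M$ is strictly increasing in $T_m$, the
sign of the fold change always matches the sign of the shift, and its
magnitude grows monotonically with $|\Delta T_m|$. The default window is
48–58 °C with `n_temperatures = 10` (one PCR tube per gradient point):
this window sits on the back half of most melting curves, and a narrower
window concentrated on the transition amplifies fold changes — on the
default proteome, the mean $|\Delta S_M|$ at $\Delta T_m = +2$ °C is
roughly 2.5–3 times larger for 48–58 °C than for 37–62 °C.

## The synthetic screen generator

The generator exists so that every downstream stage is testable against a
known ground truth without any external data.

* **Proteome.** `sample_proteome()` draws $T_m \sim N(51, 4)$ °C,
  $b \sim U(1.2, 2.5)$ °C and $c \sim U(0, 0.15)$. These defaults were
  chosen once so that well over 80 % of proteins are *window-informative*
  ($S_M \in (0.05, 0.95)$ over 48–58 °C), i.e. the window genuinely covers
  the back half of their melting transition.
* **Layout.** `design_layout()` packs compounds in duplicate plus vehicle
  channels into 16-plexes: 6 compounds + 4 vehicle channels per plex in
  cell mode (96 compounds → 16 plexes, 256 channels), 7 + 2 in lysate mode
  (70 compounds → 10 plexes, 160 channels). Both replicates of a compound
  are always co-plexed, because fold changes are only meaningful within a
  plex. Only the totals are externally constrained; the per-plex vehicle
  counts are the unique small integers that close those layouts.
* **Effects.** A `compound_effects()` row shifts one protein's $T_m$ by a
  signed amount. `effect_class = "secondary"` marks stability changes that
  arise from cellular context (e.g. signalling downstream of the direct
  target) rather than direct binding; the generator applies them in cell
  mode and suppresses them in lysate mode, reproducing the qualitative
  cell-versus-lysate dichotomy without modelling phosphorylation
  explicitly.
* **Noise.** Each measurement is multiplied by log-normal noise with
  coefficient of variation `measurement_cv` and each channel by a
  log-normal loading factor with CV `loading_cv`. The defaults are 0.05
  and 0.2: a 5 % protein-level CV is typical of summed reporter-ion TMT
  quantification, and it was fixed once after verifying that the
  vehicle-based false-hit rate of a full null screen stays within the 3 %
  calibration bound that the hit-calling cutoffs are designed to enforce
  (measured: ≈ 0.2 %). With both CVs zero the generator is exactly
  deterministic and the measured log2 fold change of every applied effect
  equals `expected_log2fc()` to machine precision.
* **Benchmark screens.** `benchmark_screen()` (50 compounds × 2,000
  proteins by default) gives every compound one primary target with
  $|\Delta T_m| \sim U(0.5, 6)$ °C of random sign — saturating ligand
  engagement produces target-specific shifts from barely detectable to
  large — and one secondary effect for a fifth of the compounds.
  `complex_screen()` plants a three-member complex sharing effect
  profiles across 8 of 40 compounds among 200 background proteins.

What the generator does **not** emulate: peptide/PSM-level effects
(reporter-ion interference, isotopic impurity, signal-to-noise filtering),
protein-abundance-dependent variance, correlated biological noise between
replicates, missingness mechanisms (values are missing only if you make
them so), and non-equilibrium denaturation kinetics. Passing tests on
synthetic screens therefore demonstrate the correctness and calibration of
the statistical machinery, not the full error structure of real screens.

## Normalization

`normalize_channel_sums()` equalizes total protein loading: within each
plex, every channel is rescaled so its summed protein quantity equals the
plex-wide mean of the original sums. The sums are computed over the
proteins quantified in *all* channels of that plex — otherwise a channel
with more missing values would be systematically over-scaled — but the
resulting factor is applied to every value in the channel. The operation
is idempotent and leaves within-channel ratios untouched. Missing values
propagate as missing; nothing in the pipeline imputes.

## Hit calling: the nSD dual-cutoff framework

With duplicate treatments, per-treatment significance tests are
underpowered, so hits are defined jointly by effect size and per-protein
variability:

1. **Fold changes** (`compute_log2fc()`). Every treated channel is
   expressed as $\log_2(\text{abundance} / \text{vehicle mean})$ within
   its plex. Each vehicle channel is additionally scored against the
   leave-one-out mean of the other vehicle channels of the plex; these
   single-replicate *vehicle pseudo-treatments* put the null behaviour of
   every protein into the variability pool on the same footing as real
   treatments.
2. **Variability** (`protein_variability()`). Replicates are averaged per
   treatment, and for each protein the trimmed mean and trimmed standard
   deviation of the treatment-level values across all treatments (vehicle
   pseudo-treatments included) are computed. Trimming removes
   $\lfloor n \cdot \text{trim} \rfloor$ values from each tail after
   sorting; the default `trim = 0.1` per tail discounts a protein's few
   genuine (or promiscuous) responses when estimating its baseline
   spread, so that a protein that responds to many compounds
   non-specifically acquires a large trimmed SD and is penalized.
3. **nSD** (`compute_nsd()`). Each treatment's score is its distance from
   the protein's trimmed mean in units of the trimmed SD — a robust
   z-score. Centring on the per-protein mean (rather than zero) absorbs
   protein-specific offsets.
4. **Dual cutoff** (`call_hits()`). A (protein, treatment) pair is a hit
   iff *every* replicate satisfies $|\log_2\text{FC}| \ge 0.2$ and the
   treatment satisfies $|\text{nSD}| \ge 3.5$. Both cutoffs are applied
   inclusively and are configurable. The fold-change filter removes
   low-amplitude background; the nSD filter removes proteins whose large
   fold changes are unexceptional *for that protein*. The direction
   (stabilized / destabilized) follows the sign of the mean fold change.

Degenerate cases: proteins with fewer than 3 treatment-level values get
`NA` statistics; a trimmed SD of exactly zero (constant protein) yields a
missing nSD — such proteins can never be hits. `trim` must lie in
$[0, 0.5)$; larger values would trim away everything and are rejected up
front. A missing replicate measurement always fails the every-replicate
rule.

**False-hit calibration** (`dmso_false_hit_rate()`). The vehicle channels
of each plex are partitioned into disjoint pairs; each pair in turn is
relabelled as a duplicate pseudo-compound and the full pipeline is re-run
against the remaining vehicle channels. The rate of pseudo-compound hits
over measured protein × pseudo-compound pairs estimates the false positive
rate of the cutoffs; at the defaults on a full null cell-mode screen it is
about 0.2 %, comfortably below the 3 % design bound. This construction
needs at least 4 vehicle channels per plex.

## Target assessment

`on_target_table()` joins hit calls to a known-target annotation. The
bookkeeping is per compound, not per pair: a compound is *on-target* in a
mode if **any** of its annotated targets is a hit there, and its target is
*quantified* if any annotated target was measured. Compounds without a
quantified target never enter rate denominators. When cell and lysate
screens are both available, `hit_rate_summary()` reports rates over the
compounds quantified in both — the directly comparable set — so the
combined (hit-in-either-mode) rate is always at least as large as either
single-mode rate. `target_separation_test()` asks globally whether
annotated targets move more than everything else: a two-sided Wilcoxon
rank-sum test on $|\text{mean log2FC}|$ of annotated pairs versus all
other measured pairs, exact below a combined group size of 30 and
normal-approximated with continuity correction above.

## The solubility correlation network

Proteins engaged by overlapping compound sets show correlated solubility
profiles even when the individual changes are small. `coef()` of a fit
(equivalently `build_profile_matrix()`) gives the protein × treatment
mean-log2FC matrix; `all_by_all_spearman()` computes rank-based
Spearman's $\rho$ for every unordered protein pair over pairwise-complete
treatments (average ranks for ties), requiring `min_pairs >= 10` complete
pairs by default so that a correlation is never estimated from a handful
of points. Rank correlation is used deliberately: it damps the influence
of single extreme responses. The total comparison count is reported with
the $P^2$ convention (self-pairs and both orders counted) to match the
established bookkeeping for these maps — an 8,390-protein matrix yields
70,392,100 binary comparisons — while the edge list itself stores each
unordered pair once.

`filter_edges()` keeps $|\rho| > 0.35$ by default, a threshold that on
large screens corresponds to roughly the top 5 % of absolute
correlations; an exact-quantile mode (deterministic tie-breaking by
$|\rho|$, then protein ids) is provided when the kept fraction itself is
the target. Per-edge significance could be attached via the usual
t-approximation, but the default filter is deliberately magnitude-based:
at screen scale, the correlation magnitude is the interpretable quantity
and a p-value threshold would simply re-derive a magnitude cut.
`build_network()` assembles an undirected igraph graph (edge weight =
$\rho$) with kinome-group node annotations
(`r paste(kinome_groups, collapse = ", ")`; unannotated nodes are
"unknown"), and `extract_subgraph()` restricts by node set or group.

## Validation problem sizes

The package validates itself at deliberately chosen scales: the null
calibration uses a full-geometry screen (16 plexes × 16 channels, 6,800
proteins); target recovery uses the default 50-compound × 2,000-protein
benchmark; planted-complex network recovery uses 100 independent seeds of
a 203-protein screen; analytic identities and oracle comparisons use
fixtures of a few proteins where brute-force recomputation is exact.
Under these conditions the defaults recover primary targets with
$|\Delta T_m| \ge 2$ °C at sensitivity ≥ 0.95 with a non-target
false-call proportion well under 1 %, and the planted complex survives
default edge filtering in essentially every seed.

## Known limitations

* The two-state logistic cannot represent multi-domain proteins with
  biphasic melting or temperature-dependent aggregation artefacts.
* The nSD statistic conditions on the screen's treatment diversity: in a
  screen where many compounds genuinely engage the same protein, the
  trimmed SD inflates and sensitivity for that protein drops — a
  trade-off inherited from the framework, not a bug of the
  implementation.
* With duplicate designs the every-replicate rule makes hit calls
  sensitive to single outlier replicates in the conservative direction
  (missed calls, not false calls).
* Dose series are handled by treating each (compound, dose) as its own
  treatment; no dose-response model is fitted.
* The vehicle-based false-hit rate estimates the behaviour of truly null
  channels; it does not capture systematic artefacts shared by all
  channels of a plex.
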