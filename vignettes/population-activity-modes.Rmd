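---
title: "Population activity modes and coding geometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population activity modes and coding geometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmodes)
```

## The scientific setting

popmodes analyzes trial-aligned extracellular recordings from frontal cortex
during a delayed-response decision task. On each trial a tactile stimulus is
presented during a *sample* epoch (1.3 s), the animal withholds its response
through a *delay* epoch (1.3 s in the primary configuration, 1.7 s in a
long-delay configuration), and an auditory go cue opens the *response*
window. Trials fall into four informative conditions by instructed side and
accuracy — correct lick-right (CR), correct lick-left (CL), error lick-right
instructed (ER), error lick-left instructed (EL) — plus ignore and early-lick
trials. All times are relative to the go cue; the 500 ms before the sample
epoch serve as the baseline (presample) window.

The package addresses two linked questions. First, are single-neuron response
profiles drawn from a continuum or from repeatable prototypes? Second, is
task information (stimulus identity, upcoming choice, movement, outcome)
carried by dedicated neuronal populations, or randomly mixed across a shared
population?

## Response-profile landscape

Each unit's PSTH is computed on a 1-ms grid spanning presample through
response epochs with a causal 100-ms boxcar by default (a Gaussian kernel is
available). The population response matrix concatenates the correct-trial
lick-right and lick-left PSTHs per unit; each segment is baseline-subtracted
by its presample mean, and the concatenated row is divided by its Euclidean
norm, making the representation invariant to overall rate scale. Units are
excluded when their spike-width class is ambiguous (0.35–0.45 ms
trough-to-peak), or when split-half PSTH reliability falls below 0.5
(interleaved odd/even trial halves per condition; the comparison is
inclusive, so exactly 0.5 passes). Every exclusion is logged with its
reason.

The landscape analysis reduces the matrix to its top principal components,
embeds the loadings in two dimensions with t-SNE (perplexity 50, cosine
distance, ten restarts keeping the lowest final Kullback–Leibler divergence)
and clusters the embedding by density peaks: each point receives a
Gaussian-kernel local density (bandwidth 2% of the embedding diameter) and
the distance to its nearest higher-density neighbor; centers are extreme in
the product of the two (both min–max scaled), and remaining points join
their nearest denser neighbor's cluster in density order. Density-peak
center selection is traditionally done by hand from the decision graph; the
default here is automatic — the largest multiplicative gap in the sorted
center score, with a floor of 5% of the score range so that noise among
near-zero scores cannot masquerade as a gap. Explicit center lists and
requested center counts are still accepted. Over-clustering is corrected by
greedily merging cluster pairs whose mean profiles correlate above a
threshold (default r = 0.95; merging is meant as a light-touch correction,
so the fraction of clusters merged is logged and should stay under ~10%). Cluster sets from different datasets are
matched by highest profile correlation (conflicts fall to the next best
match), after linear compression of long-delay PSTHs onto the short-delay
grid. Reproducibility against a second clustering (by default Louvain on the
Jaccard neighbor graph) uses a strict two-way majority rule: a matching
cluster must have more than half of its units inside the original cluster,
and the original cluster is reproducible only if more than half of its units
are captured back.

## The ePAIRS test

Whether coding vectors (PC loadings, or mode weights below) form clusters is
tested by comparing each vector's mean angle to its k nearest neighbors
(default k = 3; a 1–10 sweep is provided) against vectors resampled from a
zero-mean Gaussian with per-dimension variances matched to the data. The
test statistic is the population median of these mean neighbor angles; the
p-value is the fraction of Monte-Carlo null medians at or below the
empirical median, so clustering (unusually small angles) gives small p. The
angle metric folds antipodal vectors together (arccos of |cosine|): the sign
of a mode weight encodes trial-type preference, not a distinct response
class. An unfolded variant is available for comparison. The Monte-Carlo
core is implemented in C++; a test with 10,000 null draws at n = 500
runs in seconds.

One property of the variance-matching step deserves emphasis: because the
null's per-dimension variances are re-estimated from the tested dataset,
the tested data sit exactly at the center of the null's parameter scatter
while the null replicates spread around it. This widens the null
distribution of medians and makes the test conservative — in the package's
calibration study the rejection rate under the test's own null is about
0.03 at d = 7 and 0.01 at d = 26 for a nominal 0.05. A control variant
that feeds the true generating variances to the null
(`study_epairs_calibration(oracle = TRUE)`) is nominally calibrated, which
pins the conservatism on the variance-matching step itself rather than on
the statistic or the Monte-Carlo machinery. Conservatism never inflates
false positives, and power at the study's planted separation is still 1.0,
so clustering verdicts from the test remain trustworthy; reported p-values
near the threshold should simply be read as understated evidence.

## Selectivity vectors and the seven activity modes

With condition-averaged population vectors (100-ms windows, 1-ms steps by
default) the selectivity vectors are

- stimulus = ((CR − EL) + (ER − CL))/2 — instructed pole position,
- choice = ((CR − ER) + (EL − CL))/2 — executed lick direction,
- outcome = ((CR − ER) + (CL − EL))/2 — correct versus error.

Seven activity-mode directions are then defined on a dedicated half of the
trials (50/50 split per condition, seeded): stimulus (stimulus selectivity
averaged over the sample epoch), choice (choice selectivity over the delay),
action (CR − CL during movement initiation, 0.1–0.3 s after the go cue),
outcome (outcome selectivity over the response window), ramping (late-delay
minus presample activity, correct trials pooled), go (±100 ms around the go
cue, correct trials pooled), and response (the leading left singular vector
of the baseline-subtracted concatenated PSTH matrix, oriented so the
response-epoch projection is positive). Error-dependent modes require
strictly more than five error trials of each type. All modes are unit-norm
and then Gram–Schmidt orthogonalized in the order stimulus → choice →
action → outcome → ramping → go → response; the order is configurable and
recorded because later modes lose their components along earlier ones. The
final Gram matrix is the identity to 1e-9 on every run. Projections
`Mode' r(t)` use the complementary trial half, with bootstrap-over-neurons
standard errors (default 1,000 resamples). Variance accounting is by r.m.s.
ratio: activity over sample+delay+response epochs, stimulus/choice
selectivity over sample+delay, outcome selectivity over the response window.

Averaging selectivity vectors over an epoch equals applying the selectivity
formula to epoch-averaged rates (the formulas are linear), so mode
definitions use epoch means directly rather than sliding windows.

## The random-mixture reference population

The central geometric contrast needs a null population that preserves the
population-level signals while scrambling per-neuron weights. The response
matrix is decomposed into the seven orthonormal modes plus the leading
eigenvectors of the residual (orthogonal to the modes by construction); each
synthetic neuron is a random combination of the components' temporal
profiles with i.i.d. zero-mean Gaussian weights of variance 1/n. This
preserves each component's share of activity variance in expectation (the
realized share fluctuates like a scaled chi-square, ~3% at 2,000 synthetic
rows) and leaves re-derived mode projections unchanged up to O(1/sqrt(n)),
because the weight matrix is nearly orthonormal in expectation. The
synthesis also transforms the mode-defining condition averages, so the
entire mode pipeline can be re-run on the synthetic population — exactly
how the package's validation studies use it.

The joint-coding diagnostic takes two modes' weights per neuron, folds signs
(|w|), keeps the top 20% of neurons by 2-D vector length, and inspects the
angle distribution: random mixing gives uniform angles on [0°, 90°], while
dedicated populations pile up at 0° and 90°. Against the matched mixture
reference the test is a one-sided two-sample Kolmogorov–Smirnov comparison
on angles folded about 45°, where segregation appears as stochastically
smaller values; the 45° folding turns the two-sided "peaks at both ends"
alternative into a clean one-sided dominance.

Functional populations come from k-means on |weights| (50 restarts), with
the cluster count chosen by maximum mean silhouette over k = 2..12. A
population is provisionally named for a mode when it carries the majority of
that mode's squared weight; the definitive criterion divides the variance of
the projection recomputed with out-of-population weights zeroed by the
full-population projection variance (these restricted variances need not sum
to one).

## Decoding and noise correlations

Task variables are decoded from pseudo-populations: spike counts in 200-ms
windows (50-ms steps), trials randomly matched across units, a linear
maximum-margin classifier (SVM, C = 1) per window. For stimulus/choice/
outcome, pseudo-trials draw equally from all four conditions, which balances
the other two variables across classes; per-unit trials are split 70/30 into
train/test pools before matching (the 70/30 split fraction is a package
choice; the essential contract is that test vectors never share underlying
trials with training). Twenty repeat runs
with fresh matchings give the accuracy mean and s.d. Epoch decoding is a
four-way classification of vectors drawn from the four epochs; reaction-time
decoding contrasts the fastest and slowest thirds of correct trials; ignore
decoding contrasts responded versus ignored trials.

Noise correlations are Pearson correlations of mean-subtracted 100-ms spike
counts across trials and windows, per trial type and epoch, between
simultaneously recorded pairs more than 100 µm apart, each with more than
ten trials per type, each unit used in at most one pair (randomized greedy
maximal matching, seeded). Within- versus across-cluster distributions are
compared by a two-sided Wilcoxon rank-sum test.

## Perturbation and connectivity statistics

Behavioral photoinhibition effects use a hierarchical bootstrap — resample
mice, then sessions within mouse, then trials within session — with the
one-sided p-value equal to the fraction of replicates whose performance
change opposes the observed one. Trial-level resampling uses the exact
multinomial equivalence over (photostim × correct) category counts, which
makes 10,000 replicates essentially free. Spike-rate effects are two-tailed
t-tests on counts inside the stimulation window (trial types pooled; units
below 0.5 spikes/s control rate excluded). Mode-level effects take the
absolute control-versus-photostim projection difference in the stimulation
window, standardized by the temporal s.d. of the control projection, with
neuron-resampling bootstrap comparisons between manipulations.

Optogenetic tagging compares 20-ms pre/post pulse spike counts (one-sided
excitation test; suppressed units are by definition untagged), with latency
read from 0.5-ms bins as the first bin reaching half the peak
baseline-subtracted rate; a unit is putatively connected when excitation is
significant at 0.01, latency is under 5 ms (strict) and more than 0.2 spikes
are evoked per pulse. Whole-cell EPSP features clip spikes by interpolation
(−1 to +4 ms), subtract a 10-ms pre-stimulus baseline, and measure the mean
EPSP in a 20-ms window and the 10%-of-peak latency, defined only when the
peak clears three baseline standard deviations; the connection call is
latency ≤ 5 ms. Membrane time constants are the slow component of a
double-exponential decay fit, with a single-exponential fallback when the
two-component model is singular (a pure mono-exponential input), and an
error when the fit explains less than half the variance.

## The synthetic-data generator

Every analysis is validated against sessions with planted ground truth. A
unit's conditional rate is

λ_i(t) = max(0, b_i + Σ_m w_im f_m(t, condition) + g_k b_i),

with uniform baselines b_i (2–10 spikes/s by default), seven unit-amplitude
temporal templates f_m shaped like the canonical epoch dynamics (the
trial-type-selective ones signed by instructed side, lick direction, or
correctness), planted weights w_im, and a per-trial gain g_k shared within
subnetworks (producing positive within-subnetwork noise correlations of the
shared-gain form). Spikes are inhomogeneous-Poisson draws on a configurable
bin grid. The hard rate floor at zero is the simplest non-negative choice
and slightly biases strongly suppressed low-rate units. In the clustered
regime units load on one-hot prototype weight vectors (with 10% relative
jitter); in the random-mixed regime weights are i.i.d. Gaussian on all
modes. A configurable fraction of units carries no task signal at all —
these must fail the split-half filter. Error trials re-use the same
templates with choice-signed terms keyed to the executed response, so
planted stimulus and choice coding dissociate exactly. Photoinhibition is
applied after generation: factors ≤ 1 thin spikes inside the stimulation
window (exact for a Poisson process), factors > 1 superpose extra spikes
from the known rate.

One global seed drives everything through counter-hashed substreams
(a murmur-style avalanche hash; a plain linear hash measurably correlates
the resulting RNG streams across consecutive trials), so any subset of
units or trials regenerates identically.

What the generator does not emulate: refractoriness and bursting,
slow nonstationarities across a session, behavioral covariates (whisking,
licking kinematics) that correlate with neural activity, and realistic
spike-sorting contamination. Passing recovery tests therefore demonstrates
the correctness of the algorithms under the stated statistical model, not
robustness to every failure mode of real recordings.

## Validation studies and problem sizes

The `study_*` functions run the acceptance-level experiments end to end;
`scripts/acceptance.R` executes them all and writes a JSON summary. Problem
sizes are chosen so the full battery runs in minutes on one core while
keeping each check statistically meaningful:

- ePAIRS calibration: 200 null datasets per dimensionality (7 and 26),
  n = 500 vectors, 1,000 null draws per test; power on two antipodal
  clusters (spread 0.3) over 50 datasets.
- Mode recovery: 20 sessions of 140 units, 100 correct trials per type, all
  seven modes planted in disjoint populations; the response component gets
  twice the amplitude so the leading eigenvector is the response-epoch
  pattern, as in recorded populations.
- Demixing contrast: 50 mixture and 10 segregated sessions of 120 units;
  the variance contract is checked on 2,000-row syntheses.
- Clustering recovery: 20 sessions of 240 units with three planted
  prototypes on sustained templates, five t-SNE restarts.
- Nested bootstrap: 400 null behavioral datasets (3 mice × 2 sessions ×
  100 trials), 1,000 bootstrap replicates each.
- Perturbation: 20 sessions; the choice-coding subnetwork is silenced to
  15% of its rate on 30% of trials during the delay.

## Numerical choices and edge cases

Cell-class intervals are [0, 0.35) / [0.35, 0.45] / (0.45, ∞) ms and layer
boundaries are half-open [lower, upper) at 110 / 378.3 / 771.7 µm
(overridable). Ties in nearest-neighbor distances break by index order;
k-NN classification ties break toward the smaller summed neighbor distance.
Zero-norm response rows are excluded with a log entry; zero coding vectors
are dropped from ePAIRS with a message. A raw activity mode with zero norm
is flagged degenerate and stays zero through orthogonalization, while a
collinear non-degenerate mode raises an error naming it. Density-peak
density ties resolve toward the earlier index. The long-delay resampling is
linear interpolation onto the compressed grid — exact for constants and
ramps and amplitude-faithful for anything smooth on the 100-ms kernel
scale. All Monte-Carlo machinery (generator, splits, bootstraps, t-SNE
restarts at seeds seed..seed+restarts−1) is deterministic given its seed.

## Known limitations

The pseudo-population decoder ignores trial-to-trial correlations between
units by construction. The automatic density-peak center selection is a
heuristic; to reproduce a manually curated analysis, explicit center
lists should be used. The ePAIRS null assumes a diagonal covariance in the
analysis basis — exact for PC loadings, an approximation for mode weights.
Session-offset pooling assumes enough simultaneously recorded units per
session (at least ten) for stable per-session modes.
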