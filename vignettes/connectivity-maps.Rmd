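---
title: "Reference-electrode connectivity maps: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-electrode connectivity maps: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmaps)
```

## The problem and the statistic

Multi-channel event-related EEG is recorded as short stimulus-locked
epochs (here, 1.2-s segments starting 200 ms before a visual stimulus,
sampled at 512 Hz).  Classical connectivity analysis asks how strongly a
pair of electrodes (A, B) co-varies.  The approach implemented here asks a
different question: how does the coupling of A and B *to a third,
reference electrode C* differ between two groups of subjects?  Two
electrodes may show little direct change while their relationship as seen
from a posterior reference changes markedly -- the analogue of detecting a
cancelled airline route not by watching the route itself, but by watching
how traffic from a third city redistributes.

The primitive statistic is the lag-maximized windowed cross-correlation.
For a window size $W$ and an integer sample lag $\varphi$ bounded by a
small limit (20 ms by default), the connectivity of channels A and B in
one subject is

$$
F_{conn}(A,B) \;=\; \max_{w \in \text{grid}} \max_{|\varphi| \le \varphi_{max}}
\; \mathrm{corr}\big(\bar{A}[t],\, \bar{B}[t+\varphi]\big)_{t \in w},
$$

where $\bar A$, $\bar B$ are the trial-aggregated (by default mean over the
first 11 valid stimulus responses) signals and the window grid slides over
the 200--450 ms post-stimulus interval with 90% overlap.  Candidate window
sizes are 50/100/150/200 ms; the size actually used is chosen on training
subjects only, by the mean of the top-10 entries of the resulting Fisher
matrix.  Ties break toward the smaller window, and within the scan toward
the smaller absolute lag, then the negative lag, then the earlier window.
Because a symmetric lag range makes the ordered pair redundant, each
unordered pair is scanned once and mirrored (with negated lag).

Group structure enters through three maps over subjects $s$ with group
means $\mu_g$ and population standard deviations $\sigma_g$ of the
per-subject values $F^{(s)}_{conn}(A,B)$:

* $CM_g(A,B)$ -- the group-mean connectivity map;
* $CM\_STD_g(A,B)$ -- the group dispersion map;
* $FISHER(A,B) = |\mu_{healthy}-\mu_{patient}| \big/
  \sqrt{\sigma^2_{healthy}+\sigma^2_{patient}}$, floored at $10^{-12}$.

The discriminating features are *relative*:

* $REL_C(A,B) = conn_C(A) - conn_C(B)$ per subject, for every reference C
  and unordered target pair, $n\binom{n-1}{2}$ columns in total;
* $MUL_C(A_1,B_1,A_2,B_2) = REL_C(A_1,B_1)\,REL_C(A_2,B_2)$ for unordered
  pairs of retained REL columns *sharing the reference* C (sharing is what
  lets a multi-purpose reference amplify; the restriction to retained
  columns keeps the $O(n^5)$ combinatorics bounded);
* the Fisher score of any feature column, used for ranking.

A note on the Fisher denominator: dividing the mean difference by the
dispersion *of the dispersion maps* degenerates to zero whenever each
subject contributes a single aggregated connectivity value.  The package
therefore uses the standard Fisher discriminant denominator -- the group
standard deviations of the per-subject values, which are exactly the
$CM\_STD$ maps -- and retains the literal degenerate reading behind
`fisher_denominator = "printed"` for comparability.

## Preprocessing

Epochs are band-pass filtered to 0.1--30 Hz, rejected when any channel
exceeds 75 µV in absolute amplitude (evaluated on filtered,
pre-normalization microvolts, optionally intersected with an externally
produced behavioral/ocular mask), normalized to unit per-channel standard
deviation over the valid trials, and aggregated over the first `n_stimuli`
valid trials (invalid trials are skipped, not counted; fewer than 3 usable
trials raises a warning, zero is an error naming the subject).

**Filtering design.**  Lags carry the connectivity signal, so the filter
must be exactly zero phase.  Forward-backward IIR filtering is the common
route, but on 1.2-s epochs its start/end transients dominate: in our
measurements a forward-backward Butterworth cascade left 4--17% RMS of a
pure 40 Hz tone after 0.1--30 Hz filtering (depending on boundary
handling) and made the six 5-Hz sub-bands sum to the broadband signal only
to within 16--36% RMS.  The package instead multiplies each epoch's
spectrum by the *squared Butterworth magnitude* (order 8 at band edges,
order 2 below 1 Hz): exactly zero phase, transient-free, and
power-complementary -- a same-order low/high pair at a shared cutoff sums
to one exactly, so the six-interval filter bank reconstructs the broadband
signal to ~2% RMS and a 40 Hz tone keeps under 2% RMS.  The first 5-Hz
interval starts at the 0.1 Hz filter floor; "equal" intervals are equal in
width above it.

Band subsets (all 63 non-empty unions of the six intervals, plus the
classical named bands) are reconstructed by summing their member
intervals' filtered signals.  The default configuration analyzes the full
band only; the enumeration is available for configuration-selection
studies, in which case the subset, like the window size, must be chosen on
training folds.

## Feature selection and classification

Within each training set (and only there):

1. direct (CM) and REL columns are ranked by their between-group Fisher
   score and the top 10% retained (`retain_fraction`); MUL columns are
   built from the retained REL columns;
2. features are grouped by their source/reference electrode; for a
   candidate electrode budget $K_1$ each electrode is scored by the mean
   of its top-$K_1$ feature Fisher scores, and the top-$K_1$ electrodes
   are kept;
3. surviving features are ranked by their Laplacian score on a
   k-nearest-neighbor subject-similarity graph (heat-kernel weights with
   width set to the median squared pairwise distance; lower = better;
   constant features get the worst score) and the best $K_2$ fraction is
   kept;
4. the $(K_1, K_2)$ grid ($K_1/n \in \{0.1,\dots,1\}$,
   $K_2 \in \{5\%, 10\%\}$) is arbitrated by inner leave-one-out accuracy
   on the training fold.  The label-dependent ranking (steps 1--2 Fisher
   scores, electrode cut) is recomputed inside every inner fold; the
   Laplacian graph is label-free and computed once per training fold.
   Ties resolve toward fewer electrodes, then fewer features.

Classification uses a two-state model with independent Gaussians per
feature and class (variances floored at $10^{-12}$, equal priors): the
predicted label maximizes log-likelihood plus log-prior, the margin is the
absolute log-likelihood difference, and a Wilks-style $\chi^2_1$ tail
probability of twice the margin is reported alongside (it never drives the
decision; exact ties resolve to the healthy class and are flagged).

Outer validation is leave-one-out over subjects.  Everything that depends
on group labels -- the (band, window) choice, Fisher maps, the variance
filter and MUL set, Laplacian scores, the grid, the Gaussian fit -- is
recomputed on the remaining subjects in every fold; per-subject quantities
(filtering, rejection, aggregation, connectivity tensors) are label-free
and shared.  The patient class is positive for sensitivity.  The primary
significance measure is a label-permutation test of the LOO accuracy,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$, which is
distribution-free and honest under selection.

`direct_only_mode()` is the built-in ablation: the identical pipeline with
REL/MUL construction disabled, so feature tables contain pairwise
connectivity only.

## The synthetic cohort generator

No clinical recordings ship with the package; `generate_cohort()` supplies
study-shaped data with a known planted effect.  Each subject contributes
stimulus-locked trials of per-channel $1/f$ background noise (spectrally
shaped Gaussian noise, exponent 1) plus an evoked component -- a
Gaussian-windowed half-sine whose latency varies across the scalp along a
fixed diagonal gradient (70 ms per unit of $y + 0.6x$ scalp position by
default) and jitters $\pm 10$ ms between subjects.  Giving every
electrode a clearly distinct evoked latency matters twice over: with one
shared waveform every channel is a perfect proxy for every other under
lag realignment, and no planted source is identifiable; and the evoked
component must be narrow enough (width parameter 40 ms, the Gaussian
$\sigma$) that latency offsets of a few tens of milliseconds actually
decorrelate the waveforms -- with an 80 ms width, same-region electrodes
remained near-proxies and the top-ranked Fisher connection was ambiguous
between the planted source and its neighbors.

A coupling `source -> target` with gain $g$ and lag $\ell$ mixes the
source's full signal into the target variance-preservingly:
$\text{target} = g\,\text{source}(t-\ell) + \sqrt{1-g^2}\,\text{own}$.
In the evoked-free limit the planted lagged correlation equals $g$
exactly; with an evoked component, the *trial-averaged* waveforms -- which
are what the connectivity statistic correlates -- inherit the contrast:
a high-gain target's average is dominated by the delayed source waveform,
a low-gain target's by its own differently-timed bump.

Default study conditions (chosen once, as conditions under which the
planted posterior-to-frontal effect is recoverable, and then frozen):
20 + 20 subjects, 8 channels (`demo_montage()`), 512 Hz, 1.2-s epochs from
-200 ms, 15 trials, evoked amplitude 12 µV and width 40 ms at 300 ms
latency, noise 3 µV, artifact pulses of 100 µV for 50 ms on 5% of trials
(guaranteeing the 75 µV rejection path is exercised), and a planted
P8-to-F2 coupling at 20 ms lag with gain 0.8 (healthy) vs 0.3 (patient).
An earlier noise-carried design was abandoned for a quantitative reason
worth recording: trial-averaged $1/f$ noise inside 50--200 ms windows is
so smooth that the max-over-(window, lag) scan pushes even independent
channels to correlations near 0.9, burying any gain contrast; the evoked
carrier stabilizes the estimate and is closer to what the statistic
actually measures in event-related data.

`generate_relative_only_scenario()` constructs the cohort for the ablation
contrast: a posterior reference (O1) drives two frontal targets (F1, F2)
with a class-swapped gain split (0.7 on the favored, 0.3 on the other),
while a per-subject evoked-amplitude scale $s_i \sim U(0.1, 5)$ on the
two targets acts as a nuisance that moves every direct edge far more than
the split does.  (The scenario keeps its own latency gradient of 50 ms
per scalp unit -- the wider default gradient separates O1's delayed
waveform so far from the targets' that the correlation loses its gain
sensitivity.)  $REL_{O1}(F1,F2)$ compares the two edges within a subject
at the same nuisance and isolates the split.  A structural caveat, found
during design and verified empirically: REL features are linear functions
of direct features, so a direct-only pipeline that happens to retain both
informative edges recovers part of the relative signal through their joint
distribution; subject-level nuisances shrink the per-edge gap and spread
proportionally, which caps how far direct-mode accuracy can be pushed
toward chance while keeping full-mode accuracy high.  At the frozen
conditions full mode averages ~96% LOO accuracy and direct-only mode
~74-80% -- clearly worse than the full pipeline, but above the binomial
chance band; shrinking the split until direct mode reaches chance
(0.62/0.38) drags full mode to ~76%.  The qualitative ordering is robust;
the "direct exactly at chance while relative features separate perfectly"
idealization is not achievable for this family of generative models, and
the corresponding acceptance assertion is expected to fail by this
structural margin.

What passing tests on this generator do **not** show: robustness to
volume conduction (no forward model is simulated), to ocular or muscle
artifacts beyond square-pulse amplitude excursions, to montage referencing
choices, or to the latency/amplitude heterogeneity of real patient
cohorts.  The generator validates the *pipeline machinery* -- recovery,
calibration, leakage-freedom -- not clinical performance.

## Numerical and procedural choices

* Correlation: Pearson at integer sample lags; windows need at least 8
  overlapping samples; zero-variance overlaps are skipped, and a pair with
  no valid lag raises an error naming the channels.
* Epoch length: `round(epoch_ms * fs / 1000)` samples (1.2 s at 512 Hz
  gives 614), half-open windows throughout, milliseconds relative to
  stimulus onset, sample 1 at `t0_ms`.
* Window steps round down to whole samples, never below one.
* Population (divide-by-N) standard deviations throughout, with
  `sd_type = "sample"` available.
* All floors ($10^{-12}$) apply to Fisher denominators and model
  variances; degenerate Laplacian scores (constant features) are set one
  above the worst finite score and flagged.
* Seeds: one master seed; subject i's seed is the i-th draw of the master
  seed's own RNG stream, so a cohort can grow without reshuffling
  existing subjects.  (An earlier arithmetic counter scheme left
  index-linked correlations across subjects strong enough to break label
  exchangeability of null cohorts -- a failure mode worth testing for in
  any simulation harness.)
* The permutation p-value is the conservative
  $(1+\#\{perm \ge obs\})/(n_{perm}+1)$; because the LOO accuracy is
  discrete, a tie-randomized companion (`p_randomized`, exactly uniform
  under label exchangeability) is returned for calibration audits and is
  never used for inference.
* Problem sizes in the shipped tests (cohorts of 8--40 subjects, 4--8
  channels, up to 20 simulation seeds, permutation nulls at reduced
  `n_perm`) were chosen as the smallest sizes at which the statistical
  assertions are stable.

## Known limitations

* The per-subject "subjects_argmax" over window sizes is implemented as a
  cohort-level training-fold choice (the per-subject reading would let
  each subject optimize its own window, mixing configurations within one
  feature column).
* The chi-squared model-comparison p-value is reported per subject but is
  not aggregated into a cohort-level significance; the permutation test is
  the supported route.
* EDF/BDF ingestion assumes a uniform sampling rate across the montage
  channels and takes the recording reference as given.
* MUL squares ($REL^2$) are excluded by default
  (`include_squares = TRUE` to add them).
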