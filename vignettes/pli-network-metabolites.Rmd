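---
title: "Phase-lag-index brain networks and metabolite associations: methods"
author: "plinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index brain networks and metabolite associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plinet)
```

## The analysis in one paragraph

`plinet` implements a resting-state EEG connectome analysis for two-group
designs (for example, subclinically depressed vs healthy participants),
together with an untargeted-metabolomics screening stage and a stage that
correlates the two. Raw multichannel EEG is filtered, segmented, spatially
filtered and reduced to a phase lag index (PLI) matrix over the 20
canonical 10-20 electrodes per frequency band; proportional sparsity
thresholding turns each matrix into 36 binary graphs, on which four global
graph metrics are evaluated; group differences are tested level-by-level
with pooled *t*-tests under Benjamini-Hochberg FDR and summarised by
averaging over the significant levels; connectivity differences are also
tested edge-wise by a permutation network-based statistic (NBS).
Metabolite intensities are screened by PLS-DA variable importance in
projection (VIP > 1) combined with a univariate *t*-test (p < 0.05), and
the selected features (plus depression scores) are rank-correlated against
the topology metrics across the whole sparsity grid to locate the sparsity
of maximum correlation. Because real recordings of this kind are rarely
shareable, the package ships a synthetic-cohort generator with fully known
ground truth; every claim the test suite makes is a claim about recovering
that ground truth.

## Preprocessing

The fixed pipeline order is: broadband band-pass (0.5-45 Hz) with a 50 Hz
notch -> band-pass to the analysis band -> segmentation into 2-s epochs ->
common average reference -> downsampling to 512 Hz -> rejection of any
epoch exceeding +/-80 uV on any channel -> Hjorth nearest-neighbour
surface Laplacian. Every step appends to the epoch set's provenance log.

Filters are Hamming-window FIR designs with transition widths of 25% of
each band edge (floored at 0.2 Hz) and an order cap of 4096 taps, applied
by FFT convolution with exact integer group-delay compensation, so the net
response is zero-phase. Zero-phase filtering matters here: any residual
phase response would bias the phase-difference statistics that the PLI is
built from. The stop-band reaches more than 30 dB one octave beyond the
band edges (verified spectrally in the tests).

Band edges are not universal constants; the package uses the common
clinical split delta 0.5-4, theta 4-8, alpha-1 8-10, alpha-2 10-13,
beta-1 13-20, beta-2 20-30 and gamma 30-45 Hz — seven bands, matching the
seven connectivity matrices the design calls for. All constants live in
`run_config()` and can be changed there.

Independent-component artifact removal is deliberately absent: it is a
visual, operator-dependent step that cannot be reproduced algorithmically.
Amplitude rejection is the only artifact screen, and the per-subject
epoch-retention counts are recorded in the run log so attrition is always
explicit.

## Phase lag index

For band-limited signals the instantaneous phase is the argument of the
analytic signal (FFT Hilbert transform). For two phase series the PLI is

$$\mathrm{PLI} = \left| \left\langle \operatorname{sign}
  \sin\big(\Delta\phi(t)\big) \right\rangle \right| \in [0, 1],$$

the asymmetry of the phase-difference distribution around zero. A
consistently lagged pair scores 1, an inconsistent or zero-lag
(volume-conducted) pair scores 0; `sign(0)` contributes 0 exactly. Only
1:1 phase locking is considered.

PLI is computed per epoch and averaged across epochs (one standard
convention; whether one should average epochs or concatenate samples is
genuinely open, and the epoch-averaged variant is what the rest of the
package consumes). The first and last 10% of samples in each epoch are
discarded before the sign count to suppress Hilbert edge transients.

A consequence of per-epoch averaging worth knowing: with $n$ effectively
independent phase samples per epoch, the absolute value inside the average
gives independent channel pairs an expected PLI near
$\sqrt{2/(\pi n)}$ rather than 0 (about 0.17 for a 2-s beta-1 epoch).
This noise floor is a property of the estimator, not a bug; real planted
couplings must clear it, and the synthetic generator is designed so that
they do.

## Binary graphs and topology metrics

Each weighted PLI matrix is thresholded proportionally: sparsity $S$
keeps the $\operatorname{round}(S \cdot N(N-1)/2)$ strongest edges
(round-half-up; ties broken by lexicographic node-pair order so results
are deterministic). The default grid is $S = 0.05, 0.06, \dots, 0.40$ —
exactly 36 binary graphs per subject and band. Proportional thresholding
is used because indexing networks by $S$ only fixes the edge count under
the proportional reading; an absolute-threshold mode
(`mode = "absolute"`) is available for completeness.

On each binary graph four global metrics are computed from scratch
(breadth-first hop distances via boolean matrix powers):

- characteristic path length $L_p$: mean hop distance over connected
  ordered pairs; if the graph is fragmented the mean runs over connected
  pairs only and the result is flagged;
- clustering coefficient $C_c$: mean over nodes of
  $2t_i / k_i(k_i - 1)$, with nodes of degree < 2 contributing 0;
- global efficiency $E_{global}$: mean inverse distance with
  $1/\infty = 0$;
- local efficiency $E_{local}$: mean over nodes of the global efficiency
  of the subgraph induced on each node's neighbours.

These conventions (connected-pairs $L_p$ + fragmentation flag,
$1/\infty = 0$, degree guards) follow standard connectome-toolbox
behaviour. One subtlety the property tests document: with the
connected-pairs convention, adding an edge that merges two components can
*increase* $L_p$, so the familiar "edges never lengthen paths" intuition
only holds for connected graphs. The implementation is verified to
1e-12 against an independent brute-force Floyd-Warshall oracle and
against igraph.

## Group statistics

At every sparsity level the two groups are compared with a two-sided
pooled-variance *t*-test ($df = n_1 + n_2 - 2$). The FDR family is the 36
sparsity levels within one band x metric — the narrowest defensible
family; it is a configuration choice, not a constant of nature. Effect
sizes use the equal-n conversion $d = 2|t|/\sqrt{df}$, which is the form
that round-trips the printed effect sizes of published two-group topology
comparisons at this df; the pooled-SD $d$ from raw samples is also
exported (`cohens_d_pooled()`) and is the better choice for clearly
unequal groups. Subjects' metrics are then averaged over the significant
levels and the test is re-run on the averages — the "averaged over
significant thresholds" summary.

The NBS reimplementation tests connectivity edge-wise: pooled *t* per
edge, suprathreshold graph at $|t| > t_{primary}$ (default 2.0,
configurable), connected components scored by edge count, and a
group-label permutation null of the maximum component size. Component
p-values use the add-one estimator $(1 + \#\{\text{perm} \ge
\text{obs}\})/(1 + n_{perm})$, so p = 0 is impossible. A practical note
from the null calibration: at $t_{primary} = 2$ with ~190 edges the
suprathreshold noise graph sits near the critical regime for component
merging, so planted components are detected more cleanly at a stricter
primary threshold (e.g. 3); the false-positive rate is controlled either
way. A Wilcoxon rank-sum utility (`wilcoxon_ind()`) covers demographic
comparisons.

## Metabolite screening

Intensities are log10-transformed and unit-variance scaled (the
originating software's convention is undisclosed; both choices are
configurable), then a PLS-DA model is fitted by NIPALS with deterministic
initialisation from the y-covariance direction and X-deflation. VIP for
feature $j$ is

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a \mathrm{SSY}_a
  (w_{aj}/\lVert w_a \rVert)^2}{\sum_a \mathrm{SSY}_a}},$$

whose mean square over features is exactly 1 — an algebraic identity the
tests assert to 1e-8. The published workflow used OPLS-DA but reported
only first-component VIP; plain PLS-DA VIP is the transparent, testable
equivalent, and a single orthogonal-signal-correction pass is available
behind `osc = TRUE` for users who want the OPLS-style filtering.
Selection combines VIP > 1 with the *raw* univariate p < 0.05 (that is
the stated screening rule), while the BH-adjusted p is reported alongside;
fold changes are ratios of raw (unlogged) group means, with FC > 1
meaning up-regulation in the case group. Whether the univariate *t*-tests
should run on raw or log intensities is unstated in the source design;
the default here is log10 (variance-stabilising for log-normal data), and
`log_transform = FALSE` restores the raw-scale behaviour.

## Correlation scan

Spearman correlations (average ranks for ties; exact null for n <= 10
without ties, *t* approximation otherwise) link each selected metabolite,
and the depression scores, to each topology metric at every sparsity
level. The level of maximum |rho| is recorded per feature x band x
metric — the "highest-correlation sparsity". Because 36 correlated levels
are scanned, a max-statistic permutation p across the scan is emitted
next to the per-level raw p. A threshold-averaged variant and a
pathway-level variant (first principal-component score of the member
features, an explicit interpretation rather than a published formula) are
also provided. Conflicting published attributions of such correlations to
neighbouring beta sub-bands are not adjudicated: the scan simply computes
every band x metric slice. Where one metric is a strictly decreasing
function of another across subjects (as $L_p$ and $E_{global}$ often
nearly are), their correlations with any feature mirror in sign exactly —
a rank-algebra fact the tests assert on constructed fixtures.

## The synthetic cohort: what it emulates and what it does not

The generator's purpose is verifiability: every downstream stage must be
checkable against ground truth. Three design choices matter.

**Phase-jitter instead of per-sample sign flips.** A pair's coupling
consistency is parameterised by $q \in [0, 0.5]$ with ground-truth
PLI $|1 - 2q|$. The naive construction — flip the sign of the lag
independently at every sample with probability $q$ — is unrecoverable by
any analytic-signal method: the analytic signal of
$\mathrm{Re}\,(z e^{-iL\sigma_t})$ with i.i.d. $\sigma_t$ is
$z(\cos L - i(1-2q)\sin L)$ plus broadband noise, i.e. the estimator sees
a constant effective lag and converges far from $|1-2q|$. Instead the
second channel's phase is offset by $L + W(t)$ where $W$ is a smooth
(low-pass, cutoff well below the carrier) stationary Gaussian process
whose scale is calibrated — including phase wrap-around — so that
$\operatorname{sign} \sin \Delta\phi$ is inverted exactly a fraction $q$
of the time. The target $|1 - 2q|$ is unchanged, and the estimator can
attain it: on 60-s pairs the recovered PLI sits within 0.005 of target.

**Intermittent, slot-scheduled couplings.** Coupled pairs share a
band-limited oscillator. If every pair on a channel were active at once,
each pair's shared power fraction would be at most 1/degree, and phase
mixing would crush the expressed PLI toward the noise floor. Couplings
are therefore intermittent: a proper edge colouring assigns the pairs at
each channel to different 2-s activation windows (4 rotating slots by
default), so an active pair enjoys nearly full shared power. Intermittent
coupling is also the more realistic choice — empirical phase coupling
waxes and wanes. The expressed PLI of a planted pair is then roughly
(duty cycle) x (active PLI) + (1 - duty cycle) x (noise floor), about
0.32 versus a 0.17 floor under the defaults — comfortably separable with
20 epochs.

**A fixed backbone plus a rewired variable tier.** Each subject's coupled
subnetwork is a ring lattice over the 20 electrodes: the nearest-neighbour
cycle (20 edges) is a backbone common to all subjects; the second-
neighbour ring (20 edges) is rewired to random long-range pairs with a
per-subject probability $c$ drawn from a group-specific Beta distribution
(depressed-like group centred near 0.7, controls near 0.15). Rewiring
randomises the network — shorter paths, higher global efficiency, lower
clustering — which is exactly the topology shift the analysis is meant to
detect; and because proportional thresholding fixes the edge count, a
*spatial* reorganisation (not a mere strength change) is the only honest
way to plant a binary-topology difference. Splitting backbone from
variable tier localises the between-subject signal: below the
backbone-fill sparsity (20/190 ~ 0.105) subjects are identical and
correlations vanish; the full planted structure is expressed at the
lattice-fill sparsity (40/190 ~ 0.21), which is where the
metabolite-topology correlation peaks by construction.

The metabolite table is log-normal (positive, right-skewed, as in LC-MS
practice) with five features shifted by one natural-log unit in the case
group; one feature is rank-linked, through a Gaussian copula calibrated
to a target Spearman rho of 0.7, to the subject's *true* planted-network
global efficiency; depression-like scores increase monotonically with the
rewiring probability. The defaults mirror the recruitment scale of the
motivating design: cohorts of `n_group_a = 40` and `n_group_b = 38`
subjects, 60-s recordings at 1024 Hz, oscillator amplitude 8 uV against
1.6 uV channel noise, and sign-inconsistency q ~ 0.02-0.04 per coupled
pair; see `?synth_cohort_spec` for the full list.

What the generator does **not** emulate: 1/f background spectra, volume
conduction and realistic forward models, ocular/cardiac/muscle artifacts,
electrode noise heterogeneity, and LC-MS batch effects or missingness.
Passing tests therefore demonstrate that the chain of estimators recovers
known structure through the full pipeline — not that the pipeline is
robust to every pathology of real recordings.

## Numerical choices, in one place

- FIR: Hamming window, transition 25% of band edge (floor 0.2 Hz), order
  cap 4096, zero-phase by integer delay compensation.
- Decimation: low-pass at 0.8 x target Nyquist, integer ratios only.
- PLI: per-epoch estimates averaged; 10% epoch-edge trim; `sign(0) = 0`.
- Binarization: round-half-up edge count; lexicographic tie-break.
- Metrics: `1/Inf = 0`; degree < 2 contributes 0 to $C_c$ and
  $E_{local}$; fragmented $L_p$ averages connected pairs and flags.
- FDR family: 36 sparsity levels within band x metric.
- Permutation p: add-one estimator, everywhere.
- Spearman: exact p for n <= 10 without ties, else *t* approximation.
- PLS-DA: deterministic NIPALS; constant features scale to zero and are
  flagged rather than dropped.

## Problem sizes used by the test suite

The validation suite runs 20 seeded end-to-end cohorts of 13 + 13
subjects with 40-s recordings at 512 Hz (beta-1 band), 200-run null
calibrations on 24 matrix-level subjects, 200 random graphs for the
metric oracle, and 20-seed metabolite screens at 20 + 20 samples with 50
features. These sizes are the package's choice of a demonstration scale:
large enough that the planted effects dominate sampling noise (the
end-to-end effect sizes are d ~ 1.5-2), small enough to run routinely.
The same computations at the full published scale (around 40 + 38
subjects, 60-s recordings) only gain power.

## Known limitations

- Only the 20-channel canonical montage is bundled; other montages work
  but need a user-supplied neighbour table for the Laplacian.
- EDF reading is not implemented; recordings exchange as delimited
  matrices with a YAML sidecar (sampling rate, channel order, optional
  per-channel gain).
- The n:m phase-synchronization generalisation is fixed at 1:1.
- Weighted-graph metrics, small-world indices and nodal statistics are
  out of scope; the four global metrics above are the analysis surface.
- The per-epoch PLI noise floor means very short recordings (< ~10
  epochs) make weak couplings indistinguishable from noise; the epoch
  count is the main power lever for connectivity estimates.
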