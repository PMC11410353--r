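---
title: "Models and methods behind oddwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oddwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oddwave` implements the full computational chain of a passive auditory
oddball experiment on the mismatch negativity (MMN): constrained trial
sequence generation, a hierarchical generative model for epoched EEG,
the standard epoch-level preprocessing rules, identity-MMN difference
waves, a spatiotemporal cluster-based permutation test built from
scratch, and simulation-based power analysis. This vignette explains
the models, the tunable parameters, and the numerical and design
choices; the README shows a worked end-to-end example.

## The oddball design

A session consists of 18 blocks, three repetitions of six block types:
two tense conditions (irregular past- vs present-tense verbs as
deviants), two voicing conditions (voiced vs voiceless consonants in an
[_a] frame), and two voice-onset-time (VOT) conditions (aspirated vs
unaspirated syllables). Each block opens with 16 habituation standards,
followed by a pseudorandom segment in which every one of 40 deviants is
preceded by an unbroken run of 4 to 9 standards (271 pseudorandom
standards in total), and closes with a single standard: 328 trials per
block, 5,904 per session. Inter-trial intervals are uniform integers in
900 to 1,100 ms, offset to onset. Block order is drawn uniformly from
the permutations with no block type occurring twice in a row, by
rejection sampling.

The run lengths are the design's only nontrivial random structure:
40 integers in [4, 9] that must sum to 271. `sample_run_lengths()`
draws uniformly over *all* bounded compositions by sequential
conditional sampling, where the probability of giving run $i$ length
$v$ is proportional to the exact number of ways the remaining runs can
absorb the remaining total. Those counts come from a dynamic program
over (runs left, total left); the uniformity is testable and the tests
compare sampled frequencies against exhaustive enumeration on small
instances. Token choice is i.i.d. uniform within each role's inventory
(the runtime behaviour of the original experiment script, which
produces "similar" rather than exactly balanced token frequencies), and
every randomised stage draws from a named substream of one master seed
via `derive_seed()`, so plans are bit-reproducible.

Two readings of the printed design required a decision. First, the
block arithmetic only adds up as 16 habituation + 271 pseudorandom
standards + 40 deviants + 1 final standard = 328; we adopt that
reading, which also reproduces the 5,904-trial session. Second,
habituation standards do not count towards the first deviant's 4-9
run: the habituation trials form their own segment, and the
pseudorandom segment alone satisfies the run constraint.

## The generative model for epochs

`simulate_participant_epochs()` implements a two-level hierarchy in
microvolts:

* a participant-level identity-MMN effect per contrast,
  $\beta_{p} \sim \mathcal{N}(\mu_{\text{subj}}, \sigma_{\text{subj}}^2)$,
  with defaults $\mu_{\text{subj}} = -0.84$ and
  $\sigma_{\text{subj}} = 2.28$, the reference mean and
  between-participant SD of the MMN at Cz over 200-400 ms;
* single-trial noise, i.i.d. Gaussian with SD $\sigma_{\text{trial}}$
  at every channel and sample, white in time and space.

Deviant epochs receive $\beta_p$ multiplied by an *effect kernel*: a
spatial topography with weight 1 at the peak channel (Cz by default)
and Gaussian falloff over the schematic layout, times a unit-peak
temporal window over 200-400 ms (raised cosine by default; a boxcar is
available, for which the plain 200-400 ms window mean recovers
$\beta_p$ exactly). Epochs span the half-open window [-150, 750) ms at
1000 Hz - 900 samples, onset at sample 151 - which resolves an
off-by-one the printed epoch limits leave open. Artifact trials occur
with probability `artifact_rate` and add a 100-ms square pulse of
$\pm$ `artifact_amplitude` on one random scalp channel inside -150 to
600 ms. Trial metadata carries the ground truth (drawn effect,
artifact flag), which is what makes parameter-recovery tests exact.

$\sigma_{\text{trial}}$ deliberately has **no default**: no reference
value for it is printed anywhere in the source material, so the
configuration must state it. The examples use 10 µV per sample. That
number must be read against the whiteness assumption: real EEG
concentrates its power below ~20 Hz and is strongly autocorrelated, so
a realistic 20-40 µV RMS signal rarely crosses a 75 µV peak threshold.
White noise at 1000 Hz crosses far more often - at
$\sigma_{\text{trial}} = 20$ µV the threshold sits at 3.75 SD and a
~50,000-cell scan window would reject essentially every clean trial.
With $\sigma_{\text{trial}} = 10$ µV the artifact rejector separates
injected pulses from clean trials essentially perfectly, which is the
regime the rejection tests use. Spatially or temporally correlated
noise is a deliberate non-goal: white noise is the minimal structure
consistent with the variance components the power analysis uses, and
anything richer (1/f background, ocular morphology, drift, line noise)
is out of scope, so passing tests say nothing about artifact *shape*
classification on real recordings - only about the amplitude rule.

`simulate_diff_stack()` is the ERP-level shortcut used by calibration
studies: it draws each participant's difference wave directly as
kernel x effect plus white residual noise (`sigma_resid`, the noise
left after trial averaging), matching the full pipeline in
distribution at a small fraction of the cost.

## Preprocessing

The driver enforces the canonical order: optional bad-channel
interpolation, re-referencing to the mastoid mean, whole-epoch
demeaning, a logged no-op where ICA ocular-component removal would sit
(simulated data carry no ocular components), 100-ms pre-stimulus
baseline correction, amplitude rejection, and a 30 Hz zero-phase
low-pass. Reordering requires an explicit override and is logged.
Notable decisions:

* **Rejection** removes a trial iff any *scalp* channel exceeds 75 µV
  in absolute amplitude anywhere in the closed window [-150, 600] ms;
  reference channels are never consulted. The threshold is strict
  (exactly 75.0 survives).
* **Filtering** uses a Hamming-windowed sinc FIR with transition
  bandwidth `min(max(f_c/4, 2), f_c)` Hz (7.5 Hz at 30 Hz), order
  `3.3/(tb/fs)` rounded to even (440 at 1000 Hz), and -6 dB point at
  `f_c + tb/2`; the symmetric impulse response applied centred is
  exactly zero-phase. Epochs are short relative to the filter, so each
  signal is reflect-padded by one filter length. The designed
  response gives ~72 dB attenuation at 60 Hz and <0.02 dB passband
  ripple; both are logged per run. Because the FIR is linear and
  identical for every epoch, it commutes with trial averaging;
  `run_pipeline()` therefore filters the averaged ERPs (the tests
  prove the equality to machine precision), while `lowpass_filter()`
  remains available for per-epoch filtering.
* **Interpolation** replaces each bad channel (at most three) by the
  inverse-distance-weighted mean of its good neighbours. Spherical
  splines would be the richer choice on real geometry; the neighbour
  average is exactly testable on schematic layouts and is what the
  micro-layout examples pin down.
* All operations are pure (R copy semantics) and append their
  parameters to a provenance log carried by the epochs object.

## Identity MMN and trial exclusions

The identity MMN contrasts the same physical tokens across roles: the
ERP of a condition's deviant tokens *as deviants* minus the ERP of
those same tokens *as standards* in the mirror block type, which
removes acoustic confounds from the difference. `mark_analyzable()`
implements the pre-registered exclusions - habituation trials, the
first deviant of each block, and the standard immediately after every
deviant (which also removes the final standard) - leaving 39
analyzable deviants per block, hence 117 per condition across a
session's three repetitions, and 232 analyzable standards per block.
"First series of standards" is read as exactly the 16 habituation
trials, not additionally the first pseudorandom run; the flags are
explicit in the trial table, so the alternative reading is one line of
user code away. Participants enter the group analysis only with at
least 30 trials in every condition (the relaxed profile; the original
stricter profile uses 50; the signal-to-noise inclusion criterion of
the original pre-registration lives in a citation and is out of
scope).

## The cluster-based permutation test

`paired_t_map()` computes, at every (channel, sample) in the analysis
window, $t = \bar d / (s_d / \sqrt{n})$ over participants' difference
waves, df $= n - 1$. Zero-variance cells are degenerate inputs: all
zeros map to $t = 0$, zero variance around a nonzero mean to
$\pm\infty$; both warn, and infinite cells never enter clusters.

`extract_clusters()` follows the FieldTrip-style recipe, stated
explicitly because tools differ: (1) mask cells beyond the one-tailed
critical value at cluster-forming $p < 0.1$ (the lenient threshold
favours weak sustained effects over strong focal ones); (2) prune
*once, before clustering, per time slice*: a masked cell survives only
with at least `minnbchan = 2` masked spatial neighbours at the same
sample; (3) connected components under "spatial neighbours at the same
sample plus the same channel at lag-1 samples" (no wraparound),
computed by union-find; (4) cluster mass = sum of member t values
(maxsum). Pruning can leave singleton clusters whose supporters were
themselves pruned; that is a property of the one-pass rule, and the
brute-force oracle in the tests reproduces it cell for cell on every
mask of several small grids.

`permutation_test()` builds the null by randomly sign-flipping each
participant's difference wave - the standard realisation of
exchangeable paired condition labels for within-participant designs
(the permutation scheme is our inference; the source cites the method
without spelling it out) - recomputing the t map and the most extreme
cluster mass each iteration. Sign flips leave $\sum_p d_p^2$ invariant,
so each permutation costs one matrix product plus clustering. Cluster
p-values use $(r + 1)/(n_{\text{perm}} + 1)$, so the observed data
count as one permutation, p is never zero, and validity is guaranteed;
with 200 permutations the achievable p grid makes the test essentially
exact at $\alpha = 0.05$ (measured 0.0515 ± 0.005 over 2,000 null
simulations). The default tail is negative (the MMN direction);
two-sided mode thresholds each tail at $\alpha/2$ and doubles the
per-sign p.

One power property deserves a caution. With the reference effect
($\mu = -0.84$, $\sigma_{\text{subj}} = 2.28$, so $|d| = 0.368$) and
$n = 60$, the one-tailed noncentral-t power ceiling at
$\alpha = 0.05$ is $1 - F_{t'}(t_{0.95,59}; \delta = 0.368\sqrt{60})
= 0.880$, and the subject-level effect is a single component shared
across the cluster's support, so no mass statistic can exceed that
ceiling as trial noise shrinks. Measured detection rates of the
kernel-overlapping cluster sit at 0.85-0.88 accordingly; a ≥90%
detection expectation under these exact conditions is not attainable
by any paired test.

## Power analysis

`simulate_power_cell()` mirrors the design's nested structure at the
measurement level: per participant, the deviant-trial mean is
$\beta_p$ plus $\mathcal{N}(0, \sigma_{\text{trial}}^2 / n_d)$ noise
and the standard-trial mean is pure noise with
$n_s = n_d \times 85/15$ (the oddball ratio enters only through trial
counts; a 50:50 ratio with equal counts reproduces the classic paired
design), compared by a one-tailed paired t test at $\alpha = 0.05$.
Here $\sigma_{\text{trial}}$ is the SD of the *single-trial amplitude
measure* - the window-mean scale, not the per-sample scale of the
epoch simulator; white noise averaged over a $W$-sample window links
the two by $\sigma_{\text{measure}} \approx \sigma_{\text{sample}} /
\sqrt{W}$. The examples use 15 µV at this scale, chosen so that the
power gain from additional deviants flattens near 100 deviants per
condition, the qualitative shape the design was built around; with
that value the 60-participant, 120-deviant cell lands in the
high-70s percent, consistent with the design's intended operating
point. The trial-level variance components behind the original
analysis were imported from prior work and never printed, so printed
power figures are reproducible only in this qualitative sense - the
quantitative anchor is instead `analytic_power()`, the closed-form
noncentral-t benchmark that the simulation must match to Monte-Carlo
error in the $\sigma_{\text{trial}} \to 0$ limit (verified against an
independent quadrature oracle over the chi-square mixing
distribution). A `"reduced"` trial profile draws each participant's
deviant count uniformly between the 30-trial inclusion floor and the
nominal count, approximating (coarsely - the empirical trial-count
distribution is unknown) a sample where some participants barely
clear inclusion; it costs several points of power.

## Validation scale and limitations

The shipped studies use sizes chosen to exercise every code path at
meaningful precision: type-I calibration over 400 null datasets (12
channels x 50 samples x 15 participants, 200 permutations each),
detection over 100 datasets at $n = 60$, power cells at 2,000-4,000
simulations, exhaustive cluster-oracle sweeps over all masks of
three micro grids, and a full-pipeline recovery run of 60 simulated
participants (one block pair each, grid64, 5% artifacts) whose
grand-average matched-filter amplitude must land within
$3\sigma_{\text{subj}}/\sqrt{60}$ of $\mu_{\text{subj}}$.

Known limitations: white noise only (no 1/f, no ocular components, so
ICA is a logged no-op); schematic layout geometry rather than measured
electrode positions; inverse-distance interpolation rather than
spherical splines; data are born epoched (no continuous-recording
simulation, since every analysed rule operates on epochs); and power
for the cluster test itself is only available through the expensive
full-pipeline path - the headline power mode is the single-measure
paired t test, matching how the sample size was chosen.
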