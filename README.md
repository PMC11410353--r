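# oddwave

Simulation and analysis tools for passive auditory oddball experiments
on the **mismatch negativity (MMN)** — the negative-going ERP
deflection elicited by rare "deviant" sounds among frequent
"standards". The package is aimed at ERP researchers who want to
design, power, and validate an oddball study's entire computational
chain before (or without) collecting data: it generates the constrained
trial sequences an experiment script would present, simulates epoched
multichannel EEG with a known ground truth, applies the standard
epoch-level preprocessing rules, forms **identity-MMN (iMMN)**
difference waves — the ERP of the same physical tokens as deviants
minus as standards, which removes acoustic confounds — and tests them
with a from-scratch **spatiotemporal cluster-based permutation test**,
plus a simulation-based power analysis for the nested
participant-by-trial design.

## The statistics at the core

*Cluster test.* Per (channel, sample), a paired t statistic over
participants' difference waves, `t = mean(d) / (sd(d)/sqrt(n))`,
df = n − 1. Cells beyond the one-tailed cluster-forming threshold
(p < 0.1) are pruned unless at least `minnbchan = 2` spatial
neighbours at the same sample also pass, then grouped into
spatiotemporally connected clusters scored by their **mass**
(summed t). The null distribution of the most extreme mass comes from
random sign-flips of each participant's difference wave; each cluster
gets the Monte-Carlo p-value `(r + 1) / (n_perm + 1)`, never zero.

*Power.* Per participant, the deviant-minus-standard measure is
`beta_p + noise`, with `beta_p ~ N(mu_subj, sigma_subj^2)`
(defaults −0.84 and 2.28 µV — effect size d = −0.37) and trial noise
scaled by the 85:15 standard:deviant ratio; the one-tailed paired t
test at alpha = 0.05 defines power. In the zero-trial-noise limit the
closed form is `1 − F_nct(t_crit; df = n − 1, ncp = |d| sqrt(n))`
(`analytic_power()`), which the simulation must match to Monte-Carlo
error.

## Worked example

Generate a session plan, run the end-to-end pipeline on a small
simulated cohort, and test the group-level iMMN:

```r
library(oddwave)

plan <- mark_analyzable(build_session(2026, participant_id = "subj01"))
plan
#> <session_plan 'subj01'>: 18 blocks, 5904 trials (master seed 2026)
#>   block order: +asp past +asp -asp -voi present -asp +voi present ...

cfg <- pipeline_config(n_participants = 8, master_seed = 2026,
                       sigma_trial = 10, contrast = "vot",
                       layout = "grid12", kernel_peak = "E06",
                       blocks = "pair", artifact_rate = 0.05,
                       n_perm = 500)
rep <- run_pipeline(cfg)
rep
#> <pipeline_report>: 8 participants (8 included), 18 blocks planned each
#>   trials: 5904 planned/session, 5248 simulated total, 276 rejected
#>   contrast vot ('-asp' deviants): min cluster p = 0.01397206

head(summary(rep$cluster_result), 2)
#>  n_cells       mass sign t_min_ms t_max_ms          p
#>     1515 -4148.0673   -1      229      380 0.01397206
#>      115  -247.9137   -1      654      669 0.25748503
```

Every session has 18 blocks of 328 trials (16 habituation standards,
271 pseudorandom standards, 40 deviants each preceded by 4–9
standards, 1 final standard). The simulated unaspirated-deviant effect
(raised-cosine kernel over 200–400 ms, peak at `E06`) is recovered as
one large negative cluster spanning 229–380 ms with p ≈ 0.014 — the
`(r+1)/(n+1)` Monte-Carlo p of its mass against 500 sign-flip
permutations; the remaining small clusters are noise. 276 of 5,248
simulated trials were rejected by the 75 µV rule, matching the 5%
injected artifact rate.

Power for the published design point:

```r
analytic_power(0.3684, 60)            # zero-trial-noise ceiling
#> [1] 0.8801612
simulate_power_cell(60, 120, sim_params(sigma_trial = 15),
                    n_sims = 4000, seed = 1)
#> <power_cell>: n = 60, deviants = 120 -> power 0.762 (MC SE 0.007, 4000 sims)
```

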