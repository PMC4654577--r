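---
title: "Methods: stress, turns, and status in conversing triads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress, turns, and status in conversing triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadstress)
```

`triadstress` implements an analysis chain for instrumented triad
conversations: photoplethysmographic (PPG) stress extraction, speaking-turn
analytics, status-rank aggregation, and the endocrine statistics layer, plus
a synthetic-session generator that gives every stage a ground-truth test.
This vignette records the models, the parameter choices, and the numerical
decisions, in the order data flow through the pipeline.

## 1. The PPG signal model and beat detection

A thumb PPG waveform undulates once per heartbeat; its peak-to-peak
excursion tracks peripheral blood volume (TBV), which shrinks under
sympathetic arousal as blood is shunted away from the extremities. Two
per-beat quantities carry all downstream information: instantaneous pulse
rate (60 / interbeat interval, BPM) and peak-to-peak amplitude (beat peak
minus the following trough, arbitrary units).

The detector (`detect_beats()`) works in four steps: a 50 ms moving-average
smooth; baseline removal by a rolling median whose window (1.5 beat periods
at `min_bpm`) is long enough never to track individual pulses; an adaptive
threshold at 0.35 of the 95th percentile of the detrended signal, computed
in 10 s blocks so level shifts (stress reactivity, gain steps) neither
starve nor flood the detector; and a refractory rule keeping the larger of
any two candidate peaks closer than `60 / max_bpm` s. Defaults `min_bpm =
40`, `max_bpm = 180` cover seated adults; out-of-range rates are flagged
(`flag_oob`), never silently dropped, because a flagged beat is evidence
about signal quality. Peak and trough values are read from the *raw*
signal, so smoothing affects localization only; on noiseless synthetic
pulse trains the per-beat amplitudes equal a brute-force max/min scan of
each known cycle exactly (the test suite asserts `< 1e-9` on interior
beats; the first and last cycles are clipped by construction).

Raw amplitudes are uninterpretable — they depend on cuff tightness — so all
inference uses within-subject ratios (conversation/video,
speaking/listening). Every ratio is invariant to multiplying the whole
trace by any positive constant (tested at 1e-9), which is the formal
version of the cuff argument.

**Artifacts are inputs, not inferences.** Following the scoring practice
the pipeline models, severe perturbations are annotated by a human:
`excise` intervals drop their beats from all statistics; `step` breakpoints
multiply all later amplitudes by the ratio of mean amplitudes in the 20 s
windows before versus after the break. Excisions are applied before step
windows are formed, so an overlapping excision cannot contaminate the
correction ratio (the window width is a parameter; an empty window is an
error rather than a guess). Amplitudes, not raw samples, are corrected —
this keeps the correction exactly gain-consistent. On stationary data a
spurious breakpoint changes the post-break mean by less than twice the
standard error of the window mean, so correction is near-idempotent.

## 2. Turns, speaking, and listening

A speaking turn is a consistent utterance by one person lasting *more than*
`min_turn_s = 4` s (strict inequality; a 4.0 s utterance is not a turn),
allowing short pauses or interjections. "Short" is operationalized as
same-speaker gaps of at most `merge_gap_s = 2` s; merging happens before
thresholding, so 3 s + 1 s gap + 3 s becomes one 7 s turn. The 2 s default
is a documented parameter, not a claim: raising `min_turn_s` can only
shrink turn counts and floor time (a tested monotonicity), and merging is
independent of input order.

For a given subject, *speaking* is the union of their turns and *listening*
is the union of the other members' turns minus any overlap with their own —
overlapping speech is attributed to the subject's own speaking because
stress attribution follows own vocal effort. Silence belongs to neither
set; `speaking_listening_sets(include_silence = TRUE)` provides the
alternative reading in which silence counts as listening, but the default
follows the narrower definition (listening is *when others are speaking*).
All intervals are half-open `[start, end)` and a beat belongs to an
interval iff its peak time falls inside — an unambiguous convention that
makes disjoint-interval means exactly additive.

## 3. Status aggregation

Seven components each rank the three members 1–3 (within-component ties
share the better rank: 200, 200, 100 seconds rank 1, 1, 3). A pair is
*consistently differentiated* only when at least four of the seven
components strictly order it the same way; otherwise it ties. We read "at
least four" as operative even when the remaining components lean the other
way (4 wins vs 3 reversals still differentiates); the stricter reading —
four agreeing components *and* no reversals — is available via
`strict = TRUE`. With fewer than seven components available (missing
assays, reduced designs) the threshold is the configured fraction (default
4/7) of those available, rounded up.

Final ranks are `1 + (pairs lost) + 0.5 × (pairs tied)`, which yields
exactly the observed patterns — transitive `(1,2,3)`, top tie
`(1.5,1.5,3)`, bottom tie `(1,2.5,2.5)`, flat `(2,2,2)` — and guarantees a
rank sum of 6 for *any* pairwise outcome, cyclic ones included. Cyclic or
partially inconsistent patterns (not expected in practice, but possible)
are classed `unresolved` and fall back to the average-tie ranking of mean
component rank, flagged rather than failing: a pipeline that dies on an
odd triad is worse than one that labels it. Aggregation is equivariant
under member relabeling (tested over random permutations).

## 4. The statistics layer

**Transforms.** T (pg/mL) and AA (U/mL) are right-skewed and analyzed as
lnT and lnAA; C (µg/dL) is left raw. Changes are post − prior on the
analysis scales; "mean level" is the prior/post average, falling back to
the prior value (flagged) for a subject missing the post sample. One unit
note: T descriptives are sometimes printed as "pg/dL" in this literature
while the assay range is stated in pg/mL; the package treats all T values
as pg/mL, consistent with the assay.

**Diagonal-covariance multilevel models.** Triad membership makes ranks
non-independent (one member's rank 1 constrains the others), so
fixed effects are estimated under a marginal Gaussian model whose residual
covariance is diagonal with one free variance per repeated level — member
position within triad for the rank models, member × collection time for
the three-level analyte models. `fit_diagonal_mlm()` iterates weighted
least squares with closed-form variance updates to the exact (RE)ML fixed
point (convergence when the relative change drops below 1e-10; the
fixed point is verified against `nlme::gls` with `varIdent` weighting in
the tests). Estimation defaults to REML rather than ML: with a single
residual level REML reproduces ordinary least squares *exactly* —
estimates, SEs, t, and df — which is the natural correctness anchor for
the estimator, and it matches the convention of the mixed-model software
this analysis style comes from; ML remains available via `method = "ML"`
(its profiled variances divide by `n_g` rather than `n_g − h_g`). Singular
designs fail with the collinear columns named; non-convergence fails with
the iteration count.

**Fractional df.** t tests use a Satterthwaite approximation: for a
contrast `c`, `df = 2 (c'Vc)² / Σ_g [∂(c'Vc)/∂σ²_g]² · Var(σ̂²_g)` with
`Var(σ̂²_g) = 2σ⁴_g/ν_g`. In the single-level case this reduces to exactly
`n − p`. Fractional df will not agree with other software to the last
decimal — variance-estimator conventions differ — but the type-I error of
the null rank→lnAA model is calibrated (0.05 ± 0.02 over 1000 simulations
at 15 triads, asserted in the tests).

**Centering and simple slopes.** With `center = TRUE` all numeric
predictors are mean-centered before the design matrix is built, so
interaction products are products of centered variables. Interactions are
decomposed at moderator values of ±1 SD: the conditional slope is
`b₁ + b₃·m` with variance `V₁₁ + m²V₃₃ + 2mV₁₃` and Satterthwaite df on
the same contrast. This is algebraically a re-parameterization: re-centering
the moderator at +1 SD and refitting reproduces slope, SE, and df to
machine precision, and the tests assert agreement at 1e-6 over 50 random
datasets.

**Power.** Post-hoc power of the joint F test of a `k`-predictor
regression uses `f² = R²/(1−R²)`, `df₁ = k`, `df₂ = N − k − 1`, and
noncentrality `λ = f²·N`. The `λ = f²·N` convention is chosen because it
reproduces the canonical small-effect benchmark (R² = 0.09, N = 15, k = 3
→ power 0.12 after rounding); `convention = "error"` gives the `f²·df₂`
alternative. Power equals α at f² = 0, is strictly increasing in N and R²
until it saturates at 1, and matches a 20,000-replicate Monte-Carlo
rejection rate within 0.01 (the simulation fixes the design and scales the
coefficient vector so the exact noncentrality is hit, making the check
sharp rather than approximate).

## 5. The synthetic-session generator

The generator exists so that every stage of the pipeline can be tested
against known truth. Its defaults *are* the study conditions the package
targets: 10 non-competitive triads (study 1) plus 5 reward triads
(study 2), three men each, a 200 s relaxation video then a 600 s free
conversation, sampled at 100 Hz (adequate peak localization below 200 BPM
at modest file size).

**Waveforms.** Beats are laid down sequentially; each beat's rate and
amplitude follow the subject's state — video, listening, or speaking — with
log-normal per-beat jitter (interval sdlog 0.03, amplitude sdlog 0.05), and
the waveform is a beta-lobe template (fast upstroke, peak a quarter into
the cycle, slow decay) scaled per beat, plus slow baseline wander and white
noise. Pulse morphology is deliberately crude: peak-to-peak statistics do
not depend on it, and pretending otherwise would only slow the tests.

**Physiological calibration.** Reactivity parameters are set so the
quantities *measured through the full pipeline* — not the latent
parameters — center on the published group-level values. Three published
anchors pin each channel: the video pulse mean (77 BPM) and conversation
mean (84 BPM); the conversation TBV ratio (0.77) with ~73% of subjects
showing both faster pulse and lower TBV; and the per-study
speaking/listening means and direction rates (TBV 0.87/0.89 with 79%/87%
below 1; pulse 1.07/1.12 with 93%/87% above 1). Latent medians and
log-SDs are obtained from these by inverting the normal quantile relations
with two measurement-chain corrections estimated once from the generator
itself: the speaking-state mixture (speaking occupies roughly a third of
conversation time, so the conversation-level attenuation factor 0.78
yields a measured 0.77), and an attenuation of ~0.93 on measured log-ratios
from turn-boundary beats and the additive noise floor. Between-subject SDs
are therefore slightly different from what a naive quantile calculation on
the latent scale would give. The measured ratios also sit a few thousandths
closer to 1 than the latent factors because additive sensor noise is
amplitude-independent; this is a property of any real instrument chain and
is left in.

**Turns.** The floor alternates between speakers; the next speaker is
drawn with probability proportional to a softmax (temperature 1.5) of the
latent status scores, floored at a 0.12 share so even the lowest-status
member takes the floor occasionally, and turn durations are log-normal
(median 18 s, sdlog 0.5, minimum 5 s) with medians scaled by the speaker's
share — higher status holds the floor more often *and* longer. Inter-turn
silences are uniform 0.5–4 s. These choices keep per-speaker turn counts
inside the observed 3–13 range for a ~600 s conversation while giving a
dominant latent score the largest floor share essentially always. Each
turn is emitted as one or two utterances separated by a sub-threshold
pause, so turn building reconstructs the schedule exactly.

**Status components and measured rank.** Judge-type components rank the
latent order perturbed by Gaussian noise and *rounded to integers* —
judges work on a discrete scale, and without discreteness components could
never tie within themselves, making tied final ranks impossible. The
speaking-time and turn-count components rank the actual synthetic
schedule. Default judge noise 1.0 gives roughly one tied pair per nine —
somewhat below the observed ~18% rate, because the count-based components
almost never tie; pushing judge noise higher does not close the gap (the
tie rate plateaus) and would degrade judge–rank agreement, so the default
stays at the plateau. Hormones and rank-dependent reactivity are
conditioned on the *aggregated* rank, not the latent one, because the
published associations are with the measured hierarchy; this also means
the pipeline's fitted coefficients are centered on the programmed values
rather than attenuated by rank-measurement error.

**Saliva.** Prior/post pairs are bivariate normal on the analysis scales
with means 4.79 (lnT, +0.11 in study 2), 0.185 µg/dL (C), 4.38 (lnAA,
−0.63 in study 2); SDs 0.40, 0.08, 0.90; prior/post correlations 0.69,
0.77, 0.44; rank slopes 0.08, −0.03, +0.29 per rank unit. Back-transformed
values are truncated to the assay sensitivity ranges (T 1–600 pg/mL,
C 0.007–3 µg/dL, AA 1–2000 U/mL), so they are always positive. The lnT
level and study-2 offset were derived from the published per-study
prior/post means jointly with the raw-scale mean (≈134 pg/mL), which the
lognormal mean ties to both the level and the total spread. Within-triad
hormone covariance is not published; an optional triad-level random shift
exists (`triad_re_sd`) and defaults to 0. Structural missingness is
emulated: AA assays absent for the first five study-1 triads (the enzyme
joined the panel late) and one study-1 subject lacking the post sample.

**What the generator does not emulate.** Respiration and skin-conductance
channels, realistic pulse morphology (dicrotic notch), speech content,
diffuse status characteristics, seating position, and any coupling between
momentary physiology and the endocrine panel. Passing tests therefore
demonstrate that the *pipeline* recovers programmed effects under
realistic noise — not that the biological effects themselves would
replicate.

## 6. Problem sizes, seeds, determinism

A fixed seed makes every bundle bit-identical, down to the written CSVs;
per-triad seeds are derived from the study seed so triads are independent
replicates. Test problem sizes were chosen so Monte-Carlo error is small
against each tolerance: 90 triads (270 subjects) for the full-chain
reproduction block (SEs ≈ 0.5 BPM on pulse means, ≈ 0.01 on ratio means,
≈ 2–3 points on percentages), ~500 subjects for the hormone correlation
(SE ≈ 0.03), 500 triads per replicate for slope recovery with the bias
averaged over 20 replicates, 1000 replicates for type-I calibration, and
20,000 for the power Monte Carlo. The acceptance script uses 150 triads
for the signal metrics and a 3000-triad panel for the model coefficient,
trading a minute of compute for tighter confidence on the reported values.

## 7. Known limitations

- The beat detector assumes a single dominant positive lobe per cycle; it
  is not intended for severely motion-corrupted data without annotations,
  and it does no automatic artifact detection by design.
- Satterthwaite df use the asymptotic variance of the level variances;
  with very few observations per repeated level the df are rough (the
  type-I calibration bounds the practical consequence).
- The tie rate of the synthetic status components sits below the observed
  rate (see §5); analyses that stress tie handling should raise
  `judge_noise` deliberately.
- `run_pipeline()`'s per-study interaction models need enough complete
  cases per study; with very small synthetic studies individual model
  slots are `NULL` rather than estimates.
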