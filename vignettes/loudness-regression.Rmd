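---
title: "A central-tendency observer for 2AFC loudness judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A central-tendency observer for 2AFC loudness judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loudreg)
```

## The scientific problem

In 2AFC loudness discrimination, a probe tone (40–80 dB, 1 kHz, 300 ms) is
followed by a comparison tone drawn from a fixed set of levels around it
(method of constant stimuli), and the listener reports which was louder.
Fitted psychometric functions repeatedly show that the point of subjective
equality (PSE) is *not* the physical probe level: quiet probes are judged
louder than they are and loud probes quieter — a regression toward the mean
sound level. The effect strengthens when the probe is self-generated or its
onset is temporally cued, and it follows the session's sound statistics
when those are manipulated (an 80%-majority context). `loudreg` packages a
generative account of this pattern, the analysis used to measure it, and
the simulation machinery needed to show that the analysis recovers the
account's parameters.

## Generative model

The observer's remembered probe percept is a weighted average of the
stimulus and an internal anchor $\mu$:

$$\hat{L} = wL + (1-w)\mu,$$

while the comparison — presented immediately, never held in memory — is
perceived veridically up to noise. With independent Gaussian noise on the
two percepts ($\sigma_p$, $\sigma_c$) and lapse rate $\lambda$,

$$P(\text{"comparison louder"}) = \tfrac{\lambda}{2} + (1-\lambda)\,
\Phi\!\left(\frac{c - wL - (1-w)\mu}{\sqrt{\sigma_p^2+\sigma_c^2}}\right).$$

Three consequences drive every analysis in the package:

1. **PSE line.** The analytic PSE is $wL + (1-w)\mu$, so the deviation
   $\mathrm{PSE}-L = (1-w)(\mu-L)$ is linear in $L$ with slope $-(1-w)$.
   The per-subject OLS slope of deviation against probe level (the
   *adaptation index*) therefore identifies $w$ when the anchor is fixed.
2. **Condition effects are $w$ effects.** Self-generation and temporal
   cues are modelled purely as a lower $w$ (stronger anchor pull); the
   schedule metadata (cue onsets, inter-trial jitter) never enters the
   response model.
3. **Context effects are $\mu$ effects.** The anchor updates after every
   experienced tone (probe and comparison, in presentation order) as an
   exponential moving average $\mu' = (1-\alpha)\mu + \alpha\,\text{level}$.
   A majority context drags $\mu$ toward the context level, enhancing rare
   quiet probes in a loud context and attenuating rare loud probes in a
   quiet one.

Ties in the percept comparison have probability zero under continuous
noise; the simulator uses a strict inequality. All arithmetic stays on the
dB scale — levels, PSEs and deviations are reported in dB throughout, and
no conversion to linear pressure units is ever performed.

## Parameters, units, defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `w_by_condition` | stimulus weight per condition (dimensionless, [0,1]) | baseline 0.94; active/cued 0.88 | reproduces the ~2:1 slope ratio between self-generated/cued and passive-random conditions; the cued conditions share one value because the evidence favours no difference among them |
| `anchor_init_db` | initial anchor $\mu_0$ (dB) | 60 | everyday communication sound level, the long-term central tendency a listener brings into the lab |
| `anchor_lr` | EMA learning rate $\alpha$ per tone (dimensionless) | 0.005 | time constant of ~100 tones (~70 trials): fast enough that a 70-trial block skews the anchor measurably, slow enough that 350 majority trials are needed to re-centre it — the update window the context findings imply |
| `noise_probe_db`, `noise_comp_db` | percept noise SDs (dB) | 3, 3 | gives psychometric spreads of ~4 dB, typical of the fitted functions in this paradigm |
| `lapse` | stimulus-independent response rate (dimensionless, [0, 0.2]) | 0.02 | standard attentive-adult lapse allowance |

Cohorts draw per-subject parameters from truncated normal distributions
(default SD 0.03 on $w$); every subject's draw comes from an RNG stream
derived from (seed, subject id), so cohorts are reproducible and
order-independent. These defaults are a *stated world* for simulation and
recovery studies — they are plausible, not estimated from any dataset.

## What the synthetic cohorts emulate — and what they do not

The generators reproduce the designs exactly: 5 probe levels presented
block-wise in seeded random order, 7 comparison levels (±3 steps of 2 dB)
× 10 repetitions per 70-trial block (350 trials); cue timing metadata for
the continuous (bar-contact at 70 frames/60 Hz) and flashed (700 ms flash,
tone 700 ms later — the figure-caption convention; configurable) variants;
and the context sessions (70-trial baselines and adaptation, then 280/70
majority/minority test trials at 3 dB steps, passive lead-in phases and
self-generated test trials). Inter-trial jitter (500–3000 ms) is recorded
but unused: the model has no timing-dependent term.

They do **not** emulate: serial response dependencies beyond the anchor,
attention drift or fatigue, asymmetric adaptation to rising vs falling
levels, individual differences in noise or lapse (unless configured), or
any neural dynamics. A green qualitative-replication test therefore
establishes that the *pipeline* detects the patterns a central-tendency
observer produces at realistic sizes — not that human data contain them.

## Fitting and numerical conventions

* **Aggregation.** Responses are averaged per subject × probe ×
  comparison; the cumulative Gaussian $\Phi((c-\mathrm{PSE})/\sigma)$ is
  fitted to those proportions by nonlinear least squares (the paradigm's
  standard), with a Bernoulli maximum-likelihood option behind
  `method = "mle"` for robustness work. No lapse term is fitted — lapse
  exists only in the generative model; with symmetric lapse this leaves
  the PSE unbiased and mildly inflates $\sigma$.
* **Bounds.** PSE is constrained to probe ± 15 dB and $\sigma$ to
  [0.1, 30] dB; a solution on a bound is flagged non-converged rather than
  raising, and downstream analyses drop non-converged fits listwise (with
  a warning). Boundary proportions 0/1 are used as-is; least squares
  tolerates them.
* **Starts.** The optimizer (L-BFGS-B) starts from the interpolated 50%
  crossing with fallback starts to dodge the rare multimodal table; the
  test suite holds it to a dense grid-search oracle.
* **Exclusion.** A subject is excluded when responses at the two extreme
  comparison offsets (±3 steps — the only trials with a near-unambiguous
  correct answer) contradict the physical ordering on strictly more than
  25% of those trials, pooled over the session. The boundary case (exactly
  25%) is retained. Reading "loudest/quietest reference" as the extreme
  *comparison* levels per session is a design choice; the threshold is an
  argument for the per-block or probe-based alternatives.
* **Half-split.** With 5 blocks, blocks 1–2 count as the first half and
  4–5 as the second; the middle block is excluded, because the source
  procedure leaves its fate undefined. Subjects unclassifiable at a level
  contribute nothing for that level.
* **ANOVA.** The mixed within-between ANOVA uses the classical split-plot
  sums of squares with uncorrected df (no sphericity correction by
  default, matching how such designs are usually reported); both classical
  η² (SS effect / SS total) and partial η² are returned, since reported
  effect sizes in this literature are ambiguous between the two and the
  printed values here are only consistent with the classical flavour.
* **Bayes factor.** The two-sample JZS BF10 integrates the Cauchy
  (r = 0.707) effect-size prior via the normal-by-inverse-gamma mixture
  representation with adaptive quadrature at relative tolerance 1e-8,
  computed in likelihood-ratio form so the integrand stays O(1) even for
  large |t|. The tests verify it against an independent trapezoid
  integration of the non-central-t marginal.

## Design choices that were genuinely open

* **Anchor updating by both tones.** Each trial's probe *and* comparison
  are experienced sounds, so both update the anchor (in presentation
  order). Since comparisons are symmetric around the probe this leaves the
  anchor's expected trajectory unchanged and only doubles the effective
  update count per trial.
* **Comparison perceived veridically.** Only the probe is held in memory
  and temporally predicted, so only the probe percept takes the anchor
  pull. Pulling both tones would cancel the PSE shift entirely, which is
  incompatible with the phenomenon being modelled.
* **Flashed-cue timing.** The source material gives two tone onsets (flash
  + 300 ms in the text, + 700 ms in the figure); the package defaults to
  the caption convention and exposes `flashed_tone_offset_ms`. Nothing
  downstream consumes it.
* **Equal w across cued conditions.** The default sets active, continuous
  and flashed cue weights equal; the Bayes-factor analysis in the
  replication harness is exactly the tool for questioning that choice.
* **Config format.** Run configurations are JSON (a single nested
  key/value text file) since a YAML reader is not part of the package's
  dependency footprint.

## Known limitations

* The w = 0 limit is not recoverable by the fitted pipeline: with the PSE
  10–20 dB outside the sampled comparison range, the ±15 dB bound censors
  the fits and the group slope attenuates to ≈ −0.7 instead of −1. The
  recovery guarantee (±0.03 on the slope) holds on the realistic grid
  w ∈ [0.8, 0.95].
* The adaptation index identifies w only when the anchor is effectively
  fixed over the session (α ≈ 0); with learning, slope and α trade off and
  the index under-states 1 − w.
* The exclusion rule assumes extreme offsets are easy; with very large
  noise (σ ≳ 6 dB) honest observers approach the 25% error boundary.
* Inference functions assume balanced within-factors and complete cells;
  unbalanced data are rejected, not approximated.

Every empirical number quoted above (slope ratios, recovery error,
censoring attenuation) is computed by the test suite or the replication
harness — none is asserted from outside the package.
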