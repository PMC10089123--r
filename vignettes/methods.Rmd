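---
title: "Few-channel cross-subject motor-imagery decoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-channel cross-subject motor-imagery decoding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfbrcsp)
```

## The problem

Imagined left- versus right-hand movement modulates the power of
sensorimotor EEG rhythms (mu, ~8–12 Hz; beta, ~18–25 Hz) through
event-related desynchronization/synchronization (ERD/ERS). A practical
motor-imagery brain–computer interface wants to decode this from *few*
channels (here an 8-electrode sensorimotor montage: FC3, FCz, FC4, C3, Cz,
C4, CP3, CP4) and, ideally, for a *new* user without a long calibration
session. That forces two transfers at once: across frequency (which subband
carries the subject's reactive rhythm varies between people) and across
subjects (covariance structure differs between heads and sessions).

`vfbrcsp` implements a pipeline addressing both:

1. **Preprocessing** — zero-phase Butterworth band-pass 8–30 Hz (design
   order 6), optional cropping of the post-cue window, channel selection.
2. **Euclidean Alignment (EA)** — each subject's trials are whitened by the
   inverse principal square root of their mean trial covariance
   $\bar R = \frac{1}{N}\sum_i X_i X_i^\top / T$, so every subject's
   reference covariance becomes the identity and subjects become
   commensurate.
3. **Filter banks** — a constant filter bank (CFB: ten 4-Hz bands, 2-Hz
   overlap, 8–30 Hz) and a variable filter bank (VFB: same 2-Hz start grid,
   widths 5, 6, 7, 8, 9, 8, 7, 6, 5, 4 Hz), subband filters of design
   order 4.
4. **Regularized CSP** — per class, the covariance is a trial-count-weighted
   mixture of target and pooled-source class covariances
   ($\beta$) followed by shrinkage toward the average-eigenvalue identity
   ($\gamma$); spatial filters come from the generalized eigenproblem
   $C_1 w = \lambda (C_1 + C_2) w$; features are normalized log variances
   of the projections.
5. **Fisher-score subband selection** — per subband, the Fisher score
   $f_s = \mathrm{Tr}(S_B)/\mathrm{Tr}(S_W)$ of the spatial features; the
   selection criterion is the weighted square $\xi_n = w(n) f_{s,n}^2$ with
   $w(n) = n^{-a} + b$, and $(a, b)$ are chosen by grid search.
6. **Multi-task classifier** — one linear task per subject, coupled by a
   shared Gaussian prior $\mathcal N(\mu, \Sigma)$; the unseen target
   subject is classified with the prior mean $\mu$.
7. **Evaluation** — leave-one-subject-out (LOSO) over five variants
   (BP, RCSP, FBCSP, CFB-RCSP, VFB-RCSP), reporting percent accuracy and
   Cohen's kappa.

## The multi-task model, exactly as fitted

Each subject $s$ contributes a feature matrix $F_s$ (log-variance or band
power, plus a constant bias column) and labels $y_s \in \{\pm 1\}^{n_s}$.
The fitted objective is

$$
L(W, \mu, \Sigma) \;=\; \frac{1}{2\lambda}\sum_s \lVert F_s w_s - y_s\rVert^2
\;+\; \sum_s \tfrac{1}{2}\Big[(w_s-\mu)^\top \Sigma^{-1} (w_s-\mu)
\;+\; \log\det\Sigma\Big],
$$

the penalty being the Gaussian negative log-likelihood of each task weight
under the shared prior. With this scaling all three block updates are exact
minimizers in closed form:

* $w_s = \big(\tfrac{1}{\lambda}\Sigma F_s^\top F_s + I\big)^{-1}
  \big(\tfrac{1}{\lambda}\Sigma F_s^\top y_s + \mu\big)$,
* $\mu = \frac{1}{S}\sum_s w_s$,
* $\Sigma = \frac{1}{S}\sum_s (w_s-\mu)(w_s-\mu)^\top$ (divisor $S$, the
  maximum-likelihood estimate),

so the alternating fit is a coordinate descent and the objective is
non-increasing. Equivalent formulations in circulation scale the data term
as $1/\lambda$ and put an extra $\tfrac12$ on the log-determinant; those
scalings are mutually inconsistent with the closed-form $w_s$ update above,
and we keep the internally consistent probabilistic form so that the
printed update *is* the exact minimizer.

**Degeneracy and its floor.** The MAP problem above is degenerate: when
tasks agree, the weight scatter — and with it $\Sigma$ — collapses toward
singular and $L \to -\infty$ ($\log\det\Sigma$ diverges). We bound the
collapse by flooring the eigenvalues of the $\Sigma$ update at $10^{-8}$.
Flooring (rather than adding a ridge) matters: the eigenvalue-floored
scatter matrix is the *exact* minimizer of $L$ over the constrained set
$\{\Sigma \succeq 10^{-8} I\}$, so all three block updates remain exact
minimizers and the recorded objective is provably non-increasing (up to
floating-point rounding). The floor is far below any meaningful weight
difference (features and weights are $O(1)$), so its only effect is that
a collapsing fit settles cleanly at "all tasks share $\mu$" instead of
diverging.

Initialization is fixed ($\mu = 0$, $\Sigma = I$), so fits are
deterministic. Prediction for the unseen subject is
$\hat y = \mathrm{sign}(F_t\,\mu)$ with ties mapped to $+1$; a few-shot
mode (off by default) instead runs the $w$ update on declared calibration
trials.

## Regularized CSP and the leakage-free protocol

For class $k$,

$$
\hat C^k(\beta) = \frac{\beta N_l \bar C_t^k + (1-\beta) N_s \bar C_s^k}
                       {\beta N_l + (1-\beta) N_s},\qquad
\hat C^k(\beta,\gamma) = (1-\gamma)\,\hat C^k(\beta)
  + \gamma\,\frac{\mathrm{tr}\,\hat C^k(\beta)}{c}\, I .
$$

Per-trial covariances are trace-normalized before averaging (classic CSP
practice; it makes trials commensurate under amplitude drift), so every
class covariance has unit trace and the $\gamma$ shrinkage target — the
average-eigenvalue identity, our reading of the scaled-identity term, kept
as an explicit constant in the code — preserves the trace for every
$\gamma$.

The harness's default mode is *strict LOSO*: the target subject
contributes nothing to any fitted quantity, which forces $\beta = 0$
(there are no labeled target covariances to mix). A calibration mode
instead declares the first fraction of target trials (default 20% when
enabled) as labeled: they enter $\bar C_t^k$, join the classifier as an
extra task, and are excluded from testing. The audit log in every result
records, per fold, the source subjects, calibration and tested trial
indices, and the chosen $(\beta, \gamma, a, b)$ and bands, and the test
suite asserts the hygiene directly.

When $\beta$/$\gamma$ are not fixed by the user they are chosen per fold
by stratified 5-fold cross-validation on the *broadband* RCSP features of
the training subjects, over $\gamma \in \{0, 0.001, 0.01, 0.1\}$ (and
$\beta \in \{0, 0.1, \ldots, 0.9\}$ when calibration provides target
covariances), and the chosen values are reused for every subband. Running
the search once on the broadband rather than per subband keeps the inner
search $O(|\gamma|)$ instead of $O(|\gamma| \cdot N_{\text{bands}})$; the
cross-validated classifier is the closed-form single-task ridge form of
the weight update ($\mu = 0$, $\Sigma = I$), i.e. the same classifier
machinery at one task.

## Subband selection

$\xi_n = w(n) f_{s,n}^2$ ranks subbands, but $\xi$ values are not
comparable *across* $(a, b)$ — the weights only re-rank bands. The grid
search (defaults $a \in \{0, 0.5, 1, 1.5, 2\}$, $b \in \{0, 0.5, 1\}$)
therefore scores each cell's selected band set by inner-CV accuracy and
keeps the best, ties resolved toward the lexicographically smallest
$(a, b)$ and, within a ranking, toward the lowest band index. With
`k_bands = 1` (default, matching the singular "optimal subband" usage)
the winner is a single band; `k_bands > 1` concatenates features. Fold
assignment is deterministic (round-robin within class in trial order), so
selections are exactly reproducible.

## The synthetic cohort: what it emulates, and what it does not

`synthetic_config()` defines the verification conditions: 9 subjects,
72 trials per class, 8 channels at 250 Hz, 3-s epochs. Channels are an
instantaneous linear mixture of latent sources through
$A_s = A_0 (I + 0.3\, P_s)$, where $A_0$ is a fixed well-conditioned
matrix (condition number 3) and $P_s$ a seeded unit-spectral-norm
perturbation — the controllable inter-subject covariance shift that EA
removes exactly (post-EA, between-subject mean-covariance distances are
zero by construction).

The discriminative source models ERD/ERS as *partial* band-power
reactivity: a rhythm band-limited to 18–26 Hz (unit power, multiplied by
`effect_size = 3` for class $+1$) superimposed on *unmodulated* broadband
activity at the same source (spectral density 0.3 per Hz). The unmodulated
pedestal matters for identifiability: if the discriminative source were
purely band-limited, every analysis band overlapping it would see the same
class-variance ratio after spatial filtering, and the Fisher score of
log-variance features would then simply grow with bandwidth — the widest
overlapping band would always win, and the "planted band" would not be a
recoverable ground truth. With the pedestal, frequencies outside 18–26 Hz
dilute the class ratio, and the subband actually containing the rhythm is
the Fisher-optimal one. The remaining 7 sources are unmodulated white
background (power 1), and white sensor noise (sd 0.2) is added per
channel; both values chosen once as realistic (background activity
dominates any single source at the channel level) and not revisited.

Fully determined by `(seed, subject_index)`, the generator restores the
caller's RNG state. What it does **not** emulate: 1/f spectra, artifacts
(EOG/EMG), nonstationarity within a session, volume-conduction geometry,
class-dependent *spatial* shifts, or multi-session structure. Passing
tests on this cohort therefore demonstrate correctness of the machinery
and recoverability of planted structure — not expected accuracy on real
recordings.

## Numerical choices

* Zero-phase filtering: forward–backward IIR with odd-reflection padding
  of $3\times$ three filter lengths (well above 3× the order); subband
  designs are order 4 because narrow band-pass designs of higher order are
  numerically fragile at 250 Hz.
* Matrix inverse square roots via symmetric eigendecomposition with a
  relative eigenvalue floor of $10^{-10}$; covariances get a ridge only
  when numerically rank deficient (with a warning).
* Fisher denominator guarded by $\varepsilon = 10^{-12}$; log-variance and
  band-power features floored at $10^{-12}$ before the log.
* CSP filter signs fixed by making each filter's largest-magnitude entry
  positive, for determinism across eigensolvers.
* All tie rules are documented and deterministic: score 0 predicts $+1$;
  equal $\xi$ picks the lowest band; equal CV accuracy picks the smallest
  $(a, b)$ and the smallest $\gamma$.

## Problem sizes used in tests and the acceptance script

The verification suite runs the full study conditions where the claim
depends on them: the 9-subject default cohort for the end-to-end variant
comparison, and full default cohorts (selection pooled over all nine
subjects) for the 20-seed planted-band recovery study — subband
identifiability is a cohort-scale property, since the two widest VFB
bands overlapping the planted rhythm differ by only ~13% in population
Fisher score and small-sample selection is dominated by estimator noise.
Two studies are scaled down where the claim survives it: the null-effect
calibration uses 24 trials per class × 2-s epochs (chance level does not
depend on n; the interval widens accordingly), and the 20-seed EA-on
versus EA-off comparison uses 6 subjects × 30 trials per class × 2-s
epochs with the broadband RCSP variant and fixed gamma. The sizes are
stated here as the package's own choice of verification design.

Two statistical notes on the harness checks. First, LOSO trials within a
fold share one fitted model, so fold accuracies are not sums of
independent Bernoulli draws; the chance-level check therefore uses the
field-standard one-sample t-test of per-subject accuracies against 50%
rather than a pooled binomial interval. Second, planted-band recovery is
structurally capped below 100%: VFB band 5 (16--25 Hz) covers 7/8 of an
18--26 Hz rhythm with 9/8 the bandwidth of band 6, leaving the two bands'
population Fisher scores within ~13% of each other, and cohort-level
variability overturns that margin in a minority (~15%) of cohorts. The
frequency-decay weight $w(n)$ can only move selection toward lower bands,
so the grid search cannot recover band 6 when band 5's Fisher estimate
wins; measured recovery at the default conditions is ~85% over 20 seeds.

## Known limitations

* FBCSP here concatenates all subbands' features without
  mutual-information feature selection — a documented simplification of
  that baseline.
* Strict LOSO forces $\beta = 0$, so the covariance-mixing half of RCSP
  only engages in calibration mode.
* The multi-task prior treats tasks as exchangeable; there is no notion of
  subject similarity weighting.
* The GDF import path is an external-data adapter contract only
  (`import_gdf` documents it); no GDF parser ships with the package.
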