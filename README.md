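# vfbrcsp

Cross-subject decoding of two-class (left vs. right hand) motor-imagery EEG
from **few channels** — an 8-electrode sensorimotor montage (FC3, FCz, FC4,
C3, Cz, C4, CP3, CP4). Imagined movement modulates the power of the mu
(8–12 Hz) and beta (18–25 Hz) rhythms (ERD/ERS); which subband reacts, and
how the sources project onto the electrodes, differs between people. The
package implements a transfer-learning pipeline that handles both kinds of
variability and evaluates it subject-out, so every reported number is for
an *unseen* person.

## The method

For subjects $s = 1, \dots, S$ with epoched trials
$X_i \in \mathbb{R}^{c \times T}$ and labels $y_i \in \{\pm 1\}$:

1. **Band-pass** 8–30 Hz (zero-phase Butterworth, order 6) and optional
   cropping of the post-cue window.
2. **Euclidean Alignment** per subject: whiten every trial by
   $\bar R^{-1/2}$, where $\bar R = \frac{1}{N}\sum_i X_i X_i^\top / T$, so
   all subjects share the identity reference covariance.
3. **Filter bank**: constant (CFB, ten 4-Hz bands overlapping 2 Hz) or
   variable (VFB, widths 5, 6, 7, 8, 9, 8, 7, 6, 5, 4 Hz on the same 2-Hz
   start grid) subbands across 8–30 Hz.
4. **Regularized CSP** per subband: class covariances are mixed across
   target and source subjects and shrunk toward a scaled identity,
   $$\hat C^k(\beta) = \frac{\beta N_l \bar C_t^k + (1{-}\beta) N_s \bar C_s^k}
        {\beta N_l + (1{-}\beta) N_s}, \qquad
     \hat C^k(\beta, \gamma) = (1{-}\gamma)\hat C^k(\beta) +
        \gamma \tfrac{\mathrm{tr} \hat C^k(\beta)}{c} I,$$
   then spatial filters solve $C_1 w = \lambda (C_1 + C_2) w$ and trials
   become normalized log-variance features.
5. **Optimal-subband selection**: per subband the Fisher score
   $f_s = \mathrm{Tr}(S_B)/\mathrm{Tr}(S_W)$; the criterion
   $\xi_n = w(n) f_{s,n}^2$ with $w(n) = n^{-a} + b$ encodes the decay of
   EEG power with frequency, and $(a, b)$ are chosen by grid search with
   inner cross-validation.
6. **Multi-task classifier**: per-subject linear weights coupled by a
   shared Gaussian prior $\mathcal N(\mu, \Sigma)$, fit by alternating
   closed-form updates; the held-out subject is classified by
   $\mathrm{sign}(F_t \mu)$ — no target labels needed.
7. **Evaluation**: leave-one-subject-out accuracy (%) and Cohen's kappa for
   five variants — `BP` (band power), `RCSP` (broadband), `FBCSP` (all CFB
   subbands, plain CSP), `CFB-RCSP` and `VFB-RCSP` (subband selection).

A synthetic cohort generator with known ground truth (planted reactive
band, discriminative mixing column, controllable inter-subject covariance
shift) makes every stage verifiable offline; see the methods vignette
(`vignettes/methods.Rmd`) for the generative model and design decisions.

## Worked example

Nine synthetic subjects under the default study conditions (72 trials per
class, 8 channels, 250 Hz, 3-s epochs, a 3x class-variance effect planted
at 18–26 Hz, inter-subject mixing shift 0.3):

```r
library(vfbrcsp)

cohort <- generate_cohort(synthetic_config(seed = 42))
res <- run_variant(cohort, "VFB-RCSP")
res
#> <eval_result> VFB-RCSP, 9-fold leave-one-subject-out
#>  subject n_test accuracy kappa
#>    SYN01    144    83.33  0.67
#>    SYN02    144    81.94  0.64
#>    SYN03    144    81.94  0.64
#>    SYN04    144    77.78  0.56
#>    SYN05    144    84.03  0.68
#>    SYN06    144    77.08  0.54
#>    SYN07    144    77.08  0.54
#>    SYN08    144    79.17  0.58
#>    SYN09    144    86.81  0.74
#>   mean accuracy 81.02 +/- 3.44 %, mean kappa 0.62 +/- 0.07
```

Each row is one fold: the named subject was held out entirely, the
spatial filters, subband choice and classifier prior were fit on the other
eight, and the row reports how well the shared prior classified the unseen
subject's 144 trials. The band-power baseline on the same cohort reaches
66.98% (kappa 0.34), so the subband-selected, spatially filtered transfer
pipeline adds ~14 accuracy points here. The audit trail records what each
fold fitted:

```r
res$provenance$audit[[1]][c("gamma", "selected_bands", "band_edges")]
#> $gamma
#> [1] 0
#>
#> $selected_bands
#> [1] 6
#>
#> $band_edges
#>      low high
#> [1,]  18   26
```

Fold 1 recovered the planted 18–26 Hz band (VFB band 6).

## Command line

```sh
inst/cli/vfbrcsp bands VFB                 # print the band table
inst/cli/vfbrcsp simulate --out data/ --seed 7
inst/cli/vfbrcsp run --variant ALL --simulate --out results/
inst/cli/vfbrcsp align-check --simulate
```

`run` writes `results.csv` (per-subject accuracy/kappa, one column pair
per variant, plus the cohort mean) and `provenance.json` (selected bands,
regularization, audit trail per fold).

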