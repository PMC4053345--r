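# taprate

Respiratory rate (RR) from screen-tap intervals, with on-the-fly quality
control — plus the simulation, evaluation and optimization machinery needed
to study how well that works.

## The problem

The reference way to measure RR is counting breaths for a full 60 s. A
faster alternative: an observer taps a screen once per breath, and RR is
estimated from the inter-tap intervals — typically in well under 15 s. The
catch is bad taps: a missed breath doubles an interval, a double tap splits
one. `taprate` implements the estimator that deals with this, for anyone
evaluating rapid RR measurement methods (mHealth developers, clinical
researchers, device-specification work in resource-limited settings).

## The method

With tap timestamps $t_1 < t_2 < \dots$ and intervals $I_i = t_{i+1} - t_i$,
the current *set* is the window of the $z$ most recent intervals, with
median $\tilde I$ and consistency

$$C = 100 \cdot \max_i |I_i - \tilde I| / \tilde I \ (\%).$$

After each tap the set is evaluated; the first set with $C \le Th_C$ is
accepted and $\mathrm{RR} = 60/\tilde I$ breaths/min is reported. Efficiency
$E$ is the time from the first tap to the report; if nothing is accepted
within 60 s the measurement fails and is penalized with $E = 60$ s.
Evaluation uses NRMSE (RMS of per-observation relative errors, in %),
efficiency statistics ($E_{med}$, $E_{mean}$, $E_{95}$), completion rate,
and Bland–Altman agreement (bias ± 2 SD). The accuracy–efficiency trade-off
over the (z, Th_C) grid is resolved by minimizing
$J = 3.75 \cdot \mathrm{NRMSE} + E_{med} + E_{95}$ under 15-fold
cross-validation.

## Worked example

```r
library(taprate)

# an observer taps at 0, 1.5, 3.0, 4.5, 6.0 s
estimate_rr(c(0, 1.5, 3.0, 4.5, 6.0), z = 4, th_c = 13)
#> RR estimate: 40.0 breaths/min (z = 4, Th_C 13%)
#>   efficiency 6.0 s, 5 taps, set consistency 0.0%

# an early pair of outlier intervals (3 s, 4 s) keeps consistency above the
# threshold until the window has slid past them
estimate_rr(c(0, 1.0, 4.0, 5.0, 9.0, 10, 11, 12, 13), z = 4, th_c = 13)
#> RR estimate: 60.0 breaths/min (z = 4, Th_C 13%)
#>   efficiency 13.0 s, 9 taps, set consistency 0.0%

# a synthetic study: 30 observers x 10 reference rates (17-59 breaths/min)
study <- simulate_study(seed = 1)
cv <- crossvalidate(study, seed = 1)
cv
#> Cross-validated parameter selection (15 folds)
#>   selected: z = 3, Th_C = 27% (chosen in 14/15 folds)
#>   test sets, selected:   NRMSE 6.8 +/- 1.0%, mean E 7.3 +/- 0.6 s, E95 15.1 +/- 3.6 s, CR 100.0%
#>   test sets, z = 4 no Th_C: NRMSE 8.9 +/- 2.6%, mean E 8.0 +/- 0.3 s, E95 15.2 +/- 1.5 s, CR 100.0%
#>   paired t-test on per-fold NRMSE: t = -3.81, p = 0.0019 (significant at 0.05)
```

So on this synthetic study the consistency-filtered configuration reads out
in ~7 s on average — against the 60 s of conventional counting — with a ~7%
NRMSE, significantly better than tapping without the consistency test.
(Synthetic observers lack the autocorrelated errors of real ones, which is
why the selected set size can sit below the z = 4 typical of human data; see
the methods vignette.)

The sensitivity grid and its descriptive trends:

```r
grid <- replay_grid(study)          # z = 2..15 x Th_C = 2..30% (+ disabled)
regression_summary(grid)            # OLS trends of NRMSE and median E
plot(grid)                          # NRMSE vs threshold, one line per z
```

A command-line surface wraps the same functions (see
`inst/scripts/taprate.R`): `simulate`, `estimate`, `grid`, `optimize`,
`report`, reading/writing long-format CSV tap logs
(`subject_id,video_id,rr_ref,tap_time_s`) and JSON results.

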