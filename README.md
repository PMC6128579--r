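# cowsense

Two-stage recognition of dairy-cow behavior from leg-mounted sensor tags.

Automated behavior monitoring is a standard tool in precision livestock
farming: changes in how much a cow feeds, lies or walks are early
indicators of lameness, oestrus and metabolic disease. A leg tag that logs
1 Hz tri-axial acceleration can separate most behaviors, but it cannot
tell **feeding** from **standing** — both are "standing on four legs" as
seen from the leg. `cowsense` implements a two-stage ensemble classifier
that resolves this by adding radio-based position evidence:

1. **Multiclass AdaBoost over BP-network weak learners.** Fixed 6 s
   windows of acceleration are classified into seven behaviors (feeding,
   lying, standing, lying down, standing up, normal walking, active
   walking). Each boosting round trains a single-hidden-layer
   back-propagation network on a weighted resample and receives the
   SAMME-type coefficient

   ```
   alpha_l = 1/2 * ln((1 - err_l) / err_l) + ln(K - 1),   K = 7,
   ```

   with misclassified samples upweighted by `exp(alpha_l)`; prediction is
   the alpha-weighted vote `argmax_k sum_l alpha_l * I(G_l(p) = k)`.

2. **RSSI grid localization.** Per-second received signal strength from
   six barn sensors is converted to distances by the lognormal shadowing
   model, matched against a virtual grid of `(S-1)^2` vertices with the
   similarity score
   `E(D,H) = mean_i (1 - |d_i - h_i| / (|d_i - h_i| + u_i))`,
   and the position estimate is the centroid of the top-3 vertices. A
   fixed reference sensor supplies a relative ranging correction
   `d' = d * (1 + delta)`.

3. **Dempster-Shafer evidence fusion.** Windows first classified as
   feeding or standing are re-decided by combining the classifier verdict
   (mass 0.5 / 0.4 / 0.1 over {Feeding}, {Standing}, {Uncertainty}) with
   position evidence derived from the perpendicular distance of the leg
   to the feeding headlocks (0.9 of the mass split piecewise-linearly,
   peaking at one body length, 1.5 m). Dempster's rule combines the two
   masses; margin thresholds (eps1 = 0.2, eps2 = 0.03) decide feeding,
   standing, or abstention.

Because the original trial data are not deposited, the package ships a
seeded **synthetic barn simulator** (behavior schedules, per-behavior
acceleration motifs, behavior-consistent positions, shadowed RSSI) so the
whole pipeline — training, localization, fusion, evaluation — runs and is
tested end to end without external data, plus the trial's printed summary
tables as plain-text fixtures.

## Worked example

Recompute per-class performance from the packaged first-stage trial
confusion matrix (7212 test windows):

```r
library(cowsense)
cm <- trial_confusion_stage1()
round(t(sapply(behavior_levels(), function(cl) classwise_metrics(cm, cl))), 2)
#>                accuracy sensitivity precision
#> feeding            0.80        0.55      0.52
#> lying              0.92        0.82      0.95
#> standing           0.80        0.58      0.47
#> lying_down         0.99        0.86      0.83
#> standing_up        0.99        0.85      0.74
#> normal_walking     0.97        0.86      0.93
#> active_walking     0.99        0.89      0.95
```

Accuracy is high everywhere, but feeding and standing sensitivity
(0.55 / 0.58) shows the leg tag's blind spot. Position evidence fixes a
window predicted "feeding" whose leg sits exactly one body length from
the headlocks:

```r
m <- dempster_combine(bpa_from_classifier("feeding"), bpa_from_position(1.5))
m
#>     feeding    standing uncertainty
#>    0.921875    0.062500    0.015625
decide_behavior(m)
#> [1] "feeding"
```

Run the full synthetic pipeline (simulate, train, predict, locate, fuse,
evaluate) from R with `run_pipeline(read_run_config(), dir, seed = 1)`, or
from a shell:

```sh
Rscript inst/cli/cowsense.R all --seed 1 --out run1
```

Each stage writes plain CSV artifacts (`sensor_log.csv`, `model.json`,
`first_stage.csv`, `positions.csv`, `fused.csv`, metric tables) into the
run directory.

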