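# recumbency

Automated detection of **group recumbency** — the periods in which every
pig in a pen is lying down — from the group velocity signal of an
overhead tracking camera. Group resting behaviour is a sensitive welfare
and barn-climate indicator in weaner rearing, but scoring it from video
by hand does not scale. This package turns tracked pig positions into a
one-number activity signal and fits a cutoff that flags all-recumbent
periods automatically, for researchers and precision-livestock engineers
who have a tracker but not a labelling team.

## The method

For a pen, with $p_{i,t}$ the position of pig $i$ at frame $t$ and $S_t$
the pigs flagged standing at $t$, the cumulative group velocity of a
frame pair is

$$ v_t = \frac{\sum_{i \in S_t} \lVert p_{i,t} - p_{i,t-\Delta t}\rVert}{\Delta t}, $$

averaged over 5-minute windows. Sampled still images, coded 0 (all pigs
recumbent) or 1 (at least one standing/sitting) by two observers with
consensus resolution, are linked to their windows by pen and timestamp.
Before linking, images pass a blur gate: the variance of the 3×3
Laplacian response must reach a cutoff (default 1000), discarding frames
from soiled lenses. A threshold $\tau$ is then fitted so that
$v > \tau$ predicts code 1, by exhaustive accuracy maximisation over all
candidate cutoffs (plus a literal stepwise-loop variant and a
mean-plus-SD screening rule), and evaluated by 10-fold cross-validation
with sensitivity, specificity and accuracy. A synthetic generator
(trajectories with detection jitter and false standing detections,
images with controllable blur, two-coder label tables) reproduces the
statistical structure the analysis assumes, so everything is testable
without farm data.

## Worked example

Simulate one pen of 18 weaners alternating 30-minute recumbent/active
episodes for 4 h, aggregate velocity, link the ground-truth ethogram,
fit and cross-validate:

```r
library(recumbency)

pen <- pen_config(pen_id = "pen01")          # 2.55 m x 3.20 m, 18 pigs
schedule <- data.frame(start_s = 1800 * (0:7),
                       state = rep(c("all_recumbent", "some_active"), 4))
sim <- simulate_trajectories(pen, behavior_scenario(schedule, seed = 123),
                             duration_s = 4 * 3600)
windows <- summarize_windows(compute_group_velocity(sim$frames), window_s = 300)
samples <- link_samples(windows, sim$ethogram)
head(samples, 4)
#> # A tibble: 4 x 5
#>   pen_id   t_s    v_mps  code blur_score
#> 1 pen01      0 0.000439     0         NA
#> 2 pen01   1200 0.000417     0         NA
#> 3 pen01   2400 0.0206       1         NA
#> 4 pen01   3600 0.000402     0         NA

fit_threshold_exhaustive(samples)
#> <threshold_model> exhaustive: v > 0.01022540026 m/s -> standing
#>                   (fit on n = 12, train accuracy 100.0%)

cross_validate(samples, k = 6, seed = 123)
#> <eval_report> 6-fold CV (exhaustive fit, n = 12, seed 123)
#>   average accuracy    100.00%
#>   average sensitivity 100.00%
#>   average specificity 100.00%

velocity_ttest(samples)$p_value
#> 6.96e-07
```

Recumbent windows carry only detection jitter (~4×10⁻⁴ m/s here), active
windows the speed of the moving pig (~2×10⁻² m/s), so the fitted cutoff
falls in the gap and classification is perfect; the Welch test confirms
the class separation. On real farm data the two populations overlap and
specificity drops well below sensitivity — which is acceptable for the
intended use, surfacing only images where all animals rest.

The full pipeline (simulate → blur QC → consensus coding → velocity →
link → fit → evaluate, with CSV/PNG/JSON artifacts and a hashed
manifest) runs from a YAML config:

```r
cfg <- read_run_config(system.file("extdata/example-config.yaml",
                                   package = "recumbency"),
                       out_dir = "recumbency-run")
run_pipeline(cfg)
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/recumbency.R run --config inst/extdata/example-config.yaml \
    --out recumbency-run --seed 123
```

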