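# dnfsearch

Dynamic neural fields for visual search and scene working memory.

`dnfsearch` implements an autonomous neural dynamic architecture that
explores a visual display, builds a capacity-limited scene working memory,
retains the features of a cue object, and performs guided conjunctive
visual search — all as one coupled system of Amari-type neural fields

τ u̇(x,t) = −u(x,t) + h + s(x,t) + ξ(x,t) + ∫ ω(x−x′) σ(u(x′,t)) dx′

whose detection, selection and sustained-activation instabilities generate
the discrete events (attend, commit, reject, respond) that make up a
trial. The package also ships the closed-form capacity-limited
serial-search models

* E₁(s, c) = p + (1 − p)(s + 1)/2  (guidance: a memorized target is found
  immediately),
* E₂(s, c) = p + (1 − p)(s − c + 1)/2  (guidance plus inhibition:
  memorized distractors are not examined),

with p = min(c/s, 1), and the set-size slope analytics used to quantify
search efficiency. Stimulus arrays (colored oriented bars on a 5×4 tile
grid with a reserved cue tile), presentation timelines, and the two
preview experiments — cue simultaneous with the array versus cue shown
separately between blanks — are generated and simulated end to end.

Who this is for: modellers working with dynamic field theory or
saliency-map architectures who want a self-contained, scriptable
implementation of exploration + working memory + guided search, and
anyone wanting the preview/capacity analytics without the neural layer.

## Worked example

```r
library(dnfsearch)

# the closed-form models at capacity 3 over the experiment's set sizes
s <- c(4, 6, 8, 14, 18)
round(expected_items_eq1(s, 3), 3)
#> [1] 1.375 2.250 3.188 6.107 8.083
round(expected_items_eq2(s, 3), 3)
#> [1] 1.000 1.500 2.250 4.929 6.833
slope_reduction_percent(s, expected_items_eq2(s, 3), (s + 1) / 2)
#> [1] 14.88095

# one full simulated trial: conjunction search with an 800-ms preview
cfg <- dnf_config()
spec <- generate_array(condition = 2, set_size = 8, seed = 5)
res <- run_trial(spec, cfg, seed = 105)
res$rt_ms; res$correct; res$n_retained_at_search
#> [1] 2100
#> [1] TRUE
#> [1] 3
head(event_log(res$arch), 4)
#>   t_ms     event  detail   x   y
#> 1    0   segment   blank  NA  NA
#> 2  200   segment preview  NA  NA
#> 3  345 selection explore 170 160
#> 4  375 match_CoS explore  NA  NA
```

`res$rt_ms` is the model time from cue onset to the match event
(condition-of-satisfaction); `n_retained_at_search` is how many array
items the preview committed to the memory space/feature maps before the
search began — three on the modal trial, because the fourth
working-memory slot is taken by the cue.

A small experiment sweep:

```r
r3 <- run_experiment(1, 3, trials_per_cell = 8, seed = 42)  # no preview
r2 <- run_experiment(1, 2, trials_per_cell = 8, seed = 42)  # preview
r3$fit$slope            # ms per item, conjunction search
experiment_slope_reduction(r2, r3)   # % efficiency gain from the preview
```

A command-line wrapper with the same operations is in
`inst/cli/dnf-visearch.R`.

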