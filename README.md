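# igpsim

Quantitative workflow for DNA-based gut-content analysis of predation
and intraguild predation (IGP) among aphidophagous ladybirds.

PCR screening of field-collected predators tells you *whether* prey DNA
is in a gut, but not how to compare predators fairly: prey DNA decays at
species-specific rates after a meal, and laboratory predation rates need
not transfer to the field. `igpsim` implements the full inferential
chain that turns raw screening data into comparable, detectability-aware
conclusions:

1. **Decay models and T50.** For each predator–prey pair, a binomial GLM
   of detection on hours post feeding, `logit P(detected) = β₀ + β₁ t`,
   fitted to feeding-trial data. The half-detectability time is
   `T50 = −β₀/β₁`, the time at which prey DNA is detectable in 50% of
   fed predators. Likelihood-ratio tests (df = 2: level and rate)
   compare detectability between predators.
2. **Detectability (digestion-rate) correction.** An observed field
   proportion `p` for species A is mapped through A's own decay curve to
   a time since feeding, `t* = (logit(p) − β₀ᴬ)/β₁ᴬ`, then through the
   reference species' curve, `p' = plogis(β₀ᴿ + β₁ᴿ t*)` — the
   proportion A would show if it digested prey at the reference's rate.
   Corrected values are used only to rank predators, never re-tested.
3. **Mixed-model species comparison.** Detection flags of larvae nested
   in sampling units are compared between predator species with a
   binomial GLMM (species fixed effect, random intercept per unit).
4. **Observed vs expected IGP.** A two-part Monte Carlo model generates
   the IGP detections one *would* expect if field predation followed
   laboratory bioassays: per larva, a prey stage class is drawn
   (immobile stages, small larvae, similarly aged larvae), predation is
   drawn from that class's density-dependent logistic lab model at the
   larva's unit aphid density, and — only if predation occurred — DNA
   detection is drawn from the decay curve at a feeding time uniform on
   the 6 h pre-collection window. 5000 simulated datasets give the
   expected count, an empirical 95% CI, and the significance of the
   observed count.

A synthetic-data module generates feeding-trial, field-survey and
lab-bioassay datasets with exactly this structure (logistic decay,
unit-level clustering on the logit scale, density-dependent
stage-specific predation), so the whole pipeline is testable end to end
without external data. Small in-silico PCR utilities (FASTA reading,
reverse complement, amplicon-length prediction) cover the bundled
species-specific COI assays (104/108/263 bp).

## Worked example

```r
library(igpsim)

scenario <- default_scenario(seed = 42)   # two-ladybird melon-field study
trials   <- gen_feeding_trials(scenario, n_per_point = 6)
survey   <- gen_field_survey(scenario)
lab      <- gen_lab_bioassays(scenario, n_per_cell = 30)

fit_decay(dplyr::filter(trials,
  predator_species == "C. septempunctata", prey_species == "H. variegata"))
#> Decay model: C. septempunctata detecting H. variegata
#>   logit p(t) = 2.0282 -0.17627 * t   (n = 54)
#>   T50 = 11.51 h

summarize_detection(survey$larvae, "aphid")
#> # A tibble: 2 × 5
#>   predator_species  prey_kind n_screened n_positive proportion
#> 1 C. septempunctata aphid            164        118      0.720
#> 2 H. variegata      aphid             43         38      0.884

compare_predators_glmm(survey$larvae, survey$units, "aphid")
#> Binomial GLMM comparison (aphid detection)
#>   H. variegata vs C. septempunctata: +1.197 (SE 0.547) on the logit scale, P = 0.0286 (wald)
#>   unit SD = 0.895 over 28 units (207 larvae)

cfg <- sim_config(seed = 7, n_iterations = 5000)
run_observed_vs_expected(survey$larvae, survey$units, lab, trials, cfg)
#> Observed vs expected IGP (instars 3, 4)
#> Two-part IGP simulation: C. septempunctata (149 larvae, 5000 iterations)
#>   observed 45 (30.2%)  expected 78.8 (52.9%)  95% CI [67.0, 90.0]
#>   P = 0.0003999 (two.sided)
#> Two-part IGP simulation: H. variegata (36 larvae, 5000 iterations)
#>   observed 17 (47.2%)  expected 14.8 (41.2%)  95% CI [9.0, 20.0]
#>   P = 0.5655 (two.sided)
```

Reading: with a 54-larva feeding trial the fitted half-detectability
time for heterospecific prey in *C. septempunctata* guts is ≈ 11.5 h.
In the simulated survey *H. variegata* shows higher aphid predation
(88% vs 72%, GLMM P ≈ 0.03). Field IGP by *C. septempunctata* (30.2%)
is far below what its laboratory predation rates predict (52.9%,
P < 0.001), while *H. variegata*'s is compatible with expectation —
the pattern the detectability-aware workflow is designed to expose.

`run_replication(scenario, out_dir)` chains every stage and writes the
datasets, a results CSV per stage, a Markdown report and a JSON run
manifest (seed + configuration hash). `fit_decay_table()`, `tidy()`,
`glance()` and `autoplot()` methods cover tabular and graphical
summaries of every result type.

## Dataset schemas

Four CSV schemas (UTF-8, booleans as 0/1) connect the stages; see
`?load_table`:

| schema | columns |
|---|---|
| `feeding_trial` | `predator_species, prey_species, hours_post_feeding, detected` |
| `field_survey_units` | `unit_id, aphid_density` |
| `field_survey_larvae` | `larva_id, unit_id, predator_species, instar, detected_aphid, detected_heterospecific` |
| `lab_bioassay` | `ig_predator_species, prey_stage_class, aphid_density, predation` |

The methods vignette (`vignettes/gut-content-igp.Rmd`) documents the
models, every tunable parameter, the synthetic-data design and the
package's numerical choices.
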