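# markerdigest

Regional small-intestinal amino acid (AA) digestibility from single
post-prandial digesta collections, by the indigestible-marker ratio
method.

## The problem and who this is for

In milk-fed neonates (piglet as the infant model), milk clots in the
stomach and the curd controls how fast protein reaches the small
intestine. A terminal dissection — digesta collected from the stomach,
proximal and distal small intestine (PSI, DSI), terminal ileum and large
intestine — can localize where dietary AAs disappear, if the flow past
each sampled site is reconstructed from an unabsorbed tracer (titanium
dioxide) mixed into the meal. This package is for digestive
physiologists and nutrition scientists running such marker studies: it
turns per-animal compartment tables into a complete, flagged
digestibility ledger, and ships a ground-truth simulator so every
estimator is testable by parameter recovery.

## The method

For compartment $L$ with marker mass $m_L$ and AA mass $A_L$
(mass = DM × %DM/100), dietary intake $D$:

- marker released past $L$: $\mathrm{after}(L)$ = marker recovered
  downstream; AA released past $L$: $A_L \cdot \mathrm{after}(L)/m_L$;
- unabsorbed at the position $L$ represents (PSI → 25%, DSI → 75%,
  terminal ileum → 100% of small-intestinal length):
  stomach + compartments up to $L$ + released past $L$;
- apparent digestibility (%) $= 100\,(D - \mathrm{unabsorbed})/D$;
- gastric retention (mg/mg) $=$ stomach mass $/ D$; available-AA
  digestibility repeats the calculation on the intake that actually
  entered the small intestine, so that exactly
  apparent = available × (1 − retention);
- group rows (EAA, BCAA, NEAA, LNAA) are computed on summed member
  masses.

Over-unity retention and negative digestibility are preserved and
flagged, never clipped; zero marker at a site yields a missing row.
Terminal-ileum marker masses can be imputed from donor animals
(species-mean or overall-mean policy). Only apparent digestibility is
reported — no endogenous-loss correction.

## Worked example

Simulate the default 3-milk × 4-piglet cohort (bovine/caprine/ovine
presets), impute, digest, compare:

```r
library(markerdigest)

sim    <- simulate_cohort(sim_config(seed = 17))
cohort <- impute_terminal_marker(sim$cohort)

build_ledger(cohort[[1]])
#> <marker_ledger> intake 204.7 mg, recovery 1.017
#>         STOMACH    PSI    DSI    TI     LI
#> mass_mg 111.509 19.684 46.128 4.374 26.531

dig <- digest_cohort(cohort)
leu <- dig[dig$analyte == "LEU" & dig$location == "PSI", ]
aggregate(cbind(retention_ratio, apparent_dig_pct, available_dig_pct)
          ~ species, leu, mean)
#>   species retention_ratio apparent_dig_pct available_dig_pct
#> 1  bovine           0.679             16.4              51.8
#> 2 caprine           0.547             21.4              47.2
#> 3   ovine           0.377             29.5              47.4
```

Reading: at the 25% position, about 16% of consumed leucine has
disappeared in the bovine group versus 30% in the ovine group — but the
available-AA digestibility (right column) is similar across milks, i.e.
the difference is driven by gastric retention (0.68 vs 0.38 of intake
still in the stomach), not by intestinal uptake. The blocked comparison
makes that inferential:

```r
two_factor_blocked(dig[dig$analyte == "LEU" &
                         dig$location %in% c("PSI", "DSI"), ])
#> <blocked_comparison> species p = 0.0049711, location p = 1.2424e-07,
#>                      interaction retained (p = 0.0016819)
#> species:
#>     level n     mean      sem letter
#> 1  bovine 8 14.41800 4.157788      b
#> 2 caprine 8 27.71296 2.757965     ab
#> 3   ovine 8 37.92021 3.250879      a
```

Levels without a shared letter differ at α = 0.05 (Tukey). The marker
ledger itself can be summarized cohort-wide:

```r
marker_distribution(cohort)
#>   location mean_pct sem_pct  n
#> 1  STOMACH    52.15   1.050 12
#> 2      PSI     8.89   0.348 12
#> 3      DSI    23.07   0.762 12
#> 4       TI     1.98   0.105 12
#> 5       LI    13.22   0.472 12
```

Bundled reference tables (`milk_reference()`, `retention_reference()`,
`digestibility_reference()`) provide the raw-milk AA composition and
published cohort summaries used for simulator calibration; e.g. the ovine
group sums recompute as BCAA 154.0, EAA 314.4 mg/g protein from the
component rows.

A YAML-driven end-to-end run (`run_pipeline()`) and a thin CLI
(`inst/scripts/markerdigest simulate|digest|all`) write `animals.csv`,
`meals.csv`, `marker_ledger.tsv`, `digestibility.tsv` and comparison
tables; see `?read_run_config` for the schema, and the vignette
(`vignettes/marker-digestibility.Rmd`) for the methods and design
decisions.

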