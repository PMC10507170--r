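---
title: "Regional amino acid digestibility from a single digesta collection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional amino acid digestibility from a single digesta collection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdigest)
```

## The problem

In milk-fed neonates (modelled here by the piglet), protein digestion is
rate-limited by the stomach: milk clots under gastric acid and pepsin, and
the curd releases protein into the small intestine at a species-dependent
rate. A single post-prandial dissection — total digesta collected from the
stomach, the proximal and distal halves of the small intestine (PSI, DSI),
the terminal ileum and the large intestine — can quantify where along the
small intestine dietary amino acids (AA) disappear, *provided* the flow
past each sampled site can be reconstructed. That is what an indigestible
marker does: titanium dioxide is mixed into the meal, is neither absorbed
nor degraded, and so the AA:marker ratio of digesta at a site estimates
the composition of everything that has flowed past it.

`markerdigest` implements this accounting as a tested pipeline:

* a TiO~2~ mass ledger per animal (per-compartment masses, cumulative
  `until` and downstream `after` totals, whole-tract recovery,
  terminal-ileum imputation);
* gastric AA retention, apparent and available-AA digestibility at the
  25%, 75% and 100% small-intestinal positions, and absorbed amount per g
  protein consumed, for individual AAs and summed physiological groups;
* a seeded synthetic cohort generator with known ground truth, so every
  estimator is verifiable by parameter recovery;
* simplified cohort comparisons (one-way ANOVA with Tukey letters, and a
  blocked two-factor model with the drop-nonsignificant-interaction rule).

## The estimators

All masses are internal to the package in mg; unit conversions happen only
at I/O boundaries. For a compartment with dry matter $DM$ (g) and an
assayed concentration $c$ (% of DM), the mass is $DM \cdot c / 100$
(converted to mg). Writing $D$ for the dietary intake of an AA and $m_L$,
$A_L$ for the marker and AA masses in compartment $L$:

* **until/after ledger.** $\mathrm{until}(L)$ accumulates marker from the
  stomach through $L$; $\mathrm{after}(L)$ sums marker recovered
  downstream of $L$ (for the PSI: DSI + terminal ileum + large
  intestine). Their sum is the total recovered marker at every site — the
  conservation invariant tested on thousands of random records.
* **released past a site.** $R_L = A_L \cdot \mathrm{after}(L) / m_L$:
  digesta that left site $L$ are assumed to carry the site's AA:marker
  ratio.
* **unabsorbed and apparent digestibility.** At the position represented
  by site $L$, the unabsorbed mass is the stomach content plus every
  small-intestinal compartment content up to and including $L$ plus
  $R_L$; apparent digestibility is
  $100\,(D - \mathrm{unabsorbed})/D$. The sampled segments are assumed to
  hold digesta uniformly, so PSI and DSI contents represent the 25% and
  75% points of small-intestinal length and the terminal ileum the whole
  small intestine. The generalization from the first quarter to the
  downstream positions is cumulative by construction of those positions.
* **gastric retention and available digestibility.** Retention is
  stomach mass over intake (mg/mg). Available-AA digestibility repeats
  the calculation on the fraction of intake that actually entered the
  small intestine: both the intake and the unabsorbed mass are reduced by
  the stomach content. The algebraic identity
  $\mathrm{apparent} = \mathrm{available} \times (1 - \mathrm{retention})$
  holds exactly row by row and is asserted to machine precision in the
  tests.
* **groups.** EAA/BCAA/NEAA/LNAA rows are computed on *summed member
  masses* at every stage, never as means of member digestibilities.

Nothing is clipped: gastric retention above 1 (residual protein from
earlier meals that a washout did not clear) and negative apparent
digestibility pass through with an `over_unity_retention` flag, and
available digestibility is undefined (`NA`, flagged
`entering_nonpositive`) when nothing has entered the small intestine. A
zero marker mass at a site makes the extrapolation undefined; the row is
emitted as missing (`zero_marker`), not as zero. Marker recovery is
reported but never used to rescale masses.

Only *apparent* digestibility is computed: no endogenous-loss correction
is attempted, so values are not true digestibilities.

## Terminal-ileum imputation

Terminal-ileal digesta are frequently too scant to assay for TiO~2~ even
when an AA assay is possible. `impute_terminal_marker()` fills the missing
terminal-ileal marker *mass* with the mean mass of donor animals measured
for it — same-species donors under `species_mean` (falling back to the
overall mean when a species has none), all donors under `overall_mean`,
or an error under `fail`. Mass rather than concentration is donated
because downstream formulas consume mass and the dry matter of scant
digesta is itself unreliable. Which donor set is scientifically right is
genuinely ambiguous in practice (a species' donors may be too few), so
the policy is a configuration choice and every imputed animal is flagged
in the ledger output. Animals with measured values are never altered.

## The synthetic cohort generator

The generator is the test bed that makes the estimators falsifiable. Each
animal is a single-time-point snapshot built by mass balance: a fraction
$R$ of each dietary AA is still gastric; the marker has distributed over
stomach/PSI/DSI/TI/LI with fractions $(g, m_{PSI}, m_{DSI}, m_{TI},
m_{LI})$ summing to 1; emptied AAs have been absorbed according to a
positional curve $a(x)$ evaluated at $x = 0.25, 0.75, 1.0$. Dry matter and
concentrations are back-derived so that the mass formulas reproduce these
targets exactly, and measurement noise is applied multiplicatively
(log-normal) to concentrations — what an assay actually measures — never
to masses. AA and marker gastric retention are deliberately decoupled
($R \neq g$): in real cohorts dietary-AA retention can diverge strongly
from marker retention when residual pre-washout protein sits in the curd.

Defaults encode the reference piglet cohort this package ships summaries
of (see `?milk_reference`): body weight 5.17 kg, 2 g protein/kg BW, 5.5 mg
TiO~2~/g meal DM, per-species meal DM of 7.2/7.1/5.6 g/kg BW, gastric AA
retention 0.7/0.5/0.4 for bovine/caprine/ovine milk, marker split
52/9/24/2/13% with a 2% whole-tract loss (98% recovery), and a saturating
absorption curve $a(x) = 0.9\,(1 - e^{-3.1 x})$, which reproduces
available digestibility near 47% at the 25% point and 81% at the 75%
point. The reference data carry no per-animal variance components, so the
between-animal CVs (0.10 on retention and on the marker fractions) and
the concentration noise sd (0.05) are assumptions of this package, chosen
once as typical magnitudes for duplicate-assay nutrition data, and are
stated here rather than hidden.

Two estimator properties the generator makes visible:

* **Closed-form exactness.** With the same absorbed fraction $a$ in every
  post-gastric compartment and zero noise, the unabsorbed mass is
  $RD + D(1-R)(1-a)$ *regardless of the marker split*, so the estimator
  returns exactly $a(1-R)$ (apparent) and $a$ (available) at all three
  positions. The tests assert this to 10^-9^ relative (it holds to
  ~10^-14^).
* **Extrapolation bias under a position-dependent curve.** With a
  saturating $a(x)$, material that left a site was absorbed further at
  downstream positions than the site's own ratio implies. At the 25%
  point the estimate is exact by construction here, but at the 75% and
  100% points the estimator returns a marker-weighted mix of segment
  absorptions and under-estimates the true cumulative uptake by a few
  percentage points. This bias is a property of the marker-ratio method
  itself, is independent of cohort size, and is surfaced (not hidden) by
  `recover_parameters()`.

Because of that second property, the parameter-recovery suite separates
two error sources. Coverage of gastric retention (the species × analyte
mean estimate within ±0.05 of the mean realized truth in ≥95% of seeded
replicates) is checked under the default curve, since retention is
unaffected by absorption. The *sampling* error of the cohort-level
digestibility estimate — the quantity that shrinks like $1/\sqrt{n}$ —
is measured in the piecewise-constant regime where the estimator is
consistent; under the saturating curve the constant extrapolation bias
would dominate and no amount of animals would reduce it.

What the generator does **not** emulate: time-resolved gastric-emptying
kinetics (one snapshot only), curd mechanics, correlated assay errors
between AAs measured in one chromatography run, dry-matter measurement
error (DM is noise-free by default), and endogenous AA secretion.
Passing recovery tests therefore show that the accounting and its
implementation are correct under the stated error model — not that the
marker-ratio method is unbiased for real digesta, where the
position-dependence of absorption is unknown.

## Simplified statistics

The original inferential machinery for designs like this is a REML mixed
model with covariance-structure selection. That selection step is routine
and is not re-implemented. Instead:

* `oneway_tukey()` — `stats::aov` plus Tukey HSD at α = 0.05, with a
  compact letter display built by covering the "not significantly
  different" graph with its maximal cliques (Bron–Kerbosch); two levels
  share a letter *iff* their pairwise Tukey p-value exceeds α, a property
  the tests assert exhaustively. Degenerate (zero residual variance)
  fits are flagged and fall back to equality-of-means decisions.
* `two_factor_blocked()` — a split-plot
  `aov(y ~ species * location + Error(animal))`: species tested against
  the between-animal stratum, location and the interaction against the
  within-animal stratum. Following the usual reporting rule the
  interaction is removed and the model refitted when its p-value exceeds
  α = 0.05. Per-factor letters use Tukey–Kramer on the appropriate
  stratum's error mean square; the tests verify both the F statistics
  against a hand sums-of-squares computation and the pairwise p-values
  against `emmeans` on the same fit.

These are labelled simplified reanalyses throughout; they are not
expected to reproduce any particular published p-value (the underlying
animal-level raw data are not public), and the package never claims
otherwise.

## Numerical and design choices

* Internal mass unit mg everywhere; conversions only at I/O.
* ASX/GLX pooling: acid hydrolysis converts asparagine and glutamine to
  the acids, so milk "Asparagine"/"Glutamine" and digesta "Asp"/"Glu"
  labels are one analyte each; the synonym map is total over both
  spellings and case-insensitive.
* Group membership: BCAA = {Ile, Leu, Val}; EAA adds His, Lys, Met, Phe,
  Thr, Trp; LNAA = {Ile, Leu, Val, Phe, Trp, Tyr} (this six-member set
  reproduces the caprine reference total exactly and the bovine total to
  0.1); NEAA = {Ala, Arg, Asx, Cys, Glx, Ser, Tyr} with proline optional.
  Published NEAA totals exceed their listed component sums (undisclosed
  members, likely Pro/Gly), and the ovine LNAA total exceeds its
  six-member sum by 1.9, so neither is used as a test oracle; membership
  is configurable.
* Printed group totals are sums of *rounded* components, so aggregation
  checks use a half-unit-per-member tolerance (0.05 × members) rather
  than exact equality.
* Full floating precision everywhere; rounding (1 decimal for
  percentages, 2 for retention ratios) only at report rendering, with
  full-precision `*_raw` columns retained in machine outputs.
* CSV numerics are written with 17 significant digits so a write/read
  round trip reproduces every numeric field exactly.
* Monte-Carlo problem sizes: 200 seeded replicates for retention-recovery
  coverage, 20 + 20 for the RMSE-versus-n comparison, 1,000 random
  records for ledger invariants, 2,000 null replicates for ANOVA
  calibration — sizes at which the binomial noise on each checked
  proportion is well inside the asserted margins.

## Limitations

Single-time-point snapshots cannot separate rate from extent: a low
apparent digestibility 210 min after a meal may reflect slow emptying
rather than poor absorption, which is exactly why the available-AA
correction is reported alongside. Terminal-ileum values inherit the
imputation's averaging and should be read as indicative. The marker-ratio
extrapolation's downstream bias (above) applies to any real use of the
method. And apparent digestibility confounds dietary and endogenous AAs;
comparative statements between milks are safer than absolute ones.
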