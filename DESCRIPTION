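Package: markerdigest
Title: Regional Small-Intestinal Amino Acid Digestibility by the
    Indigestible-Marker Ratio Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes apparent amino acid (AA) digestibility at fractional
    small-intestinal positions from single-time-point digesta collections,
    using titanium dioxide as an indigestible solid-phase marker. Implements
    the full marker mass ledger (per-compartment marker masses, cumulative
    and downstream totals, whole-tract recovery, terminal-ileum imputation),
    gastric AA retention, apparent and available-AA digestibility, absorbed
    amount per g protein consumed, and aggregation over physiological AA
    groups (EAA, BCAA, NEAA, LNAA). Includes a seeded synthetic
    gut-transit/absorption cohort generator with known ground truth for
    parameter-recovery validation, simplified cohort comparisons (one-way
    ANOVA with Tukey letters and a blocked two-factor model), and CSV/TSV
    readers and writers for animal trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    withr
Config/testthat/edition: 3
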