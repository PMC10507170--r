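# Shared fixtures: a hand-balanced toy animal, a random-record generator,
# and a brute-force digestibility oracle independent of the pipeline code.

# Toy animal T1. Marker: intake 100 mg, stomach/PSI/DSI/TI/LI =
# 50/10/25/2/13 mg. One analyte (LEU): intake 100 mg, stomach 50, PSI 8,
# DSI 15, TI 1 mg. Hand mass balance gives apparent digestibility
# 10/18/19.5 % and available digestibility 20/36/39 % at PSI/DSI/TI.
toy_record <- function() {
  comp <- aa_profile(c(LEU = 10), "mg_per_g_protein")
  meal <- milk_meal("bovine", body_weight = 5, protein_dose = 2,
                    marker_dose = 5, meal_dm = 20, composition = comp)
  samples <- list(
    compartment_sample("STOMACH", 10, 0.5,
                       aa_profile(c(LEU = 0.5), "pct_DM")),
    compartment_sample("PSI", 2, 0.5, aa_profile(c(LEU = 0.4), "pct_DM")),
    compartment_sample("DSI", 5, 0.5, aa_profile(c(LEU = 0.3), "pct_DM")),
    compartment_sample("TI", 1, 0.2, aa_profile(c(LEU = 0.1), "pct_DM")),
    compartment_sample("LI", 6.5, 0.2))
  animal_record("T1", meal, samples)
}

# random valid record drawing DM masses and concentrations from wide
# uniform ranges; uses the current RNG stream
random_record <- function(id = "R1", n_aa = sample(2:5, 1)) {
  keys <- sample(aa_keys(), n_aa)
  comp <- aa_profile(stats::setNames(runif(n_aa, 5, 100), keys),
                     "mg_per_g_protein")
  meal <- milk_meal(sample(c("bovine", "caprine", "ovine"), 1),
                    runif(1, 3, 8), 2, runif(1, 4, 6), runif(1, 10, 40),
                    comp)
  rnd_sample <- function(loc, dm)
    compartment_sample(loc, dm, runif(1, 0.05, 2),
                       aa_profile(stats::setNames(runif(n_aa, 0.01, 3),
                                                  keys), "pct_DM"))
  samples <- list(
    rnd_sample("STOMACH", runif(1, 2, 15)),
    rnd_sample("PSI", runif(1, 0.5, 5)),
    rnd_sample("DSI", runif(1, 0.5, 5)),
    rnd_sample("TI", runif(1, 0.05, 2)),
    compartment_sample("LI", runif(1, 0.5, 8), runif(1, 0.05, 2)))
  animal_record(id, meal, samples)
}

# brute-force unabsorbed mass: explicit summation over raw sample fields,
# sharing no code with the pipeline
oracle_unabsorbed <- function(record, loc, aa) {
  mg <- function(dm, conc) dm * conc / 100 * 1000
  mk <- function(l) {
    s <- record$samples[[l]]
    mg(s$digesta_dm, s$marker_conc)
  }
  aam <- function(l) {
    s <- record$samples[[l]]
    mg(s$digesta_dm, unclass(s$aa_conc)[[aa]])
  }
  li_locs <- intersect(c("CECUM", "PROX_COLON", "DIST_COLON", "LI"),
                       names(record$samples))
  ti <- if (!is.na(record$samples$TI$marker_conc)) mk("TI")
  else record$ti_marker_imputed_mg
  m <- c(STOMACH = mk("STOMACH"), PSI = mk("PSI"), DSI = mk("DSI"),
         TI = ti, LI = sum(vapply(li_locs, mk, numeric(1))))
  after <- switch(loc,
                  PSI = m[["DSI"]] + m[["TI"]] + m[["LI"]],
                  DSI = m[["TI"]] + m[["LI"]],
                  TI = m[["LI"]])
  upto <- switch(loc, PSI = "PSI", DSI = c("PSI", "DSI"),
                 TI = c("PSI", "DSI", "TI"))
  aam("STOMACH") + sum(vapply(upto, aam, numeric(1))) +
    aam(loc) * after / m[[loc]]
}

oracle_apparent <- function(record, loc, aa) {
  intake <- unclass(aa_intake(record$meal))[[aa]]
  100 * (intake - oracle_unabsorbed(record, loc, aa)) / intake
}
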