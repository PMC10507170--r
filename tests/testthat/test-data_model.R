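test_that("synonym map resolves every spelling onto the canonical keys", {
  # frozen synonym table: milk labels, digesta labels, amide/acid forms
  expected <- c(
    Asparagine = "ASX", Asp = "ASX", Aspartate = "ASX", ASN = "ASX",
    Glutamine = "GLX", Glu = "GLX", Glutamate = "GLX", GLN = "GLX",
    Isoleucine = "ILE", Ile = "ILE", Leucine = "LEU", Valine = "VAL",
    Histidine = "HIS", Lysine = "LYS", Methionine = "MET",
    Phenylalanine = "PHE", Threonine = "THR", Tryptophan = "TRP",
    Alanine = "ALA", Arginine = "ARG", Cysteine = "CYS", Cystine = "CYS",
    Serine = "SER", Tyrosine = "TYR", Proline = "PRO")
  expect_identical(canonicalize_aa_name(names(expected)),
                   unname(expected))
  # identity and case-insensitivity
  expect_identical(canonicalize_aa_name(aa_keys()), aa_keys())
  expect_identical(canonicalize_aa_name("lEuCiNe"), "LEU")
  err <- tryCatch(canonicalize_aa_name("Norleucine"), error = identity)
  expect_s3_class(err, "markerdigest_unknown_aa")
  expect_match(conditionMessage(err), "Accepted names")
  expect_error(canonicalize_aa_name(""), "non-empty")
})

test_that("profiles enforce a single basis and non-negative quantities", {
  p <- aa_profile(c(Isoleucine = 30.1, Leu = 52.4), "mg_per_g_protein")
  expect_identical(names(p), c("ILE", "LEU"))
  expect_identical(aa_basis(p), "mg_per_g_protein")
  expect_error(aa_profile(c(ILE = -1), "pct_DM"), "finite and >= 0")
  expect_error(aa_profile(c(ILE = NaN), "pct_DM"), "finite")
  expect_error(aa_profile(c(Asp = 1, Asparagine = 2), "pct_DM"),
               "duplicate")
  # cross-basis use is rejected where profiles are consumed
  expect_error(
    milk_meal("bovine", 5, 2, 5, 20,
              composition = aa_profile(c(ILE = 1), "pct_DM")),
    "mg_per_g_protein")
})

test_that("group aggregation is a plain sum and is additive", {
  p <- aa_profile(c(ILE = 37.0, LEU = 74.1, VAL = 42.9, HIS = 18.9),
                  "mg_per_g_protein")
  expect_equal(unname(aggregate_groups(p, list(BCAA = c("ILE", "LEU",
                                                        "VAL")))[["BCAA"]]),
               154.0)
  expect_equal(as.numeric(aggregate_groups(p, list(EMPTY = character(0)))),
               0)
  # additivity over disjoint groups
  set.seed(11)
  for (i in 1:20) {
    keys <- sample(aa_keys(), 6)
    prof <- aa_profile(stats::setNames(runif(6, 0, 50), keys), "mg_total")
    g1 <- keys[1:3]; g2 <- keys[4:6]
    sep <- aggregate_groups(prof, list(a = g1, b = g2))
    uni <- aggregate_groups(prof, list(u = c(g1, g2)))
    expect_equal(unname(uni[["u"]]), sum(sep))
  }
  err <- tryCatch(aggregate_groups(p, list(EAA = aa_groups()$EAA)),
                  error = identity)
  expect_s3_class(err, "markerdigest_missing_member")
  expect_match(conditionMessage(err), "EAA")
  expect_match(conditionMessage(err), "LYS")
  # skip policy sums the present members
  expect_equal(
    unname(aggregate_groups(p, list(EAA = aa_groups()$EAA),
                            missing = "skip")[["EAA"]]),
    37.0 + 74.1 + 42.9 + 18.9)
})

test_that("reference milk group totals are reproduced from component rows", {
  groups <- aa_groups()
  ref <- milk_reference()
  totals <- list(BCAA = "Total BCAA", EAA = "Total EAA",
                 LNAA = "Total LNAA")
  for (sp in c("bovine", "caprine", "ovine")) {
    prof <- reference_composition(sp)
    agg <- aggregate_groups(prof, groups[names(totals)])
    for (g in names(totals)) {
      if (sp == "ovine" && g == "LNAA") next
      # (the ovine LNAA printed total exceeds its six-member sum by 1.9,
      # an unexplained gap in the source table; not used as an oracle)
      printed <- ref$mg_per_g_protein[ref$species == sp &
                                        ref$analyte == totals[[g]]]
      # printed totals are sums of rounded components: allow half-unit
      # rounding per member
      expect_lt(abs(agg[[g]] - printed),
                0.05 * length(groups[[g]]) + 1e-9)
    }
  }
  # NEAA printed totals are not reproducible from listed components
  # (undisclosed members) and are deliberately not checked
})

test_that("record validation reports every violation without stopping", {
  expect_length(validate_record(toy_record()), 0)
  rec <- toy_record()
  rec$samples$PSI$aa_conc <- NULL
  v <- validate_record(rec)
  expect_length(v, 1)
  expect_match(v, "PSI")
  rec2 <- toy_record()
  rec2$samples$STOMACH$marker_conc <- 120   # bypasses the constructor
  expect_match(validate_record(rec2), "\\[0, 100\\]", all = FALSE)
  rec3 <- toy_record()
  rec3$samples$LI <- NULL
  expect_match(validate_record(rec3), "large-intestinal", all = FALSE)
  expect_error(compartment_sample("PSI", 1, 120), "\\[0, 100\\]")
})
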