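# Bundled reference tables: amino-acid composition of raw bovine, caprine
# and ovine milk (mg/g protein, mean +/- SEM of 3 batches per milk), meal
# allowances, and published cohort summaries of gastric amino-acid
# retention and regional apparent digestibility in milk-fed piglets
# (n = 4 per milk, 210 min postprandially). Used for simulator calibration,
# aggregation checks and worked examples.

.ref_path <- function(file)
  system.file("extdata", file, package = "markerdigest", mustWork = TRUE)

#' Reference milk amino-acid composition
#'
#' Amino-acid composition of raw bovine, caprine and ovine milk on the
#' mg/g protein basis, including the published group totals (`row_type`
#' distinguishes component rows from totals). Amide amino acids are
#' reported under their milk labels (`Asparagine`, `Glutamine`) and map to
#' the pooled `ASX`/`GLX` analytes via [canonicalize_aa_name()].
#'
#' @return Data frame: `species`, `analyte`, `row_type`,
#'   `mg_per_g_protein`, `sem`.
#' @export
milk_reference <- function() {
  utils::read.csv(.ref_path("milk_aa_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference meal allowances per kg body weight
#'
#' Fresh-milk, protein, fat, lactose, dry-matter and energy allowances of
#' the reference meals, per kg body weight (protein normalized to
#' 2 g/kg BW across milks).
#'
#' @return Data frame keyed by `species`.
#' @export
milk_meal_reference <- function() {
  utils::read.csv(.ref_path("milk_meal_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference gastric amino-acid retention
#'
#' Published cohort means (mg retained per mg consumed, +/- SEM) of gastric
#' amino-acid retention at 210 min in piglets fed raw bovine, caprine or
#' ovine milk, including group-total rows.
#'
#' @return Data frame: `analyte`, `row_type`, then per-species mean and SEM
#'   columns.
#' @export
retention_reference <- function() {
  utils::read.delim(.ref_path("gastric_retention_reference.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference regional apparent digestibility
#'
#' Published cohort summaries of small-intestinal apparent amino-acid
#' digestibility (%): per-milk overall means, and means at the 25% and 75%
#' small-intestinal positions, with SEMs and significance codes.
#'
#' @return Data frame: `analyte`, `row_type`, `bovine`, `caprine`, `ovine`,
#'   `sem_milk`, `q25`, `q75`, `sem_location`, `p_milk`, `p_location`.
#' @export
digestibility_reference <- function() {
  utils::read.delim(.ref_path("apparent_digestibility_reference.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference milk composition as an amino-acid profile
#'
#' Component rows of [milk_reference()] for one species, as an
#' [aa_profile()] on the mg/g protein basis (keys canonicalized, so
#' asparagine and glutamine appear as `ASX` and `GLX`).
#'
#' @param species `"bovine"`, `"caprine"` or `"ovine"`.
#' @return An [aa_profile()].
#' @examples
#' reference_composition("ovine")
#' @export
reference_composition <- function(species = c("bovine", "caprine", "ovine")) {
  species <- match.arg(species)
  ref <- milk_reference()
  ref <- ref[ref$species == species & ref$row_type == "component", ]
  aa_profile(stats::setNames(ref$mg_per_g_protein, ref$analyte),
             basis = "mg_per_g_protein")
}
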