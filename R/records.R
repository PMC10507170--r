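# Meal, compartment-sample and animal-record containers plus validation.

.GUT_LOCATIONS <- c("STOMACH", "PSI", "DSI", "TI", "CECUM", "PROX_COLON",
                    "DIST_COLON", "LI")
.SI_LOCATIONS <- c("PSI", "DSI", "TI")
.LI_LOCATIONS <- c("CECUM", "PROX_COLON", "DIST_COLON", "LI")

#' Gut locations in aboral order
#'
#' Sampled compartments from stomach to distal colon. `LI` is a pooled
#' large-intestine pseudo-location accepted in place of the three separate
#' hindgut compartments; only the summed large-intestinal marker mass is
#' consumed downstream.
#'
#' @return Character vector of location codes in anatomical order.
#' @export
gut_locations <- function() .GUT_LOCATIONS

#' Small-intestinal sampling positions
#'
#' Fraction of small-intestinal length each sampled segment represents:
#' digesta are assumed evenly distributed within the proximal and distal
#' halves, so their contents stand for the 25% and 75% points, and the
#' terminal ileum for the whole small intestine (100%).
#'
#' @return Named numeric vector (`PSI`, `DSI`, `TI`).
#' @export
si_positions <- function() c(PSI = 0.25, DSI = 0.75, TI = 1.0)

#' Construct a milk meal
#'
#' The test meal: fresh milk normalized to a protein dose per kg body
#' weight, carrying suspended titanium dioxide as the indigestible
#' solid-phase marker.
#'
#' @param species Species label (`"bovine"`, `"caprine"`, `"ovine"`, or any
#'   custom label).
#' @param body_weight Body weight, kg.
#' @param protein_dose Protein allowance, g protein per kg body weight
#'   (default 2).
#' @param marker_dose TiO2 dose, mg per g meal dry matter.
#' @param meal_dm Meal dry matter consumed, g.
#' @param composition [aa_profile()] of the milk protein, mg per g protein.
#' @return An object of class `milk_meal`.
#' @export
milk_meal <- function(species, body_weight, protein_dose = 2, marker_dose,
                      meal_dm, composition) {
  stopifnot(is.character(species), length(species) == 1L)
  for (v in c(body_weight = body_weight, protein_dose = protein_dose,
              marker_dose = marker_dose, meal_dm = meal_dm))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("body_weight, protein_dose, marker_dose and meal_dm must be single positive numbers",
           call. = FALSE)
  if (!inherits(composition, "aa_profile") ||
      aa_basis(composition) != "mg_per_g_protein")
    stop("`composition` must be an aa_profile on the mg_per_g_protein basis",
         call. = FALSE)
  structure(list(species = species, body_weight = body_weight,
                 protein_dose = protein_dose, marker_dose = marker_dose,
                 meal_dm = meal_dm, composition = composition),
            class = "milk_meal")
}

#' Dietary amino-acid intake of a meal
#'
#' @param meal A [milk_meal()].
#' @return [aa_profile()] of total dietary intake, mg
#'   (composition x protein dose x body weight).
#' @export
aa_intake <- function(meal) {
  stopifnot(inherits(meal, "milk_meal"))
  v <- unclass(meal$composition) * meal$protein_dose * meal$body_weight
  structure(v, basis = "mg_total", class = "aa_profile")
}

#' Dietary marker intake of a meal
#'
#' @param meal A [milk_meal()].
#' @return TiO2 intake, mg (marker dose x meal dry matter).
#' @export
marker_intake <- function(meal) {
  stopifnot(inherits(meal, "milk_meal"))
  meal$marker_dose * meal$meal_dm
}

#' Protein consumed in a meal
#' @param meal A [milk_meal()].
#' @return g protein.
#' @export
protein_consumed <- function(meal) meal$protein_dose * meal$body_weight

#' Construct a digesta compartment sample
#'
#' One gut location's freeze-dried digesta: dry-matter mass, TiO2
#' concentration (% of DM) and optionally per-analyte amino-acid
#' concentrations (% of DM). The marker concentration may be `NA` for the
#' terminal ileum only (scant digesta; see [impute_terminal_marker()]);
#' amino-acid concentrations are optional for large-intestinal locations.
#'
#' @param location A code from [gut_locations()].
#' @param digesta_dm Digesta dry matter, g (>= 0).
#' @param marker_conc TiO2 concentration, % of DM, or `NA`.
#' @param aa_conc Optional [aa_profile()] on the `pct_DM` basis.
#' @return An object of class `compartment_sample`.
#' @export
compartment_sample <- function(location, digesta_dm, marker_conc = NA_real_,
                               aa_conc = NULL) {
  location <- match.arg(location, .GUT_LOCATIONS)
  if (!is.numeric(digesta_dm) || length(digesta_dm) != 1L ||
      !is.finite(digesta_dm) || digesta_dm < 0)
    stop("`digesta_dm` must be a single finite number >= 0", call. = FALSE)
  if (!length(marker_conc)) marker_conc <- NA_real_
  marker_conc <- as.numeric(marker_conc)
  if (length(marker_conc) != 1L)
    stop("`marker_conc` must be a single number or NA", call. = FALSE)
  if (!is.na(marker_conc) && (marker_conc < 0 || marker_conc > 100))
    stop("`marker_conc` must lie in [0, 100] %DM", call. = FALSE)
  if (!is.null(aa_conc)) {
    if (!inherits(aa_conc, "aa_profile") || aa_basis(aa_conc) != "pct_DM")
      stop("`aa_conc` must be an aa_profile on the pct_DM basis",
           call. = FALSE)
    if (any(unclass(aa_conc) > 100))
      stop("amino-acid concentrations must lie in [0, 100] %DM",
           call. = FALSE)
  }
  structure(list(location = location, digesta_dm = digesta_dm,
                 marker_conc = marker_conc, aa_conc = aa_conc),
            class = "compartment_sample")
}

#' Construct an animal record
#'
#' One animal's meal plus its compartment samples, at most one per
#' location. The large intestine may be supplied either pooled (`LI`) or as
#' the three hindgut compartments.
#'
#' @param animal_id Identifier string.
#' @param meal A [milk_meal()].
#' @param samples List of [compartment_sample()]s.
#' @param ti_marker_imputed_mg Optional imputed terminal-ileal marker mass,
#'   mg (set by [impute_terminal_marker()], not usually by hand).
#' @return An object of class `animal_record`.
#' @export
animal_record <- function(animal_id, meal, samples,
                          ti_marker_imputed_mg = NULL) {
  stopifnot(length(animal_id) == 1L, inherits(meal, "milk_meal"),
            is.list(samples))
  if (!all(vapply(samples, inherits, logical(1), "compartment_sample")))
    stop("`samples` must be a list of compartment_sample objects",
         call. = FALSE)
  locs <- vapply(samples, `[[`, character(1), "location")
  if (anyDuplicated(locs))
    stop(sprintf("duplicate sample location(s): %s",
                 paste(unique(locs[duplicated(locs)]), collapse = ", ")),
         call. = FALSE)
  names(samples) <- locs
  structure(list(animal_id = as.character(animal_id), meal = meal,
                 samples = samples,
                 ti_marker_imputed_mg = ti_marker_imputed_mg),
            class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record> %s (%s), %d samples: %s\n", x$animal_id,
              x$meal$species, length(x$samples),
              paste(names(x$samples), collapse = ", ")))
  invisible(x)
}

record_sample <- function(record, location) record$samples[[location]]

# TRUE when the terminal-ileal marker concentration was assayed
has_ti_marker <- function(record) {
  s <- record$samples[["TI"]]
  !is.null(s) && !is.na(s$marker_conc)
}

#' Validate an animal record
#'
#' Report-style validation: returns every violation found rather than
#' stopping at the first. A record is usable when the report is empty.
#' Checks presence of the stomach, PSI and DSI samples with both marker and
#' amino-acid concentrations, a terminal-ileum sample (measured or awaiting
#' imputation), large-intestinal marker information, and range constraints.
#'
#' @param record An [animal_record()].
#' @return Character vector of violation messages (length 0 if valid).
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "animal_record"))
  bad <- character(0)
  locs <- names(record$samples)
  for (loc in c("STOMACH", "PSI", "DSI")) {
    s <- record$samples[[loc]]
    if (is.null(s)) {
      bad <- c(bad, sprintf("missing required sample: %s", loc))
      next
    }
    if (is.na(s$marker_conc))
      bad <- c(bad, sprintf("%s: marker concentration missing", loc))
    if (is.null(s$aa_conc))
      bad <- c(bad, sprintf("%s: amino-acid concentrations missing", loc))
  }
  if (!"TI" %in% locs && is.null(record$ti_marker_imputed_mg))
    bad <- c(bad, "missing required sample: TI (and no imputed marker mass)")
  ti <- record$samples[["TI"]]
  if (!is.null(ti) && is.na(ti$marker_conc) &&
      is.null(record$ti_marker_imputed_mg))
    bad <- c(bad, "TI: marker concentration missing (imputation required)")
  if (!any(.LI_LOCATIONS %in% locs))
    bad <- c(bad, "no large-intestinal sample (LI or CECUM/PROX_COLON/DIST_COLON)")
  for (s in record$samples) {
    if (s$digesta_dm < 0)
      bad <- c(bad, sprintf("%s: negative digesta dry matter", s$location))
    if (!is.na(s$marker_conc) && (s$marker_conc < 0 || s$marker_conc > 100))
      bad <- c(bad, sprintf("%s: marker concentration outside [0, 100] %%DM",
                            s$location))
  }
  bad
}
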