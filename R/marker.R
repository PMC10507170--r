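# TiO2 mass ledger: per-location marker masses, cumulative and downstream
# totals, whole-tract recovery, terminal-ileum imputation.
#
# All masses are in mg. A concentration of c %DM in m g of digesta holds
# m * c/100 g = m * c * 10 mg of marker.

#' Marker mass in one compartment sample
#'
#' @param sample A [compartment_sample()] with a measured marker
#'   concentration.
#' @return TiO2 mass, mg: `digesta_dm (g) x marker_conc (%DM) / 100`,
#'   converted to mg.
#' @examples
#' s <- compartment_sample("PSI", digesta_dm = 2, marker_conc = 0.5)
#' marker_mass(s)  # 10 mg
#' @export
marker_mass <- function(sample) {
  stopifnot(inherits(sample, "compartment_sample"))
  if (is.na(sample$marker_conc))
    md_stop(sprintf("marker concentration missing at %s", sample$location),
            "markerdigest_missing_marker")
  sample$digesta_dm * sample$marker_conc / 100 * 1000
}

# summed large-intestinal marker mass (pooled LI or cecum + colon segments)
li_marker_mass <- function(record) {
  locs <- intersect(.LI_LOCATIONS, names(record$samples))
  if (!length(locs))
    md_stop(sprintf("animal %s: no large-intestinal marker data",
                    record$animal_id), "markerdigest_missing_marker")
  sum(vapply(record$samples[locs], marker_mass, numeric(1)))
}

# terminal-ileal marker mass: measured if assayed, else the imputed value
ti_marker_mass <- function(record) {
  if (has_ti_marker(record)) return(marker_mass(record$samples[["TI"]]))
  if (!is.null(record$ti_marker_imputed_mg))
    return(record$ti_marker_imputed_mg)
  md_stop(sprintf(
    "animal %s: terminal-ileal marker missing and not imputed",
    record$animal_id), "markerdigest_missing_marker")
}

#' Build the marker mass ledger for one animal
#'
#' Computes per-location TiO2 masses and, for each small-intestinal
#' location, the cumulative mass up to and including it (`until`) and the
#' mass recovered downstream of it (`after`):
#' `until(PSI) = stomach + PSI`, `after(PSI) = DSI + TI + LI`, and
#' analogously at DSI and the terminal ileum. `until + after` equals the
#' total recovered marker at every location. Whole-tract recovery is the
#' recovered total divided by intake; it is reported but never used to
#' rescale masses.
#'
#' @param record An [animal_record()] whose marker masses are computable
#'   (after imputation if the terminal ileum was not assayed).
#' @return An object of class `marker_ledger`: list with elements `mass`
#'   (named mg vector over STOMACH, PSI, DSI, TI, LI), `until`, `after`
#'   (named over PSI, DSI, TI), `intake` (mg), `recovery` (fraction) and
#'   `ti_imputed` (logical).
#' @export
build_ledger <- function(record) {
  stopifnot(inherits(record, "animal_record"))
  need <- c("STOMACH", "PSI", "DSI")
  for (loc in need)
    if (is.null(record$samples[[loc]]))
      md_stop(sprintf("animal %s: missing %s sample", record$animal_id, loc),
              "markerdigest_missing_marker")
  mass <- c(
    STOMACH = marker_mass(record$samples[["STOMACH"]]),
    PSI = marker_mass(record$samples[["PSI"]]),
    DSI = marker_mass(record$samples[["DSI"]]),
    TI = ti_marker_mass(record),
    LI = li_marker_mass(record)
  )
  until <- c(PSI = unname(mass["STOMACH"] + mass["PSI"]),
             DSI = unname(mass["STOMACH"] + mass["PSI"] + mass["DSI"]),
             TI  = unname(mass["STOMACH"] + mass["PSI"] + mass["DSI"] +
                            mass["TI"]))
  after <- c(PSI = unname(mass["DSI"] + mass["TI"] + mass["LI"]),
             DSI = unname(mass["TI"] + mass["LI"]),
             TI  = unname(mass["LI"]))
  intake <- marker_intake(record$meal)
  structure(list(mass = mass, until = until, after = after, intake = intake,
                 recovery = sum(mass) / intake,
                 ti_imputed = !has_ti_marker(record)),
            class = "marker_ledger")
}

#' @export
print.marker_ledger <- function(x, ...) {
  cat(sprintf("<marker_ledger> intake %.1f mg, recovery %.3f%s\n", x$intake,
              x$recovery, if (x$ti_imputed) " (TI imputed)" else ""))
  print(round(rbind(mass_mg = x$mass), 3))
  invisible(x)
}

#' Impute terminal-ileal marker mass across a cohort
#'
#' Terminal-ileal digesta are often too scant to assay for TiO2. Animals
#' without a measured terminal-ileal marker concentration receive the mean
#' terminal-ileal marker *mass* (mg) of the donor animals that do have one:
#' under `"species_mean"` donors are same-species animals (falling back to
#' the overall mean when a species has none), under `"overall_mean"` all
#' measured animals, and `"fail"` raises an error when any animal needs
#' imputation. Mass rather than concentration is donated because the
#' downstream ledger consumes masses and the dry matter of scant
#' terminal-ileal digesta is itself unreliable.
#'
#' @param cohort List of [animal_record()]s.
#' @param policy Imputation policy.
#' @return The cohort with `ti_marker_imputed_mg` filled in on imputed
#'   animals; animals with measured values are returned unchanged.
#' @export
impute_terminal_marker <- function(cohort,
                                   policy = c("species_mean", "overall_mean",
                                              "fail")) {
  policy <- match.arg(policy)
  stopifnot(is.list(cohort),
            all(vapply(cohort, inherits, logical(1), "animal_record")))
  measured <- vapply(cohort, has_ti_marker, logical(1))
  if (all(measured) || !length(cohort)) return(cohort)
  if (policy == "fail")
    md_stop("terminal-ileal marker missing and policy is 'fail'",
            "markerdigest_no_donor")
  if (!any(measured))
    md_stop("no animal with a measured terminal-ileal marker to donate",
            "markerdigest_no_donor")
  donor_mass <- vapply(cohort[measured], function(r)
    marker_mass(r$samples[["TI"]]), numeric(1))
  donor_species <- vapply(cohort[measured], function(r) r$meal$species,
                          character(1))
  overall <- mean(donor_mass)
  for (i in which(!measured)) {
    sp <- cohort[[i]]$meal$species
    m <- if (policy == "species_mean" && any(donor_species == sp))
      mean(donor_mass[donor_species == sp]) else overall
    cohort[[i]]$ti_marker_imputed_mg <- m
  }
  cohort
}

#' Marker distribution across gut locations
#'
#' Per-location mean and SEM of the percentage of marker intake recovered,
#' across a cohort.
#'
#' @param cohort List of [animal_record()]s (imputation already applied
#'   where needed).
#' @return Data frame with columns `location`, `mean_pct`, `sem_pct`, `n`.
#' @export
marker_distribution <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  pct <- t(vapply(cohort, function(r) {
    led <- build_ledger(r)
    100 * led$mass / led$intake
  }, numeric(5)))
  data.frame(
    location = colnames(pct),
    mean_pct = colMeans(pct),
    sem_pct = apply(pct, 2, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0),
    n = nrow(pct),
    row.names = NULL
  )
}
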