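# Core estimators: gastric amino-acid retention, cumulative apparent
# digestibility at each small-intestinal position, available-AA
# digestibility, and absorbed amount per g protein consumed.
#
# The marker-ratio extrapolation assumes digesta downstream of a sampled
# location carry the same AA:marker ratio as the location itself. The
# contents a position's "unabsorbed" sums over are cumulative: at the 25%
# point it is stomach + PSI + extrapolated outflow past the PSI; at 75% the
# DSI content and its outflow replace the PSI outflow; at 100% analogously
# with the terminal ileum. Values are never clipped: gastric retention may
# exceed 1 (residual protein from earlier meals) and apparent digestibility
# may be negative; available digestibility is undefined (NA) when no intake
# enters the small intestine.

#' Amino-acid mass in one compartment sample
#'
#' @param sample A [compartment_sample()] carrying amino-acid
#'   concentrations.
#' @param aa Canonical key(s); default all analytes in the sample.
#' @return Named mg vector: `digesta_dm (g) x conc (%DM) / 100` in mg.
#' @export
aa_mass <- function(sample, aa = NULL) {
  stopifnot(inherits(sample, "compartment_sample"))
  if (is.null(sample$aa_conc))
    md_stop(sprintf("no amino-acid concentrations at %s", sample$location),
            "markerdigest_missing_analyte")
  conc <- unclass(sample$aa_conc)
  if (is.null(aa)) aa <- names(conc)
  absent <- setdiff(aa, names(conc))
  if (length(absent))
    md_stop(sprintf("analyte(s) %s not assayed at %s",
                    paste(absent, collapse = ", "), sample$location),
            "markerdigest_missing_analyte")
  conc[aa] * sample$digesta_dm / 100 * 1000
}

# per-location AA mass matrix (rows STOMACH/PSI/DSI/TI, cols analytes);
# NA rows where the location was not assayed for AAs
.aa_mass_matrix <- function(record, analytes) {
  locs <- c("STOMACH", "PSI", "DSI", "TI")
  m <- matrix(NA_real_, length(locs), length(analytes),
              dimnames = list(locs, analytes))
  for (loc in locs) {
    s <- record$samples[[loc]]
    if (is.null(s) || is.null(s$aa_conc)) next
    present <- intersect(analytes, names(unclass(s$aa_conc)))
    if (length(present)) m[loc, present] <- aa_mass(s, present)
  }
  m
}

# analytes assayed in every location needed for small-intestinal
# digestibility (stomach, PSI, DSI, TI) and present in the diet
.default_analytes <- function(record) {
  keys <- names(unclass(record$meal$composition))
  for (loc in c("STOMACH", "PSI", "DSI", "TI")) {
    s <- record$samples[[loc]]
    if (is.null(s) || is.null(s$aa_conc)) return(character(0))
    keys <- intersect(keys, names(unclass(s$aa_conc)))
  }
  keys
}

#' Gastric retention ratio
#'
#' mg of an amino acid remaining in the stomach per mg consumed, at the
#' sampling time. Values above 1 are possible (residual protein retained
#' from pre-fast meals) and are preserved, not clipped; [digest_cohort()]
#' flags them.
#'
#' @param record An [animal_record()].
#' @param aa Canonical key(s); default all analytes shared by diet and
#'   stomach sample.
#' @return Named numeric vector of retention ratios.
#' @export
gastric_retention <- function(record, aa = NULL) {
  stopifnot(inherits(record, "animal_record"))
  s <- record$samples[["STOMACH"]]
  if (is.null(s)) md_stop("no stomach sample", "markerdigest_missing_marker")
  intake <- unclass(aa_intake(record$meal))
  if (is.null(aa))
    aa <- intersect(names(intake), names(unclass(s$aa_conc)))
  if (any(intake[aa] <= 0) || anyNA(intake[aa]))
    md_stop("zero or missing dietary intake for requested analyte(s)",
            "markerdigest_zero_intake")
  aa_mass(s, aa) / intake[aa]
}

#' Amino acid released past a small-intestinal location
#'
#' Marker-ratio extrapolation of the amino-acid mass that has flowed beyond
#' a sampled location: `aa_mass(loc) x marker_after(loc) / marker_mass(loc)`,
#' where `marker_after` is the marker recovered downstream of the location.
#'
#' @param record An [animal_record()].
#' @param loc `"PSI"`, `"DSI"` or `"TI"`.
#' @param aa Canonical key(s).
#' @param ledger Optional pre-built [build_ledger()] result.
#' @return Named mg vector.
#' @export
released_after <- function(record, loc, aa = NULL, ledger = NULL) {
  loc <- match.arg(loc, .SI_LOCATIONS)
  ledger <- ledger %||% build_ledger(record)
  if (ledger$mass[loc] <= 0)
    md_stop(sprintf("zero marker mass at %s: extrapolation undefined", loc),
            "markerdigest_zero_marker")
  aa_mass(record$samples[[loc]], aa) * ledger$after[[loc]] / ledger$mass[[loc]]
}

# shared computation behind the per-op accessors and digest_cohort: all
# component masses and derived quantities for one record, vectorized over
# analytes. Returns list of location x analyte matrices / analyte vectors.
.digest_record <- function(record, analytes, ledger = NULL) {
  ledger <- ledger %||% build_ledger(record)
  aam <- .aa_mass_matrix(record, analytes)
  intake <- unclass(aa_intake(record$meal))[analytes]
  prot <- protein_consumed(record$meal)
  locs <- .SI_LOCATIONS
  unabsorbed <- released <- matrix(NA_real_, length(locs), length(analytes),
                                   dimnames = list(locs, analytes))
  cum <- aam["STOMACH", , drop = TRUE]
  for (loc in locs) {
    cum <- cum + aam[loc, ]
    rel <- if (ledger$mass[[loc]] > 0)
      aam[loc, ] * ledger$after[[loc]] / ledger$mass[[loc]]
    else rep(NA_real_, length(analytes))
    released[loc, ] <- rel
    unabsorbed[loc, ] <- cum + rel
  }
  # row subsetting drops names for length-1 results; restore them
  stomach <- stats::setNames(aam["STOMACH", ], colnames(aam))
  entering <- intake - stomach
  apparent <- sweep(-unabsorbed, 2, intake, `+`)
  apparent <- sweep(apparent, 2, intake, `/`) * 100
  unabs_avail <- sweep(unabsorbed, 2, stomach, `-`)
  available <- sweep(-unabs_avail, 2, entering, `+`)
  available <- sweep(available, 2, entering, `/`) * 100
  available[, entering <= 0] <- NA_real_
  absorbed <- sweep(-unabsorbed, 2, intake, `+`) / prot
  list(ledger = ledger, intake = intake, stomach = stomach,
       entering = entering, retention = stomach / intake,
       released = released, unabsorbed = unabsorbed, apparent = apparent,
       available = available, absorbed = absorbed)
}

#' Apparent amino-acid digestibility at a small-intestinal position
#'
#' Cumulative disappearance of a dietary amino acid up to a fractional
#' small-intestinal position, as a percentage of intake:
#' `100 x (intake - unabsorbed) / intake`, where `unabsorbed` sums the
#' stomach content, every small-intestinal compartment content up to and
#' including the position's segment, and the marker-extrapolated outflow
#' past it. May be negative; bounded above by 100.
#'
#' @inheritParams released_after
#' @return Named percentage vector.
#' @examples
#' rec <- simulate_cohort(sim_config(n_per_species = 1, noise_sd = 0,
#'                                   seed = 1))$cohort[[1]]
#' apparent_digestibility(rec, "PSI", "LEU")
#' @export
apparent_digestibility <- function(record, loc, aa = NULL, ledger = NULL) {
  loc <- match.arg(loc, .SI_LOCATIONS)
  if (is.null(aa)) aa <- .default_analytes(record)
  d <- .digest_record(record, aa, ledger)
  d$apparent[loc, ]
}

#' Apparent digestibility of amino acids available for uptake
#'
#' Digestibility computed on the fraction of intake that has left the
#' stomach (uptake occurs only in the small intestine): the dietary intake
#' and the unabsorbed mass are both corrected for the gastric content.
#' Undefined (`NA`) when nothing has entered the small intestine
#' (retention >= 1). Satisfies
#' `apparent = available x (1 - retention)` exactly.
#'
#' @inheritParams released_after
#' @return Named percentage vector.
#' @export
available_digestibility <- function(record, loc, aa = NULL, ledger = NULL) {
  loc <- match.arg(loc, .SI_LOCATIONS)
  if (is.null(aa)) aa <- .default_analytes(record)
  d <- .digest_record(record, aa, ledger)
  d$available[loc, ]
}

#' Apparent amount absorbed per g protein consumed
#'
#' `(intake - unabsorbed) / protein consumed`, mg amino acid per g protein.
#' Negative disappearance (e.g. lysine with over-unity gastric retention)
#' passes through unchanged.
#'
#' @inheritParams released_after
#' @return Named mg/g vector.
#' @export
absorbed_per_g_protein <- function(record, loc, aa = NULL, ledger = NULL) {
  loc <- match.arg(loc, .SI_LOCATIONS)
  if (is.null(aa)) aa <- .default_analytes(record)
  d <- .digest_record(record, aa, ledger)
  d$absorbed[loc, ]
}

#' Digest a cohort: full long-format digestibility table
#'
#' Runs the complete estimator chain for every animal, individual analyte
#' and small-intestinal position, plus group rows. Group quantities are
#' computed on summed member masses at every stage (intake, stomach,
#' compartment contents, extrapolated outflow) — never as means of member
#' digestibilities. Per-row problems (zero marker mass, non-positive
#' entering mass) become `NA` values with flags; the run continues.
#'
#' @param cohort List of [animal_record()]s (terminal-ileum imputation
#'   already applied where needed, see [impute_terminal_marker()]).
#' @param groups Named list of group member vectors ([aa_groups()] by
#'   default), or `NULL` for no group rows.
#' @param analytes Canonical keys to digest; default: analytes assayed in
#'   every small-intestinal location of each animal.
#' @param group_policy `"strict"` drops no member silently: an error is
#'   raised if a group member is not among the analytes; `"skip"` sums the
#'   members present.
#' @return Data frame, one row per animal x analyte x location:
#'   `animal_id`, `species`, `analyte`, `location`, `si_position`,
#'   `intake_mg`, `stomach_mg`, `entering_mg`, `retention_ratio`,
#'   `unabsorbed_mg`, `released_after_mg`, `apparent_dig_pct`,
#'   `available_dig_pct`, `absorbed_mg_per_g_protein`, `flags`.
#' @export
digest_cohort <- function(cohort, groups = aa_groups(), analytes = NULL,
                          group_policy = c("strict", "skip")) {
  group_policy <- match.arg(group_policy)
  stopifnot(is.list(cohort),
            all(vapply(cohort, inherits, logical(1), "animal_record")))
  if (!is.null(groups)) .check_groups(groups)
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    record <- cohort[[i]]
    aas <- analytes %||% .default_analytes(record)
    if (!length(aas))
      stop(sprintf("animal %s: no analyte assayed across all locations",
                   record$animal_id), call. = FALSE)
    d <- .digest_record(record, aas)
    mats <- list(intake = rbind(d$intake), stomach = rbind(d$stomach),
                 entering = rbind(d$entering), retention = rbind(d$retention),
                 released = d$released, unabsorbed = d$unabsorbed,
                 apparent = d$apparent, available = d$available,
                 absorbed = d$absorbed)
    cols <- aas
    if (!is.null(groups) && length(groups)) {
      for (nm in names(groups)) {
        members <- groups[[nm]]
        absent <- setdiff(members, aas)
        if (length(absent)) {
          if (group_policy == "strict")
            md_stop(sprintf(
              "animal %s: group '%s' member(s) not digested: %s",
              record$animal_id, nm, paste(absent, collapse = ", ")),
              "markerdigest_missing_member")
          members <- setdiff(members, absent)
        }
        # summed-mass group: sum every mass component, then re-derive the
        # ratio statistics from the summed masses
        gi <- sum(d$intake[members]); gs <- sum(d$stomach[members])
        grel <- rowSums(d$released[, members, drop = FALSE])
        gun <- rowSums(d$unabsorbed[, members, drop = FALSE])
        gav <- if (gi - gs > 0)
          100 * ((gi - gs) - (gun - gs)) / (gi - gs)
        else rep(NA_real_, 3)
        mats$intake <- cbind(mats$intake, gi)
        mats$stomach <- cbind(mats$stomach, gs)
        mats$entering <- cbind(mats$entering, gi - gs)
        mats$retention <- cbind(mats$retention, gs / gi)
        mats$released <- cbind(mats$released, grel)
        mats$unabsorbed <- cbind(mats$unabsorbed, gun)
        mats$apparent <- cbind(mats$apparent, 100 * (gi - gun) / gi)
        mats$available <- cbind(mats$available, gav)
        mats$absorbed <- cbind(mats$absorbed,
                               (gi - gun) / protein_consumed(record$meal))
        cols <- c(cols, nm)
      }
    }
    locs <- .SI_LOCATIONS
    n_a <- length(cols)
    flag_base <- if (d$ledger$ti_imputed) "ti_imputed" else ""
    rows <- data.frame(
      animal_id = record$animal_id,
      species = record$meal$species,
      analyte = rep(cols, each = length(locs)),
      location = rep(locs, n_a),
      si_position = rep(unname(si_positions()[locs]), n_a),
      intake_mg = rep(as.numeric(mats$intake), each = length(locs)),
      stomach_mg = rep(as.numeric(mats$stomach), each = length(locs)),
      entering_mg = rep(as.numeric(mats$entering), each = length(locs)),
      retention_ratio = rep(as.numeric(mats$retention), each = length(locs)),
      unabsorbed_mg = as.numeric(mats$unabsorbed),
      released_after_mg = as.numeric(mats$released),
      apparent_dig_pct = as.numeric(mats$apparent),
      available_dig_pct = as.numeric(mats$available),
      absorbed_mg_per_g_protein = as.numeric(mats$absorbed),
      stringsAsFactors = FALSE
    )
    flags <- character(nrow(rows))
    add_flag <- function(flags, idx, tag) {
      idx <- which(idx)
      flags[idx] <- ifelse(nzchar(flags[idx]), paste0(flags[idx], ",", tag),
                           tag)
      flags
    }
    flags <- add_flag(flags, rows$retention_ratio > 1, "over_unity_retention")
    flags <- add_flag(flags, is.na(rows$unabsorbed_mg) &
                        rep(d$ledger$mass[locs] <= 0, n_a), "zero_marker")
    flags <- add_flag(flags, rows$entering_mg <= 0, "entering_nonpositive")
    if (nzchar(flag_base))
      flags <- ifelse(nzchar(flags), paste0(flags, ",", flag_base), flag_base)
    rows$flags <- flags
    out[[i]] <- rows
  }
  do.call(rbind, out)
}
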