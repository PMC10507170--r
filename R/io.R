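# CSV/TSV readers and writers and the top-level pipeline.
#
# Inputs are CSV (spreadsheet provenance of nutrition trial data), outputs
# TSV mirroring table layouts; UTF-8, "." decimal separator. Every output
# file starts with a comment line carrying the package version, a config
# fingerprint and the seed, so a run is traceable from its artifacts.
# Reported percentages are rendered to 1 decimal and retention ratios to
# 2 decimals; full-precision values are kept in paired *_raw columns.

.pkg_version <- function()
  as.character(utils::packageVersion("markerdigest"))

.out_header <- function(hash, seed) {
  sprintf("# markerdigest %s config_hash=%s seed=%s", .pkg_version(),
          hash %||% "none", seed %||% "none")
}

.write_tsv <- function(df, path, hash = NULL, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.out_header(hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_table <- function(path, sep) {
  if (!file.exists(path))
    md_stop(sprintf("input file not found: %s", path), "markerdigest_io")
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# render numeric columns with 17 significant digits so CSV round-trips
# reproduce every numeric field exactly
.fmt_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      v <- df[[j]]
      out <- sprintf("%.17g", v)
      out[is.na(v)] <- ""
      df[[j]] <- out
    }
  }
  df
}

# resolve aa_<label>_<suffix> headers to canonical keys
.aa_columns <- function(cols, suffix) {
  pat <- paste0("^aa_(.+)_", suffix, "$")
  hit <- grep(pat, cols, value = TRUE)
  stats::setNames(hit, canonicalize_aa_name(sub(pat, "\\1", hit)))
}

#' Write a cohort to the animals/meals CSV schemas
#'
#' `animals.csv` holds one row per animal x location (`animal_id`,
#' `species`, `body_weight_kg`, `location`, `digesta_dm_g`, `tio2_pct_dm`,
#' one `aa_<KEY>_pct_dm` column per analyte; blank = not assayed).
#' `meals.csv` holds one row per species (`species`,
#' `fresh_milk_g_per_kg_bw`, `protein_g_per_kg_bw`, `meal_dm_g`,
#' `tio2_mg_per_g_dm`, one `aa_<KEY>_mg_per_g_protein` column per analyte).
#'
#' @param cohort List of [animal_record()]s.
#' @param animals_path,meals_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, animals_path, meals_path) {
  stopifnot(length(cohort) > 0)
  keys <- sort(unique(unlist(lapply(cohort, function(r)
    names(unclass(r$meal$composition))))))
  rows <- list()
  for (r in cohort) for (s in r$samples) {
    row <- data.frame(animal_id = r$animal_id, species = r$meal$species,
                      body_weight_kg = r$meal$body_weight,
                      location = s$location, digesta_dm_g = s$digesta_dm,
                      tio2_pct_dm = s$marker_conc, stringsAsFactors = FALSE)
    conc <- if (is.null(s$aa_conc)) numeric(0) else unclass(s$aa_conc)
    for (k in keys)
      row[[paste0("aa_", k, "_pct_dm")]] <-
        if (k %in% names(conc)) conc[[k]] else NA_real_
    rows[[length(rows) + 1L]] <- row
  }
  animals <- do.call(rbind, rows)
  utils::write.csv(.fmt_num_df(animals), animals_path, row.names = FALSE,
                   na = "", quote = FALSE)

  first <- cohort[!duplicated(vapply(cohort, function(r) r$meal$species,
                                     character(1)))]
  mrows <- lapply(first, function(r) {
    m <- r$meal
    row <- data.frame(species = m$species,
                      fresh_milk_g_per_kg_bw = NA_real_,
                      protein_g_per_kg_bw = m$protein_dose,
                      meal_dm_g = m$meal_dm,
                      tio2_mg_per_g_dm = m$marker_dose,
                      stringsAsFactors = FALSE)
    comp <- unclass(m$composition)
    for (k in keys)
      row[[paste0("aa_", k, "_mg_per_g_protein")]] <-
        if (k %in% names(comp)) comp[[k]] else NA_real_
    row
  })
  utils::write.csv(.fmt_num_df(do.call(rbind, mrows)), meals_path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(c(animals_path, meals_path))
}

#' Read a cohort from the animals/meals CSV schemas
#'
#' Amino-acid column headers are resolved through [canonicalize_aa_name()],
#' so `aa_Asp_pct_dm` and `aa_Asparagine_pct_dm` land on the same analyte.
#' Blank cells are missing values. Schema violations (negative masses,
#' out-of-range concentrations, duplicate animal x location rows, unknown
#' locations, meals missing for a species) raise errors naming the row.
#'
#' @param animals_path,meals_path Input CSV paths (see
#'   [write_cohort_csv()] for the schemas).
#' @return List of [animal_record()]s.
#' @export
read_cohort <- function(animals_path, meals_path) {
  animals <- .read_table(animals_path, sep = ",")
  meals <- .read_table(meals_path, sep = ",")
  need_a <- c("animal_id", "species", "body_weight_kg", "location",
              "digesta_dm_g", "tio2_pct_dm")
  need_m <- c("species", "protein_g_per_kg_bw", "meal_dm_g",
              "tio2_mg_per_g_dm")
  if (length(miss <- setdiff(need_a, names(animals))))
    md_stop(sprintf("animals.csv missing column(s): %s",
                    paste(miss, collapse = ", ")), "markerdigest_io")
  if (length(miss <- setdiff(need_m, names(meals))))
    md_stop(sprintf("meals.csv missing column(s): %s",
                    paste(miss, collapse = ", ")), "markerdigest_io")
  if (anyDuplicated(meals$species))
    md_stop("meals.csv: duplicate species row", "markerdigest_io")
  dup <- duplicated(animals[c("animal_id", "location")])
  if (any(dup))
    md_stop(sprintf("animals.csv: duplicate animal x location at row(s) %s",
                    paste(which(dup), collapse = ", ")), "markerdigest_io")
  bad <- which(!is.na(animals$digesta_dm_g) & animals$digesta_dm_g < 0)
  if (length(bad))
    md_stop(sprintf("animals.csv: negative digesta_dm_g at row %d (animal %s, %s)",
                    bad[1], animals$animal_id[bad[1]],
                    animals$location[bad[1]]), "markerdigest_io")
  aa_cols_a <- .aa_columns(names(animals), "pct_dm")
  aa_cols_m <- .aa_columns(names(meals), "mg_per_g_protein")

  records <- list()
  for (id in unique(animals$animal_id)) {
    sub <- animals[animals$animal_id == id, , drop = FALSE]
    sp <- sub$species[1]
    mrow <- meals[meals$species == sp, , drop = FALSE]
    if (!nrow(mrow))
      md_stop(sprintf("meals.csv: no meal for species '%s' (animal %s)",
                      sp, id), "markerdigest_io")
    comp_all <- unlist(mrow[1, aa_cols_m, drop = FALSE])
    names(comp_all) <- names(aa_cols_m)
    comp_v <- comp_all[!is.na(comp_all)]
    meal <- milk_meal(sp, sub$body_weight_kg[1],
                      mrow$protein_g_per_kg_bw[1], mrow$tio2_mg_per_g_dm[1],
                      mrow$meal_dm_g[1],
                      aa_profile(comp_v, "mg_per_g_protein"))
    samples <- lapply(seq_len(nrow(sub)), function(i) {
      conc <- unlist(sub[i, aa_cols_a, drop = FALSE])
      names(conc) <- names(aa_cols_a)
      keep <- !is.na(conc)
      prof <- if (any(keep))
        aa_profile(conc[keep], "pct_DM")
      else NULL
      compartment_sample(sub$location[i], sub$digesta_dm_g[i],
                         sub$tio2_pct_dm[i], prof)
    })
    records[[id]] <- animal_record(id, meal, samples)
  }
  unname(records)
}

#' Write the ground-truth table of a simulated cohort
#' @param truth Truth data frame from [simulate_cohort()].
#' @param path Output TSV path.
#' @param hash,seed Provenance fields for the header comment.
#' @return Invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path, hash = NULL, seed = NULL)
  invisible(.write_tsv(truth, path, hash, seed))

#' Write the per-animal marker ledger table
#'
#' One row per animal x location: marker mass, percent of intake, the
#' cumulative (`until_mg`) and downstream (`after_mg`) totals for
#' small-intestinal locations, whole-tract recovery and the imputation
#' flag.
#'
#' @param cohort List of [animal_record()]s (imputation applied).
#' @param path Output TSV path.
#' @param hash,seed Provenance fields for the header comment.
#' @return The table, invisibly.
#' @export
write_ledger_tsv <- function(cohort, path, hash = NULL, seed = NULL) {
  rows <- list()
  for (r in cohort) {
    led <- build_ledger(r)
    for (loc in names(led$mass)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = r$animal_id, species = r$meal$species, location = loc,
        marker_mg = led$mass[[loc]],
        pct_of_intake = 100 * led$mass[[loc]] / led$intake,
        until_mg = if (loc %in% names(led$until)) led$until[[loc]]
        else NA_real_,
        after_mg = if (loc %in% names(led$after)) led$after[[loc]]
        else NA_real_,
        recovery = led$recovery,
        imputed = loc == "TI" && led$ti_imputed,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  .write_tsv(tab, path, hash, seed)
  invisible(tab)
}

#' Write the digestibility table
#'
#' Renders percentages to 1 decimal and retention ratios to 2 decimals
#' (table convention) while keeping full precision in paired `*_raw`
#' columns.
#'
#' @param digest Long data frame from [digest_cohort()].
#' @param path Output TSV path.
#' @param hash,seed Provenance fields for the header comment.
#' @return The rendered table, invisibly.
#' @export
write_digestibility_tsv <- function(digest, path, hash = NULL, seed = NULL) {
  out <- digest
  for (col in c("apparent_dig_pct", "available_dig_pct")) {
    out[[paste0(col, "_raw")]] <- out[[col]]
    out[[col]] <- round(out[[col]], 1)
  }
  out$retention_ratio_raw <- out$retention_ratio
  out$retention_ratio <- round(out$retention_ratio, 2)
  .write_tsv(out, path, hash, seed)
  invisible(out)
}

#' Read a run configuration from YAML
#'
#' Schema (all fields optional unless noted): `out_dir` (required for
#' [run_pipeline()]), `seed`, `animals`/`meals` (input CSV paths; when
#' absent a cohort is simulated), `sim` (any [sim_config()] argument),
#' `imputation_policy` (`species_mean`/`overall_mean`/`fail`), `groups`
#' (name -> member list overriding [aa_groups()]), `include_proline`
#' (logical, NEAA membership), `alpha`, `response` (column compared across
#' milks, default `apparent_dig_pct`).
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg %||% list(), class = "run_config")
}

#' Run the full pipeline
#'
#' simulate (or read) -> validate -> impute -> marker ledger -> digest ->
#' summarize -> compare, writing `animals.csv`/`meals.csv`/`truth.tsv`
#' (simulated runs), `marker_ledger.tsv`, `marker_distribution.tsv`,
#' `digestibility.tsv`, `comparisons.tsv` and `run_log.txt` into
#' `config$out_dir`. Deterministic for a fixed config and seed.
#'
#' @param config A `run_config` list (see [read_run_config()]), or a path
#'   to a YAML file.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir))
    md_stop("config$out_dir is required", "markerdigest_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # fingerprint the scientific configuration, not filesystem paths
  hash <- config_hash(config[setdiff(names(config),
                                     c("out_dir", "animals", "meals"))])
  seed <- config$seed
  log <- c(.out_header(hash, seed),
           utils::capture.output(utils::str(unclass(config))))

  if (!is.null(config$animals)) {
    cohort <- read_cohort(config$animals, config$meals)
  } else {
    sim_args <- config$sim %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    cohort <- sim$cohort
    write_cohort_csv(cohort, file.path(config$out_dir, "animals.csv"),
                     file.path(config$out_dir, "meals.csv"))
    write_truth_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"),
                    hash, seed)
    log <- c(log, sprintf("simulated %d animals", length(cohort)))
  }

  issues <- unlist(lapply(cohort, function(r) {
    v <- validate_record(r)
    if (length(v)) paste0(r$animal_id, ": ", v) else character(0)
  }))
  # TI-related findings are expected pre-imputation; anything else is fatal
  fatal <- issues[!grepl("TI", issues)]
  if (length(fatal))
    md_stop(paste(c("invalid cohort:", fatal), collapse = "\n"),
            "markerdigest_io")
  if (length(issues)) log <- c(log, paste("note:", issues))

  cohort <- impute_terminal_marker(
    cohort, policy = config$imputation_policy %||% "species_mean")

  write_ledger_tsv(cohort, file.path(config$out_dir, "marker_ledger.tsv"),
                   hash, seed)
  .write_tsv(marker_distribution(cohort),
             file.path(config$out_dir, "marker_distribution.tsv"),
             hash, seed)

  groups <- config$groups %||% aa_groups(isTRUE(config$include_proline))
  if (!inherits(groups, "list")) groups <- as.list(groups)
  groups <- lapply(groups, function(g) canonicalize_aa_name(unlist(g)))
  dig <- digest_cohort(cohort, groups = groups)
  write_digestibility_tsv(dig, file.path(config$out_dir,
                                         "digestibility.tsv"), hash, seed)

  alpha <- config$alpha %||% 0.05
  response <- config$response %||% "apparent_dig_pct"
  if (length(unique(dig$species)) < 2) {
    log <- c(log, "single-species cohort: comparison tables skipped")
    writeLines(c(log, sprintf("wrote outputs to %s", config$out_dir)),
               file.path(config$out_dir, "run_log.txt"))
    return(invisible(config$out_dir))
  }
  comps <- compare_cohort(dig, response = response, alpha = alpha)
  crow <- lapply(names(comps), function(a) {
    cp <- comps[[a]]
    sp <- cp$species
    data.frame(analyte = a,
               level = c(sp$level, cp$location$level),
               factor = c(rep("species", nrow(sp)),
                          rep("location", nrow(cp$location))),
               mean = round(c(sp$mean, cp$location$mean), 1),
               sem = round(c(sp$sem, cp$location$sem), 2),
               letter = c(sp$letter, cp$location$letter),
               p_species = cp$p_species, p_location = cp$p_location,
               interaction_retained = cp$interaction_retained,
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, crow),
             file.path(config$out_dir, "comparisons.tsv"), hash, seed)

  writeLines(c(log, sprintf("wrote outputs to %s", config$out_dir)),
             file.path(config$out_dir, "run_log.txt"))
  invisible(config$out_dir)
}
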