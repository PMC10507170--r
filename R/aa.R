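# Amino-acid naming, profiles, and group aggregation.
#
# Acid hydrolysis converts the amides asparagine and glutamine to aspartate
# and glutamate, so digesta assays report the pooled analytes ASX and GLX.
# Milk composition tables labelled "Asparagine"/"Glutamine" and digesta
# tables labelled "Asp"/"Glu" therefore describe the same analytes; the
# synonym map below collapses both spellings onto the pooled keys.

.AA_KEYS <- c("ILE", "LEU", "VAL", "HIS", "LYS", "MET", "PHE", "THR", "TRP",
              "ALA", "ARG", "ASX", "GLX", "CYS", "SER", "TYR", "PRO")

.aa_synonym_table <- function() {
  syn <- list(
    ILE = c("ILE", "ISOLEUCINE", "I"),
    LEU = c("LEU", "LEUCINE", "L"),
    VAL = c("VAL", "VALINE", "V"),
    HIS = c("HIS", "HISTIDINE", "H"),
    LYS = c("LYS", "LYSINE", "K"),
    MET = c("MET", "METHIONINE", "M"),
    PHE = c("PHE", "PHENYLALANINE", "F"),
    THR = c("THR", "THREONINE", "T"),
    TRP = c("TRP", "TRYPTOPHAN", "W"),
    ALA = c("ALA", "ALANINE", "A"),
    ARG = c("ARG", "ARGININE", "R"),
    ASX = c("ASX", "ASP", "ASN", "ASPARAGINE", "ASPARTATE", "ASPARTIC ACID",
            "ASP+ASN"),
    GLX = c("GLX", "GLU", "GLN", "GLUTAMINE", "GLUTAMATE", "GLUTAMIC ACID",
            "GLU+GLN"),
    CYS = c("CYS", "CYSTEINE", "CYSTINE", "C"),
    SER = c("SER", "SERINE", "S"),
    TYR = c("TYR", "TYROSINE", "Y"),
    PRO = c("PRO", "PROLINE", "P")
  )
  key <- rep(names(syn), lengths(syn))
  names(key) <- unlist(syn, use.names = FALSE)
  key
}

.AA_SYNONYMS <- .aa_synonym_table()

#' Canonical amino-acid keys
#'
#' The closed set of analyte keys used throughout the package. `ASX` and
#' `GLX` are the pooled aspartate+asparagine and glutamate+glutamine
#' analytes measurable after acid hydrolysis.
#'
#' @return Character vector of canonical keys.
#' @export
aa_keys <- function() .AA_KEYS

#' Canonicalize an amino-acid name
#'
#' Maps free-text amino-acid labels (full names, three-letter codes,
#' one-letter codes, amide or acid spellings) onto the canonical key set,
#' case-insensitively. `"Asparagine"` and `"Asp"` both map to `ASX`,
#' `"Glutamine"` and `"Glu"` to `GLX`.
#'
#' @param raw_name Character vector of names to resolve.
#' @return Character vector of canonical keys (see [aa_keys()]).
#' @examples
#' canonicalize_aa_name(c("Asparagine", "Asp", "ILE", "leucine"))
#' @export
canonicalize_aa_name <- function(raw_name) {
  if (length(raw_name) == 0L) return(character(0))
  if (!is.character(raw_name) || anyNA(raw_name) || any(!nzchar(raw_name)))
    stop("amino-acid names must be non-empty strings", call. = FALSE)
  up <- toupper(trimws(raw_name))
  hit <- .AA_SYNONYMS[up]
  if (anyNA(hit)) {
    bad <- unique(raw_name[is.na(hit)])
    stop(md_condition(
      sprintf("unknown amino-acid name(s): %s. Accepted names: %s",
              paste(sQuote(bad), collapse = ", "),
              paste(sort(names(.AA_SYNONYMS)), collapse = ", ")),
      "markerdigest_unknown_aa"))
  }
  unname(hit)
}

#' Default physiological amino-acid groups
#'
#' Group definitions used for summed-mass digestibility: branched-chain
#' (BCAA), essential (EAA), long neutral (LNAA) and non-essential (NEAA)
#' amino acids. Membership of LNAA and NEAA varies between laboratories;
#' these defaults can be overridden by supplying any named list of canonical
#' keys to the aggregation and digestion functions. Proline is excluded
#' from NEAA by default and can be added with `include_proline`.
#'
#' @param include_proline Logical; add `PRO` to the NEAA group.
#' @return Named list of character vectors of canonical keys.
#' @examples
#' aa_groups()$BCAA
#' @export
aa_groups <- function(include_proline = FALSE) {
  bcaa <- c("ILE", "LEU", "VAL")
  g <- list(
    BCAA = bcaa,
    EAA  = c(bcaa, "HIS", "LYS", "MET", "PHE", "THR", "TRP"),
    NEAA = c("ALA", "ARG", "ASX", "CYS", "GLX", "SER", "TYR"),
    LNAA = c("ILE", "LEU", "VAL", "PHE", "TRP", "TYR")
  )
  if (include_proline) g$NEAA <- c(g$NEAA, "PRO")
  g
}

.check_groups <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named list of amino-acid key vectors",
         call. = FALSE)
  for (nm in names(groups)) {
    bad <- setdiff(groups[[nm]], .AA_KEYS)
    if (length(bad))
      stop(sprintf("group '%s' contains non-canonical keys: %s",
                   nm, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(groups)
}

#' Construct an amino-acid profile
#'
#' A named non-negative numeric vector of amino-acid quantities on a single
#' declared basis. Names are resolved through [canonicalize_aa_name()], so
#' `"Asparagine"` and `"Asp"` land on the same key. Arithmetic across
#' different bases is rejected by the consuming functions.
#'
#' @param values Named numeric vector; names are amino-acid labels.
#' @param basis One of `"mg_per_g_protein"`, `"pct_DM"`, `"mg_total"`.
#' @return An object of class `aa_profile`: a named numeric vector with a
#'   `basis` attribute, keyed by canonical amino-acid keys.
#' @examples
#' aa_profile(c(Isoleucine = 30.1, Leu = 52.4), basis = "mg_per_g_protein")
#' @export
aa_profile <- function(values, basis = c("mg_per_g_protein", "pct_DM",
                                         "mg_total")) {
  basis <- match.arg(basis)
  if (!is.numeric(values) || is.null(names(values)))
    stop("`values` must be a named numeric vector", call. = FALSE)
  keys <- canonicalize_aa_name(names(values))
  if (anyDuplicated(keys))
    stop(sprintf("duplicate analytes after canonicalization: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  v <- as.numeric(values)
  if (any(!is.finite(v)) || any(v < 0))
    stop("profile quantities must be finite and >= 0", call. = FALSE)
  names(v) <- keys
  structure(v, basis = basis, class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat(sprintf("<aa_profile> %d analytes, basis = %s\n", length(x),
              attr(x, "basis")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Basis of an amino-acid profile
#' @param profile An [aa_profile()].
#' @return The basis string.
#' @export
aa_basis <- function(profile) attr(profile, "basis")

#' Sum an amino-acid profile over groups
#'
#' Group quantities are the sums of the member quantities on the same basis
#' (group digestibility downstream is computed on summed masses, never on
#' means of member digestibilities).
#'
#' @param profile An [aa_profile()].
#' @param groups Named list of member key vectors, e.g. [aa_groups()].
#' @param missing `"strict"` errors on a group member absent from the
#'   profile; `"skip"` sums the members that are present.
#' @return Named numeric vector of group sums with a `basis` attribute.
#' @examples
#' p <- aa_profile(c(ILE = 37.0, LEU = 74.1, VAL = 42.9),
#'                 basis = "mg_per_g_protein")
#' aggregate_groups(p, aa_groups()["BCAA"])
#' @export
aggregate_groups <- function(profile, groups = aa_groups(),
                             missing = c("strict", "skip")) {
  missing <- match.arg(missing)
  if (!inherits(profile, "aa_profile"))
    stop("`profile` must be an aa_profile", call. = FALSE)
  .check_groups(groups)
  out <- vapply(names(groups), function(nm) {
    members <- groups[[nm]]
    absent <- setdiff(members, names(profile))
    if (length(absent) && missing == "strict")
      stop(md_condition(
        sprintf("group '%s' member(s) missing from profile: %s",
                nm, paste(absent, collapse = ", ")),
        "markerdigest_missing_member"))
    sum(unclass(profile)[intersect(members, names(profile))])
  }, numeric(1))
  structure(out, basis = aa_basis(profile))
}
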