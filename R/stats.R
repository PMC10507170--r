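# Cohort summaries and simplified group comparisons: means +/- SEM,
# one-way ANOVA with Tukey HSD letters, and a blocked (split-plot)
# two-factor model with the drop-nonsignificant-interaction rule.
#
# These are deliberately simplified reanalyses: the original mixed-model
# machinery with REML covariance-structure selection is replaced by a
# fixed blocked ANOVA with the animal as block, so outputs are labelled
# accordingly and are not expected to reproduce any particular published
# p-value.

#' Group means and standard errors
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length.
#' @return Data frame: `group`, `n`, `mean`, `sem` (`sd/sqrt(n)`; 0 with a
#'   `singleton` flag column when a group has one observation).
#' @export
describe <- function(values, group) {
  stopifnot(length(values) == length(group), length(values) > 0)
  g <- factor(group)
  if (any(tabulate(g) == 0)) g <- droplevels(g)
  n <- as.integer(table(g))
  mean_ <- tapply(values, g, mean)
  sem <- tapply(values, g, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  data.frame(group = levels(g), n = n, mean = as.numeric(mean_),
             sem = as.numeric(sem), singleton = n == 1L, row.names = NULL)
}

# maximal cliques (Bron-Kerbosch) of the "not significantly different"
# graph; the compact letter display assigns one letter per clique
.maximal_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- setdiff(which(adj[v, ]), v)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

# letters from a pairwise p-value matrix: levels in a common maximal clique
# of "p > alpha" share a letter; cliques ordered by their best (largest)
# mean so 'a' marks the top group
.cld <- function(means, pmat, alpha) {
  k <- length(means)
  if (k == 1L) return(stats::setNames("a", names(means)))
  adj <- pmat > alpha
  diag(adj) <- TRUE
  cliques <- .maximal_cliques(adj)
  best <- vapply(cliques, function(cl) max(means[cl]), numeric(1))
  cliques <- cliques[order(-best)]
  letters_out <- rep("", k)
  for (i in seq_along(cliques))
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]],
                                        letters[i])
  stats::setNames(letters_out, names(means))
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Fits `values ~ group` by [stats::aov()], reports the overall F-test
#' p-value, and renders pairwise Tukey HSD decisions at level `alpha` as a
#' compact letter display (levels without a common letter differ). When
#' the residual variance is zero the fit is flagged degenerate and the
#' pairwise decision falls back to equality of means.
#'
#' @param values Numeric response.
#' @param group Grouping vector (>= 2 groups, each with >= 2 observations
#'   for a non-degenerate test).
#' @param alpha Significance level for the letter display.
#' @return Object of class `comparison_table`: data frame `level`, `n`,
#'   `mean`, `sem`, `letter`, with attributes `p_value`, `pairwise_p`
#'   (matrix), `alpha`, `degenerate`.
#' @examples
#' set.seed(1)
#' oneway_tukey(c(rnorm(4), rnorm(4, 10)), rep(c("a", "b"), each = 4))
#' @export
oneway_tukey <- function(values, group, alpha = 0.05) {
  g <- droplevels(factor(group))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1]]
  mse <- .aov_cell(sm, "Residuals", "Mean Sq")
  # residual variance at rounding-noise level relative to the data spread
  # means every group is internally constant: flag as degenerate
  ss_tot <- sum((values - mean(values))^2)
  degenerate <- !is.finite(mse) || mse <= 0 ||
    sum(stats::residuals(fit)^2) <= 1e-12 * max(ss_tot, 1e-300)
  p_f <- if (degenerate) NA_real_ else .aov_cell(sm, "g", "Pr(>F)")
  means <- tapply(values, g, mean)
  lev <- levels(g)
  pmat <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  if (!degenerate) {
    tk <- stats::TukeyHSD(fit, "g")$g
    pairs_ <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs_)) {
      a <- pairs_[[i]][1]; b <- pairs_[[i]][2]
      pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
    }
  } else {
    # zero residual variance: any difference in means is a difference
    for (a in lev) for (b in lev)
      pmat[a, b] <- if (isTRUE(all.equal(means[[a]], means[[b]]))) 1 else 0
  }
  desc <- describe(values, g)
  desc$letter <- unname(.cld(means, pmat, alpha)[desc$group])
  names(desc)[1] <- "level"
  structure(desc[c("level", "n", "mean", "sem", "letter")],
            p_value = p_f, pairwise_p = pmat, alpha = alpha,
            degenerate = degenerate, class = c("comparison_table",
                                               "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> F-test p = %s%s\n",
              format.pval(attr(x, "p_value")),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate variance)"
              else ""))
  print.data.frame(x, ...)
  invisible(x)
}

# aov summary tables pad their row names with spaces
.aov_cell <- function(tab, row, col) {
  i <- match(row, trimws(rownames(tab)))
  if (is.na(i)) return(NA_real_)
  tab[i, col]
}

# Tukey-Kramer pairwise p-value matrix given cell means, per-level counts,
# an error mean square and its df
.tukey_pmat <- function(means, ns, ms, df, k_total) {
  lev <- names(means)
  pmat <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  if (!is.finite(ms) || ms <= 0 || df <= 0) {
    for (a in lev) for (b in lev)
      pmat[a, b] <- if (isTRUE(all.equal(means[[a]], means[[b]]))) 1 else 0
    return(pmat)
  }
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    se <- sqrt(ms / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(means[[i]] - means[[j]]) / se
    p <- stats::ptukey(q, k_total, df, lower.tail = FALSE)
    pmat[i, j] <- pmat[j, i] <- p
  }
  pmat
}

#' Blocked two-factor comparison (simplified reanalysis)
#'
#' Split-plot ANOVA for a digestibility-style design: a between-animal
#' factor (milk species), a within-animal factor (small-intestinal
#' location) and their interaction, with the animal as block —
#' `aov(y ~ species * location + Error(animal))`. Species effects are
#' tested against the between-animal stratum, location and interaction
#' against the within-animal stratum. Following the usual reporting rule,
#' the interaction is removed and the model refitted when its p-value
#' exceeds `alpha`. Per-factor Tukey letters use the Tukey-Kramer
#' studentized-range test on the appropriate stratum's error mean square.
#'
#' @param data Data frame with one value per animal x location.
#' @param response Name of the response column.
#' @param species_col,location_col,animal_col Column names of the factors.
#' @param alpha Significance level (interaction drop rule and letters).
#' @return Object of class `blocked_comparison`: list with `p_species`,
#'   `p_location`, `p_interaction` (the tested value, also when dropped),
#'   `interaction_retained`, `species` and `location` comparison tables
#'   (`level`, `n`, `mean`, `sem`, `letter`), `degenerate`, and the final
#'   `fit`.
#' @export
two_factor_blocked <- function(data, response = "apparent_dig_pct",
                               species_col = "species",
                               location_col = "location",
                               animal_col = "animal_id", alpha = 0.05) {
  stopifnot(all(c(response, species_col, location_col, animal_col) %in%
                  names(data)))
  d <- data.frame(y = data[[response]],
                  species = droplevels(factor(data[[species_col]])),
                  location = droplevels(factor(data[[location_col]])),
                  animal = droplevels(factor(data[[animal_col]])))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$species)) < 2 ||
      nlevels(droplevels(d$location)) < 2)
    md_stop("blocked comparison needs >= 2 species and >= 2 locations",
            "markerdigest_config")
  tab <- table(d$animal, d$location)
  if (any(tab != 1))
    warning("unbalanced design: not one value per animal x location; ",
            "fitting on available cells", call. = FALSE)
  fit_full <- stats::aov(y ~ species * location + Error(animal), data = d)
  sm <- summary(fit_full)
  between <- sm[["Error: animal"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  p_int <- .aov_cell(within, "species:location", "Pr(>F)")
  degenerate <- all(is.na(c(between[, "Pr(>F)"], within[, "Pr(>F)"])))
  retained <- isTRUE(p_int <= alpha)
  fit <- if (retained) fit_full
  else stats::aov(y ~ species + location + Error(animal), data = d)
  sm2 <- summary(fit)
  between <- sm2[["Error: animal"]][[1]]
  within <- sm2[["Error: Within"]][[1]]
  p_species <- .aov_cell(between, "species", "Pr(>F)")
  p_location <- .aov_cell(within, "location", "Pr(>F)")
  ms_b <- .aov_cell(between, "Residuals", "Mean Sq")
  df_b <- .aov_cell(between, "Residuals", "Df")
  ms_w <- .aov_cell(within, "Residuals", "Mean Sq")
  df_w <- .aov_cell(within, "Residuals", "Df")

  comp <- function(fac, ms, df) {
    means <- tapply(d$y, d[[fac]], mean)
    ns <- tapply(d$y, d[[fac]], length)
    pmat <- .tukey_pmat(means, ns, ms, df, length(means))
    out <- describe(d$y, d[[fac]])
    out$letter <- unname(.cld(means, pmat, alpha)[out$group])
    names(out)[1] <- "level"
    out[c("level", "n", "mean", "sem", "letter")]
  }
  structure(list(
    p_species = unname(p_species), p_location = unname(p_location),
    p_interaction = unname(p_int), interaction_retained = retained,
    species = comp("species", ms_b, df_b),
    location = comp("location", ms_w, df_w),
    degenerate = degenerate, alpha = alpha, fit = fit),
    class = "blocked_comparison")
}

#' @export
print.blocked_comparison <- function(x, ...) {
  cat(sprintf(
    "<blocked_comparison> species p = %s, location p = %s, interaction %s (p = %s)\n",
    format.pval(x$p_species), format.pval(x$p_location),
    if (x$interaction_retained) "retained" else "dropped",
    format.pval(x$p_interaction)))
  cat("species:\n"); print(x$species)
  cat("location:\n"); print(x$location)
  invisible(x)
}

#' Comparison tables for every analyte of a digestibility run
#'
#' Applies [two_factor_blocked()] per analyte to the long table produced
#' by [digest_cohort()].
#'
#' @param digest Long data frame from [digest_cohort()].
#' @param response Response column to compare.
#' @param locations Locations to include (default PSI and DSI, i.e. the
#'   25% and 75% positions, where per-animal measurements are direct).
#' @param alpha Significance level.
#' @return Named list of `blocked_comparison` objects, one per analyte.
#' @export
compare_cohort <- function(digest, response = "apparent_dig_pct",
                           locations = c("PSI", "DSI"), alpha = 0.05) {
  stopifnot(response %in% names(digest))
  d <- digest[digest$location %in% locations, , drop = FALSE]
  out <- lapply(split(d, d$analyte), function(dd)
    two_factor_blocked(dd, response = response, alpha = alpha))
  out
}
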