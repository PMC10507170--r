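test_that("describe returns arithmetic mean and sd/sqrt(n)", {
  d <- describe(c(1, 2, 3), rep("g", 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(d$sem, 0.577, tolerance = 1e-3)
  d2 <- describe(c(5, 5, 5, 7), c("a", "a", "a", "b"))
  expect_equal(d2$sem, c(0, 0))
  expect_true(d2$singleton[d2$group == "b"])
})

test_that("Tukey letters separate distant groups and join equal ones", {
  set.seed(21)
  # three groups with equal means: one shared letter
  y0 <- rnorm(12)
  t0 <- oneway_tukey(y0, rep(c("a", "b", "c"), each = 4))
  if (attr(t0, "p_value") > 0.05)
    expect_equal(length(unique(t0$letter)), 1)
  # two groups separated by 10 sd: distinct letters
  y1 <- c(rnorm(4), rnorm(4, 10))
  t1 <- oneway_tukey(y1, rep(c("lo", "hi"), each = 4))
  expect_false(t1$letter[t1$level == "lo"] == t1$letter[t1$level == "hi"])
  expect_lt(attr(t1, "p_value"), 0.001)
  # hand check against the studentized range: q = diff/sqrt(MSE/n)
  means <- tapply(y1, rep(c("lo", "hi"), each = 4), mean)
  fit <- stats::aov(y1 ~ factor(rep(c("lo", "hi"), each = 4)))
  q <- abs(diff(means)) / sqrt(sum(stats::residuals(fit)^2) / 6 / 4)
  p_hand <- stats::ptukey(q, 2, 6, lower.tail = FALSE)
  expect_equal(attr(t1, "pairwise_p")["lo", "hi"], unname(p_hand),
               tolerance = 1e-9)
  # degenerate variance flagged; equal means share, different means differ
  td <- oneway_tukey(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(attr(td, "degenerate"))
  expect_false(td$letter[1] == td$letter[2])
})

test_that("letter display agrees pairwise with the Tukey decisions", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    y <- rnorm(4 * k, mean = rep(runif(k, 0, 6), each = 4))
    g <- rep(letters[1:k], each = 4)
    ct <- oneway_tukey(y, g)
    pmat <- attr(ct, "pairwise_p")
    lt <- stats::setNames(ct$letter, ct$level)
    share <- function(a, b)
      length(intersect(strsplit(lt[[a]], "")[[1]],
                       strsplit(lt[[b]], "")[[1]])) > 0
    for (a in ct$level) for (b in ct$level) {
      if (a == b) next
      expect_identical(share(a, b), unname(pmat[a, b] > 0.05),
                       info = sprintf("rep %d pair %s-%s", i, a, b))
      expect_identical(share(a, b), share(b, a))
    }
  }
})

test_that("split-plot F statistics match a hand sum-of-squares computation", {
  set.seed(41)
  # balanced 3 species x 2 locations x 4 animals toy
  sp <- rep(c("b", "c", "o"), each = 8)
  loc <- rep(c("PSI", "DSI"), 12)
  an <- rep(sprintf("a%02d", 1:12), each = 2)
  y <- rnorm(24, mean = 2 * (sp == "o") + 3 * (loc == "DSI"))
  d <- data.frame(y = y, species = sp, location = loc, animal_id = an)
  cmp <- two_factor_blocked(d, response = "y")

  # brute-force sums of squares
  gm <- mean(y)
  ss_sp <- 8 * sum((tapply(y, sp, mean) - gm)^2)
  ss_loc <- 12 * sum((tapply(y, loc, mean) - gm)^2)
  ss_an <- 2 * sum((tapply(y, an, mean) - gm)^2)
  cell <- tapply(y, list(sp, loc), mean)
  ss_int <- 4 * sum((sweep(sweep(cell, 1, tapply(y, sp, mean)), 2,
                           tapply(y, loc, mean)) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_an_resid <- ss_an - ss_sp                     # between-animal error
  ss_within_resid <- ss_tot - ss_an - ss_loc - ss_int
  # df: between-animal 11 = species 2 + resid 9;
  # within-animal 12 = location 1 + interaction 2 + resid 9
  f_sp <- (ss_sp / 2) / (ss_an_resid / 9)
  f_int <- (ss_int / 2) / (ss_within_resid / 9)
  p_sp <- stats::pf(f_sp, 2, 9, lower.tail = FALSE)
  p_int <- stats::pf(f_int, 2, 9, lower.tail = FALSE)

  expect_equal(cmp$p_interaction, p_int, tolerance = 1e-9)
  if (!cmp$interaction_retained) {
    # after dropping the interaction its SS folds into the within error
    f_loc2 <- (ss_loc / 1) / ((ss_within_resid + ss_int) / 11)
    expect_equal(cmp$p_location,
                 stats::pf(f_loc2, 1, 11, lower.tail = FALSE),
                 tolerance = 1e-9)
    expect_equal(cmp$p_species, p_sp, tolerance = 1e-9)
  }
})

test_that("interaction drop rule follows the generative model", {
  # additive model: interaction dropped, both main effects detected
  set.seed(51)
  drops <- effects <- logical(20)
  for (i in 1:20) {
    sp <- rep(c("b", "c", "o"), each = 8)
    loc <- rep(c("PSI", "DSI"), 12)
    an <- rep(sprintf("a%02d", 1:12), each = 2)
    animal_re <- rep(rnorm(12, 0, 0.5), each = 2)
    y <- 10 + 3 * (sp == "o") + 4 * (loc == "DSI") + animal_re + rnorm(24,
                                                                       0, 0.5)
    cmp <- two_factor_blocked(data.frame(y = y, species = sp,
                                         location = loc, animal_id = an),
                              response = "y")
    drops[i] <- !cmp$interaction_retained
    effects[i] <- cmp$p_species <= 0.05 && cmp$p_location <= 0.05
  }
  expect_gte(mean(drops), 0.8)
  expect_gte(mean(effects), 0.9)
  # strong crossing interaction: retained nearly always
  set.seed(52)
  kept <- logical(20)
  for (i in 1:20) {
    sp <- rep(c("b", "c", "o"), each = 8)
    loc <- rep(c("PSI", "DSI"), 12)
    an <- rep(sprintf("a%02d", 1:12), each = 2)
    y <- 10 + 6 * (sp == "o") * (loc == "DSI") - 6 * (sp == "b") *
      (loc == "DSI") + rnorm(24, 0, 0.5)
    cmp <- two_factor_blocked(data.frame(y = y, species = sp,
                                         location = loc, animal_id = an),
                              response = "y")
    kept[i] <- cmp$interaction_retained
  }
  expect_gte(mean(kept), 0.9)
})

test_that("split-plot Tukey p-values agree with emmeans", {
  set.seed(61)
  sp <- rep(c("b", "c", "o"), each = 8)
  loc <- rep(c("PSI", "DSI"), 12)
  an <- rep(sprintf("a%02d", 1:12), each = 2)
  y <- rnorm(24, 2 * (sp == "c") + 3 * (loc == "DSI"))
  d <- data.frame(y = y, species = factor(sp), location = factor(loc),
                  animal = factor(an))
  # same split-plot structure the blocked comparison fits internally
  # (sum-to-zero contrasts so emmeans does not need to refit the call)
  fit <- stats::aov(y ~ species + location + Error(animal), data = d,
                    contrasts = list(species = "contr.sum",
                                     location = "contr.sum"))
  em <- suppressMessages(emmeans::emmeans(fit, ~species, data = d))
  pp <- summary(pairs(em, adjust = "tukey"))
  # our pairwise p-values, computed the way the letters are formed
  sm <- summary(fit)
  bet <- sm[["Error: animal"]][[1]]
  i <- match("Residuals", trimws(rownames(bet)))
  means <- tapply(d$y, d$species, mean)
  ns <- tapply(d$y, d$species, length)
  pm <- markerdigest:::.tukey_pmat(means, ns, bet[i, "Mean Sq"],
                                   bet[i, "Df"], 3)
  expect_equal(unname(c(pm["b", "c"], pm["b", "o"], pm["c", "o"])),
               pp$p.value, tolerance = 1e-8)
  # and the letter display built from them is consistent with emmeans
  d2 <- d
  names(d2)[4] <- "animal_id"
  cmp <- two_factor_blocked(d2, response = "y")
  expect_identical(cmp$species$letter[cmp$species$level == "c"] !=
                     cmp$species$letter[cmp$species$level == "b"],
                   pp$p.value[1] <= 0.05)
})
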