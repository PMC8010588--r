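test_that("incidence rates and their intervals behave correctly", {
  r <- incidence_rate(14, 4527)
  expect_equal(round(r$value, 2), 3.09)
  r2 <- incidence_rate(445, 224009)
  expect_equal(round(r2$value, 2), 1.99)

  z <- incidence_rate(0, 1000)
  expect_equal(z$value, 0)
  expect_equal(z$ci_low, 0)

  expect_error(incidence_rate(3, 0), "positive")
  expect_error(incidence_rate(-1, 10), "non-negative")

  # log-normal variant: rate * exp(+/- 1.96/sqrt(cases))
  ln <- incidence_rate(14, 4527, ci_method = "lognormal")
  expect_equal(round(ln$ci_low, 2), 1.83)
  expect_equal(round(ln$ci_high, 2), 5.22)
})

test_that("incidence rate ratios reduce to hand arithmetic", {
  eq <- incidence_rate_ratio(10, 1000, 20, 2000)
  expect_equal(eq$value, 1.0)
  dbl <- incidence_rate_ratio(20, 1000, 10, 1000)
  expect_equal(dbl$value, 2.0)
  # planted rates on a synthetic split
  set.seed(2)
  c1 <- 37; py1 <- 5000; c0 <- 260; py0 <- 91000
  got <- incidence_rate_ratio(c1, py1, c0, py0)
  expect_equal(got$value, (c1 / py1) / (c0 / py0))
  expect_error(incidence_rate_ratio(5, 100, 0, 100), "undefined")
})

test_that("crude odds ratios reproduce Woolf arithmetic", {
  sym <- crude_or(10, 20, 10, 20)
  expect_equal(sym$value, 1.0)
  expect_warning(zc <- crude_or(0, 10, 5, 100), "Haldane")
  expect_true(is.finite(zc$value))
  or <- crude_or(30, 130, 25, 225)
  expect_equal(or$value, (30 / 100) / (25 / 200))
  expect_equal(or$se, sqrt(1 / 30 + 1 / 100 + 1 / 25 + 1 / 200))
})

test_that("the adjusted OR collapses to the crude OR without confounding", {
  set.seed(5)
  n <- 30000
  rows <- data.frame(
    rel_affected = runif(n) < 0.1,
    birth_year = sample(1950:2000, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    county = sample(paste0("c", 1:5), n, replace = TRUE),
    education_gt11 = runif(n) < 0.3
  )
  beta <- log(2)
  p <- plogis(-3 + beta * rows$rel_affected)
  rows$case <- runif(n) < p
  adj <- adjusted_or(rows)
  cr <- crude_or(sum(rows$case & rows$rel_affected), sum(rows$rel_affected),
                 sum(rows$case & !rows$rel_affected), sum(!rows$rel_affected))
  expect_lt(abs(log(adj$value) - log(cr$value)), 2 * cr$se)
  expect_lt(abs(log(adj$value) - beta), 2 * adj$se)
})

test_that("degenerate covariates are dropped instead of breaking the fit", {
  set.seed(6)
  n <- 4000
  rows <- data.frame(
    rel_affected = runif(n) < 0.2,
    birth_year = sample(1950:2000, n, replace = TRUE),
    sex = "female",                       # constant: must be dropped
    county = sample(paste0("c", 1:3), n, replace = TRUE),
    education_gt11 = runif(n) < 0.3
  )
  rows$case <- runif(n) < plogis(-2 + 0.5 * rows$rel_affected)
  adj <- adjusted_or(rows)
  expect_false("sexmale" %in% rownames(summary(attr(adj, "fit"))$coefficients))
  expect_true(is.finite(adj$value))
})

test_that("tetrachoric estimation honours exact special cases", {
  ind <- tetrachoric(c(n11 = 10, n10 = 30, n01 = 30, n00 = 90))
  expect_lt(abs(ind$value), 1e-5)   # n11*n00 == n10*n01 => independence

  expect_warning(conc <- tetrachoric(c(n11 = 40, n10 = 0, n01 = 0, n00 = 60)),
                 "concordant")
  expect_gt(conc$value, 0.999)

  expect_error(tetrachoric(c(n11 = 5, n10 = 5, n01 = 0, n00 = 0)),
               "degenerate margin")
})

test_that("tetrachoric ML agrees with the rho-grid oracle", {
  tab <- c(n11 = 50, n10 = 450, n01 = 450, n00 = 9050)
  expect_equal(tetrachoric(tab)$value, oracle_tetrachoric(tab),
               tolerance = 1e-3)
  # a handful of structured tables; the full random panel runs with the
  # acceptance checks
  for (tab in list(c(n11 = 120, n10 = 80, n01 = 80, n00 = 720),
                   c(n11 = 5, n10 = 95, n01 = 95, n00 = 805),
                   c(n11 = 200, n10 = 600, n01 = 300, n00 = 900))) {
    expect_equal(tetrachoric(tab)$value, oracle_tetrachoric(tab),
                 tolerance = 1e-3)
  }
})

test_that("tetrachoric is invariant to single- vs double-entry counts", {
  tab <- c(n11 = 60, n10 = 140, n01 = 140, n00 = 1660)
  half <- tab / 2
  expect_equal(tetrachoric(tab)$value, tetrachoric(half)$value,
               tolerance = 1e-6)
})

test_that("the resemblance interaction model needs class contrast", {
  rows <- data.frame(case = c(TRUE, FALSE), rel_affected = c(TRUE, FALSE),
                     resemblance = 0.5)
  expect_error(resemblance_interaction(rows), "single relationship class")
})

test_that("shuffling resemblance within relation nulls the interaction", {
  sim <- simulate_registry(liability_params(
    n_families = 4000, twin_prob = 0.5, half_sib_prob = 0.5, h2 = 0.4,
    c2 = 0, female_liability_shift = 0, death_rate = 0, emigration_rate = 0,
    seed = 13))
  fw <- follow_up(sim$registry)
  pr <- build_all_pairs(sim$registry)
  rows <- pair_rows(pr, sim$registry, fw)
  set.seed(14)
  rows$resemblance <- sample(unique(rows$resemblance), nrow(rows),
                             replace = TRUE)
  est <- resemblance_interaction(rows, adjust = character())
  expect_gt(est$p_value, 0.01)
  expect_lt(abs(log(est$value)), 3 * est$se)
})

test_that("Pearson trend over relationship classes", {
  # documented per-class tetrachoric sequence: strongly positive trend
  tr <- pearson_trend(c(0.66, 0.5, 0.25, 0.125), c(0.17, 0.11, 0.05, 0.02))
  expect_gt(tr$value, 0.9)

  expect_equal(pearson_trend(c(0.125, 0.25, 0.5), c(1, 2, 4))$value,
               cor(c(0.125, 0.25, 0.5), c(1, 2, 4)))
  expect_equal(pearson_trend(c(1, 2, 3), c(2, 4, 6))$value, 1)
  expect_error(pearson_trend(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_trend(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("stratified estimation handles symmetry and empty strata", {
  set.seed(15)
  n <- 6000
  rows <- data.frame(
    rel_affected = runif(n) < 0.2,
    birth_year = sample(1950:2000, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    county = "c1",
    education_gt11 = runif(n) < 0.3,
    sex_pair = sample(c("male-male", "female-female"), n, replace = TRUE),
    index_id = paste0("p", 1:n), onset_age = NA_real_
  )
  rows$case <- runif(n) < plogis(-2 + log(2) * rows$rel_affected)
  st <- stratify(rows, by = "sex", estimator = adjusted_or)
  expect_equal(sort(st$stratum), c("female-female", "male-male"))
  expect_true(all(is.finite(st$value)))

  # a stratum with no cases yields an NA row, not an error
  rows2 <- rows
  rows2$case[rows2$sex_pair == "male-male"] <- FALSE
  st2 <- suppressWarnings(stratify(rows2, by = "sex", estimator = adjusted_or))
  expect_true(any(is.na(st2$value)))
})

test_that("single- and double-entry give identical point estimates", {
  sim <- simulate_registry(liability_params(n_families = 1500, twin_prob = 0.4,
                                            h2 = 0.4, seed = 16))
  fit_d <- famagg(sim$registry, relations = "full_sibling",
                  adjust = character())
  fit_s <- famagg(sim$registry, relations = "full_sibling",
                  adjust = character(), entry = "single")
  pick <- function(fit, m) fit$estimates$value[fit$estimates$measure == m]
  pickci <- function(fit, m) {
    e <- fit$estimates[fit$estimates$measure == m, ]
    log(e$ci_high / e$ci_low)
  }
  # exposure is a person attribute and the 2x2 table is defined over double
  # entry, so crude OR and tetrachoric points are identical
  expect_equal(pick(fit_s, "OR_crude"), pick(fit_d, "OR_crude"),
               tolerance = 1e-10)
  expect_equal(pick(fit_s, "tetrachoric"), pick(fit_d, "tetrachoric"),
               tolerance = 1e-10)
  # the adjusted OR is refit on the thinned rows: near-identical point,
  # wider interval under single entry
  expect_lt(abs(log(pick(fit_s, "OR_adjusted") / pick(fit_d, "OR_adjusted"))),
            2 * fit_s$estimates$se[fit_s$estimates$measure == "OR_adjusted"])
  expect_gt(pickci(fit_s, "OR_adjusted"), pickci(fit_d, "OR_adjusted"))
})

test_that("dropping families with differential codes removes their pairs", {
  p <- fixture_pedigree()
  d <- data.frame(person_id = c("d1", "c1"),
                  code = c("TLOC_DIFF", "R559"),
                  event_year = c(2003L, 2005L), source = "inpatient",
                  stringsAsFactors = FALSE)
  reg <- new_registry(p, d)
  fit <- famagg(reg, relations = "full_sibling", adjust = character(),
                rules = NULL)
  sf <- sensitivity_filters(fit, "exclude_differential")
  ids <- unique(c(sf$refit$rows$index_id, sf$refit$rows$relative_id))
  expect_false("d1" %in% ids)
  expect_false("d2" %in% ids)  # same nuclear family

  # no differential codes anywhere: estimates unchanged
  reg2 <- new_registry(p, d[d$code == "R559", , drop = FALSE])
  fit2 <- famagg(reg2, relations = "full_sibling", adjust = character(),
                 rules = NULL)
  sf2 <- sensitivity_filters(fit2, "exclude_differential")
  expect_equal(sf2$refit$estimates$value, fit2$estimates$value)
})
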