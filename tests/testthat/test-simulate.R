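test_that("infeasible liability parameters are rejected", {
  expect_error(liability_params(h2 = 0.7, c2 = 0.5), "h2 \\+ c2")
  expect_error(liability_params(target_prevalence = -0.1), "probabilities")
  expect_error(liability_params(twin_prob = 1.5), "probabilities")
})

test_that("threshold calibration hits the target prevalence", {
  # no sex shift: closed form available as a cross-check
  expect_equal(famagg:::liability_threshold(0.023, 0),
               qnorm(1 - 0.023), tolerance = 1e-8)
  # with sex shift: plug the root back into the mixture
  tau <- famagg:::liability_threshold(0.05, 0.3)
  got <- 0.5 * pnorm(tau, lower.tail = FALSE) +
    0.5 * pnorm(tau - 0.3, lower.tail = FALSE)
  expect_equal(got, 0.05, tolerance = 1e-8)
})

test_that("the same seed reproduces the registry exactly", {
  p <- liability_params(n_families = 50, seed = 99)
  a <- simulate_registry(p)
  b <- simulate_registry(p)
  expect_identical(a$registry$persons, b$registry$persons)
  expect_identical(a$registry$diagnoses, b$registry$diagnoses)
  c <- simulate_registry(liability_params(n_families = 50, seed = 100))
  expect_false(identical(a$registry$diagnoses, c$registry$diagnoses))
})

test_that("independent liabilities give the target prevalence and no familial correlation", {
  sim <- simulate_registry(liability_params(
    n_families = 8000, h2 = 0, c2 = 0, female_liability_shift = 0,
    death_rate = 0, emigration_rate = 0, seed = 21))
  fw <- follow_up(sim$registry)
  prev <- mean(fw$event[!fw$excluded])
  n <- sum(!fw$excluded)
  se <- sqrt(0.023 * 0.977 / n)
  expect_lt(abs(prev - 0.023), 3 * se)

  sib <- build_pairs(sim$registry, "full_sibling")
  xt <- cross_tabulate(sib, fw)
  tc <- tetrachoric(xt$table)
  expect_lt(abs(tc$value), 3 * tc$se)
})

test_that("sibling tetrachoric recovers the liability correlation 0.5 * h2", {
  sim <- simulate_registry(liability_params(
    n_families = 12000, h2 = 0.25, c2 = 0, female_liability_shift = 0,
    death_rate = 0, emigration_rate = 0, seed = 31))
  fw <- follow_up(sim$registry)
  sib <- build_pairs(sim$registry, "full_sibling")
  tc <- tetrachoric(cross_tabulate(sib, fw)$table)
  expect_lt(abs(tc$value - 0.125), 3 * tc$se)
})

test_that("a positive female liability shift yields female-excess prevalence", {
  sim <- simulate_registry(liability_params(
    n_families = 6000, female_liability_shift = 0.3, seed = 41))
  fw <- follow_up(sim$registry)
  p <- sim$registry$persons
  aff <- fw$event & !fw$excluded
  prev_f <- mean(aff[p$sex == "female"])
  prev_m <- mean(aff[p$sex == "male"])
  expect_gt(prev_f, prev_m)
})

test_that("sex assignment is same-sex for MZ and independent otherwise", {
  set.seed(7)
  mz <- replicate(300, sex_assignment("twin", "MZ"))
  expect_true(all(mz[1, ] == mz[2, ]))
  dz <- replicate(4000, sex_assignment("twin", "DZ"))
  opp <- mean(dz[1, ] != dz[2, ])
  expect_lt(abs(opp - 0.5), 3 * sqrt(0.25 / 4000))
  expect_error(sex_assignment("twin", NA), "zygosity")
})

test_that("simulated twin sexes reflect the MZ/DZ mixture", {
  # opposite-sex fraction of a mixture with MZ fraction f is (1 - f) / 2
  f <- 0.31
  sim <- simulate_registry(liability_params(
    n_families = 6000, twin_prob = 1, mz_fraction_of_twins = f, seed = 51))
  tw <- single_entry(build_pairs(sim$registry, "twin"))
  p <- sim$registry$persons
  s1 <- p$sex[match(tw$index_id, p$person_id)]
  s2 <- p$sex[match(tw$relative_id, p$person_id)]
  opp <- mean(s1 != s2)
  expect_lt(abs(opp - (1 - f) / 2), 3 * sqrt(0.345 * 0.655 / nrow(tw)))
  # and the simulator's latent zygosity labels match the MZ fraction
  zyg <- sim$truth$zygosity
  expect_lt(abs(mean(zyg$zygosity == "MZ") - f),
            3 * sqrt(f * (1 - f) / nrow(zyg)))
})

test_that("differential codes appear at the configured rate among the diagnosed", {
  sim <- simulate_registry(liability_params(
    n_families = 8000, differential_frac = 0.02, seed = 61))
  d <- sim$registry$diagnoses
  n_dx <- length(unique(d$person_id[d$code == "R559"]))
  n_diff <- length(unique(d$person_id[d$code == "TLOC_DIFF"]))
  expect_gt(n_dx, 0)
  expect_lt(abs(n_diff / n_dx - 0.02), 3 * sqrt(0.02 * 0.98 / n_dx))
})
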