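test_that("nuclear-family pair extraction matches the definitions", {
  reg <- fixture_registry()

  sib <- build_pairs(reg, "full_sibling")
  # sibships: (c1,c3),(c2,c3) [c1-c2 are twins], (A,B), (d1,d2) -> 8 rows
  expect_equal(nrow(sib), 8L)
  expect_false("c1 c2" %in% pair_keys_of(sib))

  tw <- build_pairs(reg, "twin")
  expect_equal(pair_keys_of(tw), "c1 c2")
  expect_equal(nrow(tw), 2L)

  hs <- build_pairs(reg, "half_sibling")
  expect_setequal(pair_keys_of(hs), c("c1 h1", "c2 h1", "c3 h1"))

  cz <- build_pairs(reg, "cousin")
  expect_equal(length(pair_keys_of(cz)), 8L)  # {c1,c2,c3,h1} x {d1,d2}
  expect_true(all(c("c1 d1", "d2 h1") %in% pair_keys_of(cz)))
})

test_that("every pair table is double-entered with mirrored orientations", {
  reg <- fixture_registry()
  for (rel in c("twin", "full_sibling", "half_sibling", "cousin")) {
    pr <- build_pairs(reg, rel)
    key_fwd <- paste(pr$index_id, pr$relative_id)
    key_rev <- paste(pr$relative_id, pr$index_id)
    expect_setequal(key_fwd, key_rev)
    expect_true(all(pr$index_id != pr$relative_id))
  }
  expect_equal(nrow(single_entry(build_pairs(reg, "cousin"))), 8L)
})

test_that("pair extraction agrees with the O(n^2) kinship oracle", {
  # hand fixture
  reg <- fixture_registry()
  oracle <- oracle_all_pairs(reg$persons)
  for (rel in c("twin", "full_sibling", "half_sibling", "cousin")) {
    got <- pair_keys_of(build_pairs(reg, rel))
    want <- oracle[oracle$relation == rel, ]
    expect_setequal(got, sort(paste(pmin(want$a, want$b),
                                    pmax(want$a, want$b))))
  }

  # simulated registry under 200 persons
  sim <- simulate_registry(liability_params(n_families = 16, twin_prob = 0.5,
                                            half_sib_prob = 0.5, seed = 8))
  persons <- sim$registry$persons
  expect_lte(nrow(persons), 200)
  oracle <- oracle_all_pairs(persons)
  for (rel in c("twin", "full_sibling", "half_sibling", "cousin")) {
    got <- pair_keys_of(build_pairs(sim$registry, rel))
    want <- oracle[oracle$relation == rel, ]
    expect_setequal(got, sort(paste(pmin(want$a, want$b),
                                    pmax(want$a, want$b))))
  }
})

test_that("the relationship datasets are disjoint", {
  sim <- simulate_registry(liability_params(n_families = 40, twin_prob = 0.5,
                                            half_sib_prob = 0.5, seed = 9))
  keys <- lapply(c("twin", "full_sibling", "half_sibling", "cousin"),
                 function(r) pair_keys_of(build_pairs(sim$registry, r)))
  all_keys <- unlist(keys)
  expect_equal(anyDuplicated(all_keys), 0L)
})

test_that("exclusion rules drop the right pairs and log them", {
  p <- fixture_pedigree()
  p$emigration_year[p$person_id == "d1"] <- 2001L  # emigrated at age 15
  reg <- new_registry(p)
  cz <- build_pairs(reg, "cousin")
  kept <- apply_exclusions(cz, reg, exclusion_rules(family_alive_from = NA))
  log <- attr(kept, "exclusion_log")
  # d1 pairs with c1, c2, c3, h1: 4 unordered cousin pairs dropped
  expect_equal(unname(log[["emigrated_lt_min_age"]]), 4L)
  expect_false(any(kept$index_id == "d1" | kept$relative_id == "d1"))

  # compliant data: a no-op
  reg_ok <- fixture_registry()
  sib <- build_pairs(reg_ok, "full_sibling")
  kept_ok <- apply_exclusions(sib, reg_ok,
                              exclusion_rules(parent_birth_range = NULL,
                                              child_birth_range = NULL))
  expect_equal(nrow(kept_ok), nrow(sib))
  expect_true(all(attr(kept_ok, "exclusion_log") == 0L))
})

test_that("a death before study start removes the whole nuclear family", {
  p <- fixture_pedigree()
  p$death_year[p$person_id == "c3"] <- 1990L
  reg <- new_registry(p)
  sib <- build_pairs(reg, "full_sibling")
  kept <- apply_exclusions(sib, reg,
                           exclusion_rules(parent_birth_range = NULL,
                                           child_birth_range = NULL))
  # c3's nuclear family is A x sA: c1, c2, c3 all poisoned, so the (A,B) and
  # (d1,d2) sibling pairs survive but nothing involving c1..c3 does
  expect_setequal(pair_keys_of(kept), c("A B", "d1 d2"))
  log <- attr(kept, "exclusion_log")
  expect_gt(log[["family_member_lost_before_start"]], 0L)
})

test_that("unknown parents exclude a person from pair datasets silently", {
  p <- fixture_pedigree()
  # founders (unknown parents) never appear in any pair set
  for (rel in c("full_sibling", "half_sibling", "cousin")) {
    pr <- build_pairs(new_registry(p), rel)
    expect_false(any(c("sA", "sB", "sX", "gm1", "gf1") %in%
                       c(pr$index_id, pr$relative_id)))
  }
})

test_that("cross-tabulation matches a brute-force loop over ordered pairs", {
  sim <- simulate_registry(liability_params(n_families = 60, twin_prob = 0.3,
                                            seed = 12, target_prevalence = 0.2))
  fw <- follow_up(sim$registry)
  pr <- build_pairs(sim$registry, "full_sibling")
  xt <- cross_tabulate(pr, fw)

  aff <- setNames(fw$event & !fw$excluded, fw$person_id)
  exc <- setNames(fw$excluded, fw$person_id)
  n <- c(n11 = 0L, n10 = 0L, n01 = 0L, n00 = 0L)
  for (i in seq_len(nrow(pr))) {
    if (exc[pr$index_id[i]] || exc[pr$relative_id[i]]) next
    a <- aff[pr$index_id[i]]; b <- aff[pr$relative_id[i]]
    cellname <- paste0("n", as.integer(a), as.integer(b))
    n[cellname] <- n[cellname] + 1L
  }
  expect_equal(xt$table, n)

  # double-entry symmetry and completeness
  expect_equal(xt$table[["n10"]], xt$table[["n01"]])
  expect_equal(sum(xt$table), sum(!exc[pr$index_id] & !exc[pr$relative_id]))
})

test_that("degenerate single-pair tables count as expected", {
  p <- fixture_pedigree()
  d <- data.frame(person_id = c("d1", "d2"), code = "R559",
                  event_year = c(2005L, 2007L), source = "primary_care",
                  stringsAsFactors = FALSE)
  reg <- new_registry(p, d)
  fw <- follow_up(reg)
  sib <- build_pairs(reg, "full_sibling")
  dd <- sib[sib$index_id %in% c("d1", "d2") &
              sib$relative_id %in% c("d1", "d2"), ]
  xt <- cross_tabulate(dd, fw)
  # one concordant-affected pair double-entered: n11 = 2
  expect_equal(unname(xt$table), c(2L, 0L, 0L, 0L))

  d2 <- d[1, ]  # now discordant
  reg2 <- new_registry(p, d2)
  fw2 <- follow_up(reg2)
  xt2 <- cross_tabulate(dd, fw2)
  expect_equal(xt2$table[["n10"]], 1L)
  expect_equal(xt2$table[["n01"]], 1L)
})
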