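test_that("a hand-written registry file round-trips through read_registry", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "person_id\tsex\tbirth_year\tdeath_year\temigration_year\tmother_id\tfather_id\tborn_in_country\tcounty\teducation_gt11\ttwin_group_id",
    "p1\tfemale\t1970\t\t\t\t\t1\tc1\t0\t",
    "p2\tmale\t1990\t\t\tp1\tp3\t1\tc1\t1\t",
    "p3\tmale\t1968\t\t\t\t\t1\tc2\t0\t"
  ), file.path(dir, "persons.tsv"))
  writeLines(c(
    "person_id\tcode\tevent_year\tsource",
    "p2\tR559\t2005\tprimary_care"
  ), file.path(dir, "diagnoses.tsv"))

  reg <- read_registry(file.path(dir, "persons.tsv"),
                       file.path(dir, "diagnoses.tsv"))
  expect_s3_class(reg, "famagg_registry")
  expect_equal(nrow(reg$persons), 3L)
  expect_equal(nrow(reg$diagnoses), 1L)
  expect_identical(reg$persons$mother_id[2], "p1")
  expect_true(is.na(reg$persons$death_year[1]))

  out <- withr::local_tempdir()
  write_registry(reg, out)
  reg2 <- read_registry(file.path(out, "persons.tsv"),
                        file.path(out, "diagnoses.tsv"))
  expect_identical(reg$persons, reg2$persons)
  expect_identical(reg$diagnoses, reg2$diagnoses)
})

test_that("registry validation rejects invariant violations", {
  p <- fixture_pedigree()
  dup <- rbind(p, p[1, ])
  expect_error(new_registry(dup), "duplicate person_id")

  bad <- p
  bad$death_year[1] <- 1900L
  expect_error(new_registry(bad), "death_year before birth_year")

  bad <- p
  bad$birth_year[bad$person_id == "c2"] <- 1987L  # co-twins must share year
  expect_error(new_registry(bad), "twin group")

  # orphan diagnosis rows are reported and dropped, not fatal
  d <- data.frame(person_id = c("c1", "ghost"), code = "R559",
                  event_year = c(2000L, 2001L), source = "inpatient",
                  stringsAsFactors = FALSE)
  expect_warning(reg <- new_registry(p, d), "unknown person_id")
  expect_equal(nrow(reg$diagnoses), 1L)

  expect_error(new_registry(transform(p, event = 1)[, -3]), "lacks columns")
})

test_that("malformed numeric fields name the offending line", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "person_id\tsex\tbirth_year\tdeath_year\temigration_year\tmother_id\tfather_id\tborn_in_country\tcounty\teducation_gt11\ttwin_group_id",
    "p1\tfemale\tnineteen70\t\t\t\t\t1\tc1\t0\t"
  ), file.path(dir, "persons.tsv"))
  expect_error(read_registry(file.path(dir, "persons.tsv")),
               "birth_year at data line 1")
})

test_that("follow-up windows follow the study-period rules", {
  p <- fixture_pedigree()
  p <- rbind(p, within(p[1, ], {
    person_id <- "old"; birth_year <- 1950L; death_year <- 1990L
  }))
  d <- data.frame(person_id = c("c1", "h1"), code = c("R559", "R559"),
                  event_year = c(2010L, 1995L), source = "primary_care",
                  stringsAsFactors = FALSE)
  reg <- new_registry(p, d)
  fw <- follow_up(reg)
  rownames(fw) <- fw$person_id

  # born before 1997, no events: window [1997, 2015], 18 person-years
  expect_equal(fw["c3", "start"], 1997)
  expect_equal(fw["c3", "end"], 2015)
  expect_false(fw["c3", "event"])
  expect_equal(fw["c3", "person_years"], 18)

  # event inside the window ends follow-up at the event year
  expect_true(fw["c1", "event"])
  expect_equal(fw["c1", "end"], 2010)
  expect_equal(fw["c1", "person_years"], 2010 - 1997)

  # died before study start: flagged excluded, not an error
  expect_true(fw["old", "excluded"])
  expect_equal(fw["old", "person_years"], 0)

  # event before study start cannot count as an in-window event
  expect_false(fw["h1", "event"])
})

test_that("a person born after study start is followed from birth", {
  p <- fixture_pedigree()
  p$birth_year[p$person_id == "h1"] <- 2000L
  d <- data.frame(person_id = "h1", code = "R559", event_year = 2010L,
                  source = "outpatient", stringsAsFactors = FALSE)
  fw <- follow_up(new_registry(p, d))
  row <- fw[fw$person_id == "h1", ]
  expect_equal(row$start, 2000)
  expect_equal(row$end, 2010)
  expect_true(row$event)
})

test_that("an event in the first year of follow-up keeps 0.5 person-years", {
  p <- fixture_pedigree()[1:2, ]
  d <- data.frame(person_id = "gm1", code = "R559", event_year = 1997L,
                  source = "inpatient", stringsAsFactors = FALSE)
  fw <- follow_up(new_registry(p, d))
  expect_equal(fw$person_years[fw$person_id == "gm1"], 0.5)
})

test_that("cohort person-years equal brute-force per-person accumulation", {
  sim <- simulate_registry(liability_params(n_families = 10, seed = 5,
                                            death_rate = 0.1,
                                            emigration_rate = 0.1))
  fw <- follow_up(sim$registry)
  expect_lte(nrow(fw), 120)
  expect_equal(sum(fw$person_years), oracle_person_years(fw))
})
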