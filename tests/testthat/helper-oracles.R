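# Independent oracles used to validate the estimators. Each deliberately
# takes a different computational route from the implementation it checks.

# ---- brute-force O(n^2) kinship classifier -----------------------------

oracle_relation <- function(persons, a, b) {
  pa <- persons[persons$person_id == a, , drop = FALSE]
  pb <- persons[persons$person_id == b, , drop = FALSE]
  both_known <- function(x) !is.na(x$mother_id) && !is.na(x$father_id)
  if (!is.na(pa$twin_group_id) && !is.na(pb$twin_group_id) &&
      pa$twin_group_id == pb$twin_group_id) return("twin")
  if (both_known(pa) && both_known(pb)) {
    shared <- (pa$mother_id == pb$mother_id) + (pa$father_id == pb$father_id)
    if (shared == 2) return("full_sibling")
    if (shared == 1) return("half_sibling")
    full_sibs <- function(x, y) {
      if (is.na(x) || is.na(y) || x == y) return(FALSE)
      px <- persons[persons$person_id == x, , drop = FALSE]
      py <- persons[persons$person_id == y, , drop = FALSE]
      nrow(px) == 1 && nrow(py) == 1 && both_known(px) && both_known(py) &&
        px$mother_id == py$mother_id && px$father_id == py$father_id
    }
    for (qa in c(pa$mother_id, pa$father_id))
      for (qb in c(pb$mother_id, pb$father_id))
        if (full_sibs(qa, qb)) return("cousin")
  }
  NA_character_
}

oracle_all_pairs <- function(persons) {
  ids <- persons$person_id
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    rel <- oracle_relation(persons, ids[i], ids[j])
    if (!is.na(rel))
      out[[length(out) + 1L]] <- data.frame(a = ids[i], b = ids[j],
                                            relation = rel,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(),
                      relation = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# unordered canonical keys of a double-entered pair table
pair_keys_of <- function(pairs) {
  a <- pmin(pairs$index_id, pairs$relative_id)
  b <- pmax(pairs$index_id, pairs$relative_id)
  sort(unique(paste(a, b)))
}

# ---- tetrachoric rho-grid oracle ---------------------------------------

# orthant probability P(X > h, Y > k) by outer numerical integration over x
oracle_orthant <- function(h, k, rho) {
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((k - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  stats::integrate(f, h, Inf, rel.tol = 1e-10)$value
}

oracle_tetrachoric <- function(tab) {
  n <- sum(tab)
  p1 <- (tab[["n11"]] + tab[["n10"]]) / n
  p2 <- (tab[["n11"]] + tab[["n01"]]) / n
  h <- stats::qnorm(1 - p1)
  k <- stats::qnorm(1 - p2)
  ll <- function(r) {
    p11 <- oracle_orthant(h, k, r)
    pr <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
    pr <- pmax(pr, 1e-320)
    sum(c(tab[["n11"]], tab[["n10"]], tab[["n01"]], tab[["n00"]]) * log(pr))
  }
  coarse <- seq(-0.99, 0.99, by = 0.01)
  best <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(best - 0.012, -0.999), min(best + 0.012, 0.999), by = 2e-4)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# ---- survival oracles --------------------------------------------------

# hand-rolled product-limit estimator ("events before censorings at equal
# times" is what the ">= t" at-risk rule encodes)
oracle_km <- function(time, event, at = sort(unique(time[event]))) {
  vapply(at, function(t0) {
    s <- 1
    for (t in sort(unique(time[event & time <= t0]))) {
      n_at_risk <- sum(time >= t)
      d <- sum(event & time == t)
      s <- s * (1 - d / n_at_risk)
    }
    s
  }, numeric(1))
}

# two-group log-rank by direct observed-minus-expected accumulation
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ts <- sort(unique(time[event]))
  U <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# ---- person-years by explicit per-person accumulation ------------------

oracle_person_years <- function(windows) {
  total <- 0
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (w$excluded) next
    py <- w$end - w$start
    if (w$event && py == 0) py <- 0.5
    total <- total + py
  }
  total
}

# ---- hand-built pedigree fixture ---------------------------------------

# 13-person, 3-generation pedigree with every relationship class:
#   G0 couple gm1 x gf1 -> full siblings A (f) and B (m)
#   A x sA -> twins c1, c2 (group T1) and singleton c3
#   A x sX -> h1 (half-sibling of c1..c3)
#   B x sB -> d1, d2
# cousins: {c1, c2, c3, h1} x {d1, d2}
fixture_pedigree <- function() {
  person <- function(id, sex, by, mo = NA, fa = NA, twin = NA,
                     death = NA, emig = NA, born = TRUE, edu = FALSE) {
    data.frame(person_id = id, sex = sex, birth_year = as.integer(by),
               death_year = as.integer(death),
               emigration_year = as.integer(emig),
               mother_id = as.character(mo), father_id = as.character(fa),
               born_in_country = born, county = "c1",
               education_gt11 = edu, twin_group_id = as.character(twin),
               stringsAsFactors = FALSE)
  }
  rbind(
    person("gm1", "female", 1935), person("gf1", "male", 1933),
    person("A", "female", 1960, "gm1", "gf1"),
    person("B", "male", 1962, "gm1", "gf1"),
    person("sA", "male", 1958), person("sB", "female", 1961),
    person("sX", "male", 1965),
    person("c1", "male", 1985, "A", "sA", twin = "T1"),
    person("c2", "female", 1985, "A", "sA", twin = "T1"),
    person("c3", "female", 1988, "A", "sA"),
    person("h1", "male", 1992, "A", "sX"),
    person("d1", "female", 1986, "sB", "B"),
    person("d2", "male", 1990, "sB", "B")
  )
}

fixture_registry <- function(diagnoses = NULL) {
  d <- if (is.null(diagnoses)) {
    data.frame(person_id = character(), code = character(),
               event_year = integer(), source = character(),
               stringsAsFactors = FALSE)
  } else diagnoses
  new_registry(fixture_pedigree(), d)
}

# windows table built directly (for survival fixtures)
manual_windows <- function(time, event) {
  data.frame(person_id = paste0("p", seq_along(time)),
             start = 0, end = time, event = event,
             event_year = ifelse(event, time, NA_real_),
             person_years = time, excluded = FALSE,
             stringsAsFactors = FALSE)
}
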