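# Synthetic multigeneration registry with a known liability-threshold
# familial structure. Three generations per family:
#   G0: a founder couple with two full-sibling children (the G1 sibs);
#   G1: each G1 sib partners a founder spouse and has children (so the two
#       G1 sibships are first cousins of each other); one sibship may be a
#       twin pair (latent MZ/DZ zygosity); a G1 parent may re-partner and
#       have an extra child, creating half-siblings;
#   G2: the study children.
# Liability L = A + C + E with Var(A) = h2, Var(C) = c2, Var(E) = 1-h2-c2.
# A is transmitted as A_child = (A_mother + A_father)/2 + N(0, h2/2), which
# yields additive-genetic correlations of 1 (MZ), 0.5 (DZ/full sib),
# 0.25 (half-sib) and 0.125 (first cousin); C is shared within a nuclear
# sibship (same father and mother). Diagnosis occurs when L plus a female
# liability shift exceeds a threshold calibrated numerically so the marginal
# diagnosed fraction matches the target prevalence.

#' Simulation parameters for the synthetic registry
#'
#' Bundles and validates the settings of the liability-threshold registry
#' simulator. Defaults describe the emulated register cohort: a 2.3%
#' diagnosed fraction over follow-up, a female excess in risk, an MZ share of
#' twin pairs of 0.31 (which makes the Weinberg-estimated mean twin
#' resemblance come out near 0.66), a 2% rate of concurrent differential
#' transient-loss-of-consciousness codes among the diagnosed, and mild
#' death/emigration censoring.
#'
#' @param target_prevalence Probability of a diagnosed event over follow-up.
#' @param h2 Additive genetic fraction of liability variance.
#' @param c2 Shared-environment (nuclear household) fraction of liability
#'   variance. `h2 + c2` must not exceed 1.
#' @param female_liability_shift Liability-scale shift added for females
#'   (> 0 gives a female excess in prevalence).
#' @param mz_fraction_of_twins Probability a twin pair is monozygotic.
#' @param twin_prob Probability that a G1 sibship is born as a twin pair.
#' @param half_sib_prob Probability that a family contains a re-partnered
#'   parent with an extra (half-sibling) child.
#' @param n_children Number of children per G1 sibship.
#' @param n_families Number of independent three-generation families.
#' @param death_rate,emigration_rate Per-person probability of death or
#'   emigration during follow-up (censoring).
#' @param differential_frac Fraction of diagnosed persons also carrying a
#'   differential (non-reflex) diagnosis code.
#' @param onset_meanlog,onset_sdlog Log-normal age-at-onset parameters
#'   (defaults put the onset median near 22 years, IQR roughly 16-33).
#' @param study_start,study_end Calendar bounds of follow-up.
#' @param seed Integer seed; the same seed reproduces the registry exactly.
#' @return A validated list of class `liability_params`.
#' @export
liability_params <- function(target_prevalence = 0.023,
                             h2 = 0.25,
                             c2 = 0,
                             female_liability_shift = 0.15,
                             mz_fraction_of_twins = 0.31,
                             twin_prob = 0.015,
                             half_sib_prob = 0.15,
                             n_children = 2L,
                             n_families = 1000L,
                             death_rate = 0.01,
                             emigration_rate = 0.01,
                             differential_frac = 0.0207,
                             onset_meanlog = log(22),
                             onset_sdlog = 0.537,
                             study_start = 1997L,
                             study_end = 2015L,
                             seed = 1L) {
  p <- list(target_prevalence = target_prevalence, h2 = h2, c2 = c2,
            female_liability_shift = female_liability_shift,
            mz_fraction_of_twins = mz_fraction_of_twins,
            twin_prob = twin_prob, half_sib_prob = half_sib_prob,
            n_children = as.integer(n_children),
            n_families = as.integer(n_families),
            death_rate = death_rate, emigration_rate = emigration_rate,
            differential_frac = differential_frac,
            onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
            study_start = as.integer(study_start),
            study_end = as.integer(study_end),
            seed = as.integer(seed))
  probs <- c(target_prevalence, h2, c2, mz_fraction_of_twins, twin_prob,
             half_sib_prob, death_rate, emigration_rate, differential_frac)
  if (any(probs < 0) || any(probs[-(2:3)] > 1))
    stop("probabilities must lie in [0, 1]")
  if (h2 + c2 > 1) stop("h2 + c2 must not exceed 1")
  if (p$n_families < 1L) stop("n_families must be positive")
  if (p$n_children < 1L) stop("n_children must be positive")
  class(p) <- "liability_params"
  p
}

#' Expected genetic resemblance by relationship class
#'
#' The fixed additive-genetic correlations used throughout: 1 for MZ twins,
#' 0.5 for DZ twins and full siblings, 0.25 for half-siblings, 0.125 for
#' first cousins. The working value for an MZ/DZ twin *mixture* is estimated
#' from data by [weinberg()].
#' @return Named numeric vector.
#' @export
resemblance_map <- function() {
  c(mz_twin = 1.0, dz_twin = 0.5, full_sibling = 0.5,
    half_sibling = 0.25, cousin = 0.125)
}

#' Calibrate the liability threshold for a target prevalence
#'
#' Solves, by numerical root finding on the standard-normal marginal, for the
#' threshold tau with
#' `P(L + shift_sex > tau) = target` averaged over an equal sex split, where
#' females receive `+shift` on the liability scale.
#' @param target Target marginal prevalence.
#' @param shift Female liability shift.
#' @return The threshold (numeric scalar).
#' @keywords internal
liability_threshold <- function(target, shift = 0) {
  if (target <= 0 || target >= 1) stop("target prevalence must be in (0,1)")
  f <- function(tau) {
    0.5 * stats::pnorm(tau, lower.tail = FALSE) +
      0.5 * stats::pnorm(tau - shift, lower.tail = FALSE) - target
  }
  stats::uniroot(f, interval = c(-10, 10), tol = 1e-10)$root
}

#' Assign sexes to a relative pair
#'
#' MZ co-twins are always the same sex (a single fair draw applied to both);
#' every other pair type gets two independent fair draws.
#'
#' @param pair_type One of `"twin"`, `"full_sibling"`, `"half_sibling"`,
#'   `"cousin"`.
#' @param zygosity For twins, `"MZ"` or `"DZ"`; ignored otherwise.
#' @return Character vector of two sexes.
#' @examples
#' set.seed(1)
#' sex_assignment("twin", "MZ")   # always same-sex
#' @export
sex_assignment <- function(pair_type, zygosity = NA_character_) {
  draw <- function(n) c("male", "female")[1L + (stats::runif(n) < 0.5)]
  if (pair_type == "twin") {
    if (is.na(zygosity)) stop("twin pairs need a zygosity")
    if (zygosity == "MZ") return(rep(draw(1L), 2L))
  }
  draw(2L)
}

#' Simulate a multigeneration registry under a liability-threshold model
#'
#' Generates `n_families` independent three-generation families containing
#' full siblings, MZ/DZ twin pairs (twin group recorded, zygosity latent),
#' half-siblings and first cousins, assigns each person a latent liability
#' with the familial correlation structure implied by `h2` and `c2`, converts
#' threshold exceedances into diagnosis events with a log-normal
#' age-at-onset truncated to the person's follow-up window, and applies
#' death/emigration censoring. A small configurable fraction of diagnosed
#' persons also receives a differential transient-loss-of-consciousness code
#' (`"TLOC_DIFF"`), supporting the sensitivity analysis that drops such
#' families.
#'
#' @param params A [liability_params()] object.
#' @return A list with components `registry` (a `famagg_registry`) and
#'   `truth` (a data frame of per-person latent liabilities, the zygosity of
#'   each twin group, and the parameters used; consumed only by validation
#'   code, never by the analysis pipeline).
#' @examples
#' out <- simulate_registry(liability_params(n_families = 50, seed = 7))
#' out$registry
#' @export
simulate_registry <- function(params) {
  stopifnot(inherits(params, "liability_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  nf <- params$n_families
  h2 <- params$h2
  c2 <- params$c2
  e2 <- 1 - h2 - c2
  k <- params$n_children

  # --- family structure (vectorised over families) -----------------------
  # sibship 1 is a twin pair (needs at least 2 children per sibship)
  twin1 <- (k >= 2L) & (stats::runif(nf) < params$twin_prob)
  mz <- twin1 & (stats::runif(nf) < params$mz_fraction_of_twins)
  halfs <- stats::runif(nf) < params$half_sib_prob    # extra half-sib child

  # founders: G0 couple (2), two G1 spouses (2); G1 sibs (2); children (2k);
  # optional half-sib child + its outside parent
  fid <- seq_len(nf)

  # helper to draw founder additive values
  rA <- function(n) stats::rnorm(n, 0, sqrt(h2))
  rM <- function(n) stats::rnorm(n, 0, sqrt(h2 / 2))  # mendelian segregation

  # G0 couple
  g0f_A <- rA(nf); g0m_A <- rA(nf)
  # G1 sibs (children of G0): sib1 marries spouse1, sib2 marries spouse2
  g1a_A <- (g0f_A + g0m_A) / 2 + rM(nf)
  g1b_A <- (g0f_A + g0m_A) / 2 + rM(nf)
  sp1_A <- rA(nf); sp2_A <- rA(nf)
  # outside partner for the half-sib child
  sp3_A <- rA(nf)

  # children of sibship 1 (parents g1a + sp1) and sibship 2 (g1b + sp2)
  kid_A <- function(pa, pb, n) (pa + pb) / 2 + rM(n)
  c1_A <- matrix(0, nf, k)
  c2_A <- matrix(0, nf, k)
  for (j in seq_len(k)) {
    c1_A[, j] <- kid_A(g1a_A, sp1_A, nf)
    c2_A[, j] <- kid_A(g1b_A, sp2_A, nf)
  }
  # MZ twins: second child's additive value is a copy of the first
  if (k >= 2L) c1_A[mz, 2L] <- c1_A[mz, 1L]
  # half-sib child of g1a with outside partner sp3
  hs_A <- kid_A(g1a_A, sp3_A, nf)

  # --- birth years -------------------------------------------------------
  ryear <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
  g0_by <- ryear(nf, 1932L, 1945L)
  g1_by <- pmin(pmax(g0_by + ryear(nf, 20L, 30L), 1952L), 1975L)
  g1b_by <- pmin(pmax(g0_by + ryear(nf, 20L, 30L), 1952L), 1975L)
  sp_by <- ryear(nf, 1952L, 1975L)
  kid_by <- function(parent_by) pmin(parent_by + ryear(nf, 20L, 32L), 2005L)
  c1_by <- matrix(0L, nf, k)
  c2_by <- matrix(0L, nf, k)
  c1_by[, 1L] <- kid_by(g1_by)
  c2_by[, 1L] <- kid_by(g1b_by)
  if (k >= 2L) for (j in 2:k) {
    c1_by[, j] <- pmin(c1_by[, 1L] + ryear(nf, 1L, 6L), 2005L)
    c2_by[, j] <- pmin(c2_by[, 1L] + ryear(nf, 1L, 6L), 2005L)
  }
  # co-twins share a birth year
  if (k >= 2L) c1_by[twin1, 2L] <- c1_by[twin1, 1L]
  hs_by <- pmin(g1_by + ryear(nf, 22L, 34L), 2005L)

  # --- assemble person table --------------------------------------------
  id_mat <- function(role, m) {
    matrix(sprintf("F%06d_%s%d", rep(fid, m), role,
                   rep(seq_len(m), each = nf)), nf, m)
  }
  g0f_id <- sprintf("F%06d_G0F", fid); g0m_id <- sprintf("F%06d_G0M", fid)
  g1a_id <- sprintf("F%06d_P1", fid); g1b_id <- sprintf("F%06d_P2", fid)
  sp1_id <- sprintf("F%06d_S1", fid); sp2_id <- sprintf("F%06d_S2", fid)
  sp3_id <- sprintf("F%06d_S3", fid)
  c1_id <- id_mat("C1_", k)
  c2_id <- id_mat("C2_", k)
  hs_id <- sprintf("F%06d_H1", fid)

  # sexes: G1a/G1b mother-or-father roles fixed for simplicity
  # (g1a female, sp1 male; g1b male, sp2 female; sp3 male)
  rsex <- function(n) c("male", "female")[1L + (stats::runif(n) < 0.5)]
  c1_sex <- matrix(rsex(nf * k), nf, k)
  c2_sex <- matrix(rsex(nf * k), nf, k)
  if (k >= 2L) c1_sex[mz, 2L] <- c1_sex[mz, 1L]   # MZ pairs share sex
  hs_sex <- rsex(nf)

  twin_grp <- ifelse(twin1, sprintf("F%06d_TW", fid), NA_character_)

  county_pool <- sprintf("county_%02d", 1:21)
  n_c1 <- nf * k

  rows <- list(
    data.frame(person_id = g0f_id, sex = "male", birth_year = g0_by,
               mother_id = NA_character_, father_id = NA_character_,
               A = g0f_A, hh = NA_character_, twin_group_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(person_id = g0m_id, sex = "female", birth_year = g0_by,
               mother_id = NA_character_, father_id = NA_character_,
               A = g0m_A, hh = NA_character_, twin_group_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(person_id = g1a_id, sex = "female", birth_year = g1_by,
               mother_id = g0m_id, father_id = g0f_id,
               A = g1a_A, hh = sprintf("F%06d_HH0", fid),
               twin_group_id = NA_character_, stringsAsFactors = FALSE),
    data.frame(person_id = g1b_id, sex = "male", birth_year = g1b_by,
               mother_id = g0m_id, father_id = g0f_id,
               A = g1b_A, hh = sprintf("F%06d_HH0", fid),
               twin_group_id = NA_character_, stringsAsFactors = FALSE),
    data.frame(person_id = sp1_id, sex = "male", birth_year = sp_by,
               mother_id = NA_character_, father_id = NA_character_,
               A = sp1_A, hh = NA_character_, twin_group_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(person_id = sp2_id, sex = "female", birth_year = sp_by,
               mother_id = NA_character_, father_id = NA_character_,
               A = sp2_A, hh = NA_character_, twin_group_id = NA_character_,
               stringsAsFactors = FALSE)
  )
  # sibship 1 children: mother g1a, father sp1
  rows <- c(rows, list(
    data.frame(person_id = as.vector(c1_id), sex = as.vector(c1_sex),
               birth_year = as.vector(c1_by),
               mother_id = rep(g1a_id, k), father_id = rep(sp1_id, k),
               A = as.vector(c1_A), hh = rep(sprintf("F%06d_HH1", fid), k),
               twin_group_id = c(if (k >= 1L) twin_grp,
                                 if (k >= 2L) twin_grp,
                                 rep(NA_character_, n_c1 - min(n_c1, 2L * nf))),
               stringsAsFactors = FALSE),
    # sibship 2 children: mother sp2, father g1b
    data.frame(person_id = as.vector(c2_id), sex = as.vector(c2_sex),
               birth_year = as.vector(c2_by),
               mother_id = rep(sp2_id, k), father_id = rep(g1b_id, k),
               A = as.vector(c2_A), hh = rep(sprintf("F%06d_HH2", fid), k),
               twin_group_id = NA_character_, stringsAsFactors = FALSE)
  ))
  # half-sib child: mother g1a, father sp3 (only where halfs)
  if (any(halfs)) {
    rows <- c(rows, list(
      data.frame(person_id = sp3_id[halfs], sex = "male",
                 birth_year = sp_by[halfs],
                 mother_id = NA_character_, father_id = NA_character_,
                 A = sp3_A[halfs], hh = NA_character_,
                 twin_group_id = NA_character_, stringsAsFactors = FALSE),
      data.frame(person_id = hs_id[halfs], sex = hs_sex[halfs],
                 birth_year = hs_by[halfs],
                 mother_id = g1a_id[halfs], father_id = sp3_id[halfs],
                 A = hs_A[halfs], hh = sprintf("F%06d_HH3", fid[halfs]),
                 twin_group_id = NA_character_, stringsAsFactors = FALSE)
    ))
  }
  pers <- do.call(rbind, rows)
  n <- nrow(pers)

  # --- liabilities and diagnosis ----------------------------------------
  # shared environment: one draw per nuclear household (hh), persons without
  # a household (founders) draw independently
  hh_keys <- unique(pers$hh[!is.na(pers$hh)])
  hh_C <- stats::rnorm(length(hh_keys), 0, sqrt(c2))
  C <- ifelse(is.na(pers$hh), stats::rnorm(n, 0, sqrt(c2)),
              hh_C[match(pers$hh, hh_keys)])
  E <- stats::rnorm(n, 0, sqrt(e2))
  L <- pers$A + C + E

  shift <- ifelse(pers$sex == "female", params$female_liability_shift, 0)
  tau <- liability_threshold(params$target_prevalence,
                             params$female_liability_shift)
  liable <- (L + shift) > tau

  # censoring
  died <- stats::runif(n) < params$death_rate
  emig <- stats::runif(n) < params$emigration_rate
  span <- params$study_end - pmax(pers$birth_year, params$study_start)
  death_year <- ifelse(died & span > 0,
                       pmax(pers$birth_year, params$study_start) +
                         floor(stats::runif(n) * pmax(span, 1)),
                       NA_real_)
  emigration_year <- ifelse(emig & span > 0 & !died,
                            pmax(pers$birth_year, params$study_start) +
                              floor(stats::runif(n) * pmax(span, 1)),
                            NA_real_)

  # onset year: log-normal age at onset truncated to the follow-up window
  fw_start <- pmax(pers$birth_year, params$study_start)
  fw_end <- pmin(ifelse(is.na(death_year), Inf, death_year),
                 ifelse(is.na(emigration_year), Inf, emigration_year),
                 params$study_end)
  can_event <- liable & fw_end >= fw_start
  age_lo <- fw_start - pers$birth_year
  age_hi <- fw_end - pers$birth_year
  onset_age <- rep(NA_real_, n)
  idx <- which(can_event)
  if (length(idx)) {
    p_lo <- stats::plnorm(age_lo[idx], params$onset_meanlog, params$onset_sdlog)
    p_hi <- stats::plnorm(age_hi[idx] + 1, params$onset_meanlog,
                          params$onset_sdlog)
    u <- p_lo + stats::runif(length(idx)) * pmax(p_hi - p_lo, 1e-12)
    onset_age[idx] <- stats::qlnorm(pmin(u, 1 - 1e-12), params$onset_meanlog,
                                    params$onset_sdlog)
  }
  event_year <- pmin(pmax(floor(pers$birth_year + onset_age), fw_start), fw_end)
  has_event <- can_event & !is.na(onset_age)

  source_pool <- c("primary_care", "inpatient", "outpatient")
  ev_idx <- which(has_event)
  diagnoses <- data.frame(
    person_id = pers$person_id[ev_idx],
    code = "R559",
    event_year = as.integer(event_year[ev_idx]),
    source = source_pool[1L + floor(stats::runif(length(ev_idx)) * 3)],
    stringsAsFactors = FALSE
  )
  # differential TLOC codes for a small fraction of diagnosed persons
  diff_idx <- ev_idx[stats::runif(length(ev_idx)) < params$differential_frac]
  if (length(diff_idx)) {
    diagnoses <- rbind(diagnoses, data.frame(
      person_id = pers$person_id[diff_idx],
      code = "TLOC_DIFF",
      event_year = as.integer(event_year[diff_idx]),
      source = "inpatient",
      stringsAsFactors = FALSE
    ))
  }

  persons <- data.frame(
    person_id = pers$person_id,
    sex = pers$sex,
    birth_year = as.integer(pers$birth_year),
    death_year = as.integer(death_year),
    emigration_year = as.integer(emigration_year),
    mother_id = pers$mother_id,
    father_id = pers$father_id,
    born_in_country = TRUE,
    county = county_pool[1L + floor(stats::runif(n) * length(county_pool))],
    education_gt11 = stats::runif(n) < 0.30,
    twin_group_id = pers$twin_group_id,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    person_id = pers$person_id,
    liability = L,
    additive = pers$A,
    liable = liable,
    stringsAsFactors = FALSE
  )
  zyg <- data.frame(
    twin_group_id = twin_grp[twin1],
    zygosity = ifelse(mz[twin1], "MZ", "DZ"),
    stringsAsFactors = FALSE
  )

  list(registry = new_registry(persons, diagnoses),
       truth = list(persons = truth, zygosity = zyg, params = params,
                    threshold = tau))
}
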