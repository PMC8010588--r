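# Relative-pair extraction from parent links. Four relationship classes are
# recognised, each emitted double-entered (every unordered pair appears once
# with each member as index person):
#   twin          same twin_group_id (optionally: same parents + birth year)
#   full_sibling  same mother and father, not co-twins
#   half_sibling  exactly one shared parent (both parents known for both)
#   cousin        a parent of one is a full sibling of a parent of the other

RELATIONS <- c("twin", "full_sibling", "half_sibling", "cousin")

# default working resemblance per class; the twin value is the mean over the
# MZ/DZ mixture and is re-estimated from the data by weinberg() when possible
DEFAULT_RESEMBLANCE <- c(twin = 0.66, full_sibling = 0.5,
                         half_sibling = 0.25, cousin = 0.125)

#' Extract double-entered relative pairs of one relationship class
#'
#' Builds the pair dataset for one relationship class from the registry's
#' parent links. Twin pairs are detected by shared `twin_group_id` (the
#' fallback of same parents plus same birth year is opt-in, because
#' year-resolution data cannot distinguish twins from same-year singleton
#' siblings). Full siblings share both parents and are not co-twins; twin
#' pairs are excluded from the full-sibling set. Half-siblings share exactly
#' one parent (with both parents known on both sides). Cousins are children
#' of full-sibling parents. A person may belong to several relationship
#' datasets; a person with both parents unknown contributes no pairs.
#'
#' @param registry A `famagg_registry`.
#' @param relation One of `"twin"`, `"full_sibling"`, `"half_sibling"`,
#'   `"cousin"`.
#' @param twin_resemblance Working genetic resemblance attached to twin
#'   pairs (default 0.66, the MZ/DZ mixture mean; see [weinberg()]).
#' @param twin_fallback_birth_year If `TRUE`, also call a pair of full
#'   siblings born in the same year twins when `twin_group_id` is absent.
#' @return Data frame of class `famagg_pairs` with columns `index_id`,
#'   `relative_id`, `relation`, `resemblance`; double-entered, so each
#'   unordered pair contributes two rows.
#' @examples
#' reg <- simulate_registry(liability_params(n_families = 30, seed = 2))$registry
#' sib <- build_pairs(reg, "full_sibling")
#' nrow(sib) %% 2 == 0
#' @export
build_pairs <- function(registry, relation,
                        twin_resemblance = DEFAULT_RESEMBLANCE[["twin"]],
                        twin_fallback_birth_year = FALSE) {
  stopifnot(inherits(registry, "famagg_registry"))
  relation <- match.arg(relation, RELATIONS)
  p <- registry$persons

  unordered <- switch(
    relation,
    twin = twin_pairs(p, twin_fallback_birth_year),
    full_sibling = setdiff_pairs(sib_pairs(p), twin_pairs(p, FALSE)),
    half_sibling = half_sib_pairs(p),
    cousin = cousin_pairs(p)
  )
  res <- if (relation == "twin") twin_resemblance
         else DEFAULT_RESEMBLANCE[[relation]]
  double_enter(unordered, relation, res)
}

#' Build all four relationship datasets at once
#'
#' @inheritParams build_pairs
#' @param relations Character vector of classes to build.
#' @return A single `famagg_pairs` data frame stacking all classes.
#' @export
build_all_pairs <- function(registry, relations = RELATIONS,
                            twin_resemblance = DEFAULT_RESEMBLANCE[["twin"]],
                            twin_fallback_birth_year = FALSE) {
  out <- lapply(relations, build_pairs, registry = registry,
                twin_resemblance = twin_resemblance,
                twin_fallback_birth_year = twin_fallback_birth_year)
  res <- do.call(rbind, out)
  class(res) <- c("famagg_pairs", "data.frame")
  res
}

# unordered pair tables: two-column character matrices with a < b canonical
# order and no duplicates
canonical_pairs <- function(a, b) {
  if (!length(a)) return(cbind(a = character(), b = character()))
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- a != b
  m <- unique(cbind(a = a[keep], b = b[keep]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

pairs_within_groups <- function(ids, key) {
  ok <- !is.na(key)
  grp <- split(ids[ok], key[ok])
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(canonical_pairs(character(), character()))
  len <- lengths(grp)
  # size-2 groups (the overwhelming majority) handled without per-group calls
  u <- unlist(grp[len == 2L], use.names = FALSE)
  a <- u[c(TRUE, FALSE)]
  b <- u[c(FALSE, TRUE)]
  big <- grp[len > 2L]
  if (length(big)) {
    mats <- lapply(big, function(g) utils::combn(g, 2L))
    m <- do.call(cbind, mats)
    a <- c(a, m[1L, ])
    b <- c(b, m[2L, ])
  }
  canonical_pairs(a, b)
}

twin_pairs <- function(p, fallback_birth_year) {
  out <- pairs_within_groups(p$person_id, p$twin_group_id)
  if (fallback_birth_year) {
    both_known <- !is.na(p$mother_id) & !is.na(p$father_id)
    key <- ifelse(both_known,
                  paste(p$mother_id, p$father_id, p$birth_year, sep = "\r"),
                  NA_character_)
    out <- rbind(out, pairs_within_groups(p$person_id, key))
    out <- canonical_pairs(out[, 1L], out[, 2L])
  }
  out
}

sib_pairs <- function(p) {
  both_known <- !is.na(p$mother_id) & !is.na(p$father_id)
  key <- ifelse(both_known, paste(p$mother_id, p$father_id, sep = "\r"),
                NA_character_)
  pairs_within_groups(p$person_id, key)
}

half_sib_pairs <- function(p) {
  both_known <- !is.na(p$mother_id) & !is.na(p$father_id)
  q <- p[both_known, , drop = FALSE]
  # group by each single parent, then keep pairs sharing exactly one parent
  by_mother <- pairs_within_groups(q$person_id, q$mother_id)
  by_father <- pairs_within_groups(q$person_id, q$father_id)
  cand <- rbind(by_mother, by_father)
  if (!nrow(cand)) return(cand)
  cand <- canonical_pairs(cand[, 1L], cand[, 2L])
  ma <- q$mother_id[match(cand[, 1L], q$person_id)]
  mb <- q$mother_id[match(cand[, 2L], q$person_id)]
  fa <- q$father_id[match(cand[, 1L], q$person_id)]
  fb <- q$father_id[match(cand[, 2L], q$person_id)]
  shared <- (ma == mb) + (fa == fb)
  cand[shared == 1L, , drop = FALSE]
}

cousin_pairs <- function(p) {
  both_known <- !is.na(p$mother_id) & !is.na(p$father_id)
  q <- p[both_known, , drop = FALSE]
  sibs <- sib_pairs(p)               # full-sibling pairs among the parents
  if (!nrow(sibs) || !nrow(q)) return(canonical_pairs(character(), character()))
  # child -> parent edge list (one row per child-parent link), joined twice
  # against the parent full-sibling pairs (both orientations)
  edges <- unique(data.frame(
    child = c(q$person_id, q$person_id),
    parent = c(q$mother_id, q$father_id),
    stringsAsFactors = FALSE
  ))
  sp <- data.frame(p1 = c(sibs[, 1L], sibs[, 2L]),
                   p2 = c(sibs[, 2L], sibs[, 1L]),
                   stringsAsFactors = FALSE)
  m1 <- merge(sp, edges, by.x = "p1", by.y = "parent")
  if (!nrow(m1)) return(canonical_pairs(character(), character()))
  m2 <- merge(m1, edges, by.x = "p2", by.y = "parent",
              suffixes = c("_a", "_b"))
  cand <- canonical_pairs(m2$child_a, m2$child_b)
  if (!nrow(cand)) return(cand)
  # children of full-sibling parents can also be (half-)siblings of each
  # other in pathological pedigrees; keep the cousin set disjoint
  drop <- pair_key(cand) %in% c(pair_key(sib_pairs(p)),
                                pair_key(half_sib_pairs(p)))
  cand[!drop, , drop = FALSE]
}

pair_key <- function(m) {
  if (!nrow(m)) return(character())
  paste(m[, 1L], m[, 2L], sep = "\r")
}

setdiff_pairs <- function(m, remove) {
  if (!nrow(m) || !nrow(remove)) return(m)
  m[!(pair_key(m) %in% pair_key(remove)), , drop = FALSE]
}

double_enter <- function(unordered, relation, resemblance) {
  n <- nrow(unordered)
  out <- data.frame(
    index_id = c(unordered[, 1L], unordered[, 2L]),
    relative_id = c(unordered[, 2L], unordered[, 1L]),
    relation = rep(relation, 2L * n),
    resemblance = rep(resemblance, 2L * n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("famagg_pairs", "data.frame")
  out
}

#' Single-entry view of a double-entered pair table
#'
#' Keeps one orientation per unordered pair: the row whose `index_id` sorts
#' before its `relative_id` (a deterministic, documented rule).
#' @param pairs A `famagg_pairs` data frame.
#' @return The de-duplicated pair table.
#' @export
single_entry <- function(pairs) {
  out <- pairs[pairs$index_id < pairs$relative_id, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("famagg_pairs", "data.frame")
  out
}

#' Default inclusion/exclusion rules for pair datasets
#'
#' Mirrors the register study's eligibility rules: both parents known; born
#' in the country; no emigration before age 17; no family member dead or
#' emigrated before follow-up start; birth-cohort windows for children
#' (1948-2005) and their parents (1932-1985). Each rule can be switched off
#' or re-parameterised.
#'
#' @param require_parents_known Drop persons with an unknown parent.
#' @param require_born_in_country Drop persons not born in the country.
#' @param min_emigration_age Drop persons who emigrated younger than this.
#' @param family_alive_from Drop whole nuclear families with any member dead
#'   or emigrated before this year (`NA` disables).
#' @param family_scope `"nuclear"` applies the family-level rule to the
#'   person's nuclear family (parents + their common children);
#'   `"pair"` applies it to the two pair members only.
#' @param child_birth_range,parent_birth_range Two-element year windows
#'   (`NULL` disables).
#' @return A list of class `famagg_rules`.
#' @export
exclusion_rules <- function(require_parents_known = TRUE,
                            require_born_in_country = TRUE,
                            min_emigration_age = 17,
                            family_alive_from = 1997,
                            family_scope = c("nuclear", "pair"),
                            child_birth_range = c(1948, 2005),
                            parent_birth_range = c(1932, 1985)) {
  structure(list(require_parents_known = require_parents_known,
                 require_born_in_country = require_born_in_country,
                 min_emigration_age = min_emigration_age,
                 family_alive_from = family_alive_from,
                 family_scope = match.arg(family_scope),
                 child_birth_range = child_birth_range,
                 parent_birth_range = parent_birth_range),
            class = "famagg_rules")
}

#' Apply eligibility rules to a pair dataset
#'
#' Drops every double-entered row in which either pair member (or, for the
#' family-level alive-at-start rule, any member of the relevant nuclear
#' family) violates a rule, and logs the number of unordered pairs removed
#' per rule (a pair failing several rules is logged under the first that
#' catches it, in the order of the log).
#'
#' @param pairs A `famagg_pairs` data frame.
#' @param registry The `famagg_registry` the pairs came from.
#' @param rules An [exclusion_rules()] list.
#' @return The filtered pairs, with an `exclusion_log` attribute (named
#'   integer vector of dropped unordered-pair counts).
#' @export
apply_exclusions <- function(pairs, registry, rules = exclusion_rules()) {
  stopifnot(inherits(registry, "famagg_registry"))
  p <- registry$persons
  idx <- match(pairs$index_id, p$person_id)
  rel <- match(pairs$relative_id, p$person_id)
  if (anyNA(idx) || anyNA(rel))
    stop("pair table refers to person ids absent from the registry")

  person_fail <- function(test) test[idx] | test[rel]
  log <- c(parents_unknown = 0L, not_born_in_country = 0L,
           emigrated_lt_min_age = 0L, family_member_lost_before_start = 0L,
           child_birth_cohort = 0L, parent_birth_cohort = 0L)
  drop <- rep(FALSE, nrow(pairs))
  tally <- function(new_drop, rule) {
    fresh <- new_drop & !drop
    # count unordered pairs (rows are double-entered)
    log[[rule]] <<- log[[rule]] + as.integer(sum(fresh) / 2)
    drop <<- drop | new_drop
  }

  if (isTRUE(rules$require_parents_known)) {
    unknown <- is.na(p$mother_id) | is.na(p$father_id)
    tally(person_fail(unknown), "parents_unknown")
  }
  if (isTRUE(rules$require_born_in_country)) {
    foreign <- !is.na(p$born_in_country) & !p$born_in_country
    tally(person_fail(foreign), "not_born_in_country")
  }
  if (!is.na(rules$min_emigration_age)) {
    young_emig <- !is.na(p$emigration_year) &
      (p$emigration_year - p$birth_year) < rules$min_emigration_age
    tally(person_fail(young_emig), "emigrated_lt_min_age")
  }
  if (!is.na(rules$family_alive_from)) {
    lost <- (!is.na(p$death_year) & p$death_year < rules$family_alive_from) |
      (!is.na(p$emigration_year) &
         p$emigration_year < rules$family_alive_from)
    if (rules$family_scope == "nuclear") {
      # propagate: a nuclear family (mother+father) with any lost child, or
      # a lost parent, poisons all children of that couple
      fam_key <- ifelse(!is.na(p$mother_id) & !is.na(p$father_id),
                        paste(p$mother_id, p$father_id, sep = "\r"),
                        NA_character_)
      lost_fams <- unique(stats::na.omit(fam_key[lost]))
      lost_parent_ids <- p$person_id[lost]
      parent_lost <- (!is.na(p$mother_id) & p$mother_id %in% lost_parent_ids) |
        (!is.na(p$father_id) & p$father_id %in% lost_parent_ids)
      fam_lost <- lost | (!is.na(fam_key) & fam_key %in% lost_fams) |
        parent_lost
      tally(person_fail(fam_lost), "family_member_lost_before_start")
    } else {
      tally(person_fail(lost), "family_member_lost_before_start")
    }
  }
  if (!is.null(rules$child_birth_range)) {
    out_of_range <- p$birth_year < rules$child_birth_range[1] |
      p$birth_year > rules$child_birth_range[2]
    tally(person_fail(out_of_range), "child_birth_cohort")
  }
  if (!is.null(rules$parent_birth_range)) {
    mo_by <- p$birth_year[match(p$mother_id, p$person_id)]
    fa_by <- p$birth_year[match(p$father_id, p$person_id)]
    bad_parent <- (!is.na(mo_by) & (mo_by < rules$parent_birth_range[1] |
                                      mo_by > rules$parent_birth_range[2])) |
      (!is.na(fa_by) & (fa_by < rules$parent_birth_range[1] |
                          fa_by > rules$parent_birth_range[2]))
    tally(person_fail(bad_parent), "parent_birth_cohort")
  }

  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("famagg_pairs", "data.frame")
  attr(out, "exclusion_log") <- log
  out
}

#' Cross-tabulate pair outcomes into a double-entry 2x2 table
#'
#' Counts double-entered pair rows by (index affected, relative affected),
#' and summarises exposure at the person level: each distinct index person is
#' classified as exposed (has at least one affected relative of this class)
#' or unexposed, with their own case status and person-years attached — the
#' row structure of a familial-risk table.
#'
#' @param pairs A `famagg_pairs` data frame (double-entered).
#' @param windows Output of [follow_up()] for the same registry.
#' @return A list of class `famagg_xtab`: `table` (named counts `n11`,
#'   `n10`, `n01`, `n00` of double-entered rows), `exposure` (data frame with
#'   rows `affected`/`unaffected` relative: `cases`, `persons_at_risk`,
#'   `person_years`), and `persons` (the per-person classification).
#' @export
cross_tabulate <- function(pairs, windows) {
  aff <- stats::setNames(windows$event & !windows$excluded, windows$person_id)
  keep <- !(windows$excluded[match(pairs$index_id, windows$person_id)] |
              windows$excluded[match(pairs$relative_id, windows$person_id)])
  pr <- pairs[keep, , drop = FALSE]
  ia <- aff[pr$index_id]
  ra <- aff[pr$relative_id]
  tab <- c(n11 = sum(ia & ra), n10 = sum(ia & !ra),
           n01 = sum(!ia & ra), n00 = sum(!ia & !ra))

  # person-level exposure: index persons with >= 1 affected relative
  exp_by_person <- tapply(ra, pr$index_id, any)
  ids <- names(exp_by_person)
  w <- windows[match(ids, windows$person_id), , drop = FALSE]
  exposed <- as.logical(exp_by_person)
  persons <- data.frame(person_id = ids, exposed = exposed,
                        case = as.logical(aff[ids]),
                        person_years = w$person_years,
                        stringsAsFactors = FALSE)
  summarise <- function(sel) {
    data.frame(cases = sum(persons$case[sel]),
               persons_at_risk = sum(sel),
               person_years = sum(persons$person_years[sel]))
  }
  exposure <- rbind(affected = summarise(exposed),
                    unaffected = summarise(!exposed))
  structure(list(table = tab, exposure = exposure, persons = persons),
            class = "famagg_xtab")
}

#' @export
print.famagg_xtab <- function(x, ...) {
  cat("Double-entry 2x2 pair table (index x relative affected)\n")
  print(x$table)
  cat("\nPerson-level exposure (relative affected?):\n")
  print(x$exposure)
  invisible(x)
}
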