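# Kaplan-Meier syncope-free survival by relative-history status, and the
# two-group log-rank test. The product-limit and log-rank machinery is the
# survival package's (survfit/survdiff); this file adapts follow-up windows
# to its interface and re-shapes the output. At equal (year-resolution)
# times, events are handled before censorings — survfit's convention.

#' Kaplan-Meier curves by group
#'
#' Product-limit estimates of event-free survival with right censoring at
#' death, emigration or the administrative end of follow-up. The time axis
#' is years since the start of follow-up (the study start, or birth if
#' later).
#'
#' @param windows Output of [follow_up()] (excluded persons are dropped).
#' @param groups Named or unnamed vector of group labels aligned with
#'   `windows` rows (e.g. "affected relative" / "no affected relative").
#' @return Data frame of class `famagg_km`: `group`, `time`, `survival`,
#'   `at_risk`, `events` (one row per distinct observed time per group).
#' @export
km_curve <- function(windows, groups) {
  if (length(groups) != nrow(windows))
    stop("groups must align with windows rows")
  keep <- !windows$excluded & !is.na(groups)
  w <- windows[keep, , drop = FALSE]
  g <- groups[keep]
  if (!nrow(w)) stop("no usable follow-up windows")
  if (any(tabulate(factor(g)) == 0L)) stop("empty group")
  time <- pmax(w$end - w$start, 0.5)  # events in the first year count as 0.5
  fit <- survival::survfit(survival::Surv(time, w$event) ~ g)
  strata_names <- if (is.null(fit$strata)) unique(as.character(g)) else
    sub("^g=", "", names(fit$strata))
  strata_rep <- if (is.null(fit$strata)) length(fit$time) else fit$strata
  out <- data.frame(
    group = rep(strata_names, strata_rep),
    time = fit$time,
    survival = fit$surv,
    at_risk = fit$n.risk,
    events = fit$n.event,
    stringsAsFactors = FALSE
  )
  class(out) <- c("famagg_km", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic comparing event-free survival between two
#' groups, referred to a chi-square distribution with 1 degree of freedom.
#'
#' @inheritParams km_curve
#' @return List of class `famagg_logrank`: `chi_square`, `df` (1),
#'   `p_value`.
#' @export
log_rank <- function(windows, groups) {
  if (length(groups) != nrow(windows))
    stop("groups must align with windows rows")
  keep <- !windows$excluded & !is.na(groups)
  w <- windows[keep, , drop = FALSE]
  g <- factor(groups[keep])
  if (nlevels(g) != 2L) stop("log-rank test needs exactly 2 non-empty groups")
  time <- pmax(w$end - w$start, 0.5)
  if (any(tapply(time, g, sum) <= 0))
    stop("a group has no at-risk time")
  sd <- survival::survdiff(survival::Surv(time, w$event) ~ g)
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE)),
            class = "famagg_logrank")
}

#' @export
print.famagg_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.2f (1 df), p = %.3g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Relative-history grouping for survival comparison
#'
#' Labels each person in the windows table by whether they have at least one
#' affected relative of the given class at baseline (ever affected during
#' the study window), the grouping used for the survival comparison.
#'
#' @param pairs A `famagg_pairs` table for one relationship class.
#' @param windows Output of [follow_up()].
#' @return Character vector aligned with `windows` rows: `"affected
#'   relative"`, `"no affected relative"`, or `NA` for persons not in the
#'   pair dataset.
#' @export
relative_history_groups <- function(pairs, windows) {
  aff <- stats::setNames(windows$event & !windows$excluded, windows$person_id)
  ra <- as.logical(aff[pairs$relative_id])
  exposed <- tapply(ra, pairs$index_id, any)
  status <- exposed[match(windows$person_id, names(exposed))]
  ifelse(is.na(status), NA_character_,
         ifelse(status, "affected relative", "no affected relative"))
}
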