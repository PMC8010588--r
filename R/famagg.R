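#' Fit a familial-aggregation analysis to a registry
#'
#' The package's central fitting function. From a validated multigeneration
#' registry it derives per-person follow-up windows, extracts double-entered
#' relative pairs for the requested relationship classes, applies the
#' eligibility rules, estimates the twin MZ/DZ composition by the Weinberg
#' differential method (the estimated mean twin resemblance replaces the
#' 0.66 default when twins are present), and computes, per relationship
#' class: incidence rates among persons with and without an affected
#' relative, the incidence rate ratio, crude and covariate-adjusted familial
#' odds ratios, and the tetrachoric correlation. Across classes it fits the
#' genetic-resemblance interaction model and the resemblance-risk Pearson
#' trend.
#'
#' @param registry A `famagg_registry` (from [read_registry()] or
#'   [simulate_registry()]).
#' @param relations Relationship classes to analyse (default all four).
#' @param adjust Covariates for the adjusted odds ratio (any of
#'   `"birth_year"`, `"sex"`, `"county"`, `"education_gt11"`).
#' @param entry `"double"` (default; each pair contributes a row in both
#'   orientations) or `"single"` (one orientation per pair, the sensitivity
#'   variant).
#' @param rules Eligibility rules, see [exclusion_rules()]; `NULL` skips
#'   exclusions.
#' @param code Diagnosis code defining the event (default `"R559"`).
#' @param study_start,study_end Follow-up calendar bounds.
#' @param rate_ci `"exact"` or `"lognormal"` incidence-rate intervals.
#' @return An object of class `famagg`; see [summary.famagg()]. Components
#'   include `estimates` (long data frame of all per-class estimates),
#'   `tables` (double-entry 2x2 tables), `zygosity` (a [weinberg()] object
#'   or `NULL`), `interaction`, `trend_tetrachoric`, `trend_or`, `windows`,
#'   `rows` (pooled pair-level analysis rows) and `exclusions`.
#' @examples
#' sim <- simulate_registry(liability_params(n_families = 300, seed = 42,
#'                                           twin_prob = 0.5))
#' fit <- famagg(sim$registry)
#' fit
#' coef(fit)
#' @export
famagg <- function(registry,
                   relations = c("twin", "full_sibling", "half_sibling",
                                 "cousin"),
                   adjust = c("birth_year", "sex", "county", "education_gt11"),
                   entry = c("double", "single"),
                   rules = exclusion_rules(),
                   code = "R559",
                   study_start = 1997L, study_end = 2015L,
                   rate_ci = c("exact", "lognormal")) {
  stopifnot(inherits(registry, "famagg_registry"))
  entry <- match.arg(entry)
  rate_ci <- match.arg(rate_ci)
  relations <- match.arg(relations, several.ok = TRUE)
  call_args <- list(registry = registry, relations = relations,
                    adjust = adjust, entry = entry, rules = rules,
                    code = code, study_start = study_start,
                    study_end = study_end, rate_ci = rate_ci)

  windows <- follow_up(registry, code = code, study_start = study_start,
                       study_end = study_end)

  zygosity <- NULL
  exclusions <- list()
  all_rows <- list()
  tables <- list()
  est <- list()
  km <- list()
  add <- function(relation, e) {
    est[[length(est) + 1L]] <<- data.frame(
      relation = relation, measure = e$measure, stratum = e$stratum,
      value = e$value, ci_low = e$ci_low, ci_high = e$ci_high, se = e$se,
      p_value = e$p_value, n = e$n, stringsAsFactors = FALSE)
  }

  for (rel in relations) {
    pr <- build_pairs(registry, rel)
    if (!is.null(rules)) {
      pr <- apply_exclusions(pr, registry, rules)
      exclusions[[rel]] <- attr(pr, "exclusion_log")
    }
    if (!nrow(pr)) next

    if (rel == "twin") {
      zygosity <- tryCatch(weinberg_from_pairs(pr, registry),
                           error = function(e) NULL)
      if (!is.null(zygosity))
        pr$resemblance <- zygosity$mean_resemblance
    }

    # person-level exposure and the 2x2 table are defined over the full
    # double-entered pair set (exposure is an attribute of the person);
    # single entry thins only the regression rows
    pr_use <- if (entry == "single") single_entry(pr) else pr
    xt <- cross_tabulate(pr, windows)
    tables[[rel]] <- xt

    ex <- xt$exposure
    if (ex["affected", "person_years"] > 0) {
      r1 <- incidence_rate(ex["affected", "cases"],
                           ex["affected", "person_years"], rate_ci)
      r1$stratum <- "relative affected"
      add(rel, r1)
    }
    if (ex["unaffected", "person_years"] > 0) {
      r0 <- incidence_rate(ex["unaffected", "cases"],
                           ex["unaffected", "person_years"], rate_ci)
      r0$stratum <- "relative unaffected"
      add(rel, r0)
    }
    irr <- tryCatch(incidence_rate_ratio(
      ex["affected", "cases"], ex["affected", "person_years"],
      ex["unaffected", "cases"], ex["unaffected", "person_years"]),
      error = function(e) NULL)
    if (!is.null(irr)) add(rel, irr)
    co <- tryCatch(suppressWarnings(crude_or(
      ex["affected", "cases"], ex["affected", "persons_at_risk"],
      ex["unaffected", "cases"], ex["unaffected", "persons_at_risk"])),
      error = function(e) NULL)
    if (!is.null(co)) add(rel, co)

    rows <- pair_rows(pr_use, registry, windows)
    all_rows[[rel]] <- rows
    ao <- tryCatch(adjusted_or(rows, adjust), error = function(e) NULL)
    if (!is.null(ao)) {
      attr(ao, "fit") <- NULL
      add(rel, ao)
    }
    tc <- tryCatch(suppressWarnings(tetrachoric(xt$table)),
                   error = function(e) NULL)
    if (!is.null(tc)) add(rel, tc)
  }

  estimates <- if (length(est)) do.call(rbind, est) else
    data.frame(relation = character(), measure = character(),
               stratum = character(), value = numeric(), ci_low = numeric(),
               ci_high = numeric(), se = numeric(), p_value = numeric(),
               n = numeric(), stringsAsFactors = FALSE)
  rows_pooled <- if (length(all_rows)) do.call(rbind, all_rows) else NULL
  if (!is.null(rows_pooled)) rownames(rows_pooled) <- NULL

  interaction <- if (!is.null(rows_pooled) &&
                     length(unique(rows_pooled$resemblance)) >= 2L)
    tryCatch(resemblance_interaction(rows_pooled, adjust),
             error = function(e) NULL) else NULL

  trend_of <- function(measure) {
    sub <- estimates[estimates$measure == measure &
                       is.na(estimates$stratum), , drop = FALSE]
    if (nrow(sub) < 3L || is.null(rows_pooled)) return(NULL)
    res <- vapply(sub$relation, function(r)
      rows_pooled$resemblance[match(r, rows_pooled$relation)], numeric(1))
    tryCatch(pearson_trend(res, sub$value), error = function(e) NULL)
  }

  structure(list(
    estimates = estimates,
    tables = tables,
    zygosity = zygosity,
    interaction = interaction,
    trend_tetrachoric = trend_of("tetrachoric"),
    trend_or = trend_of("OR_adjusted"),
    windows = windows,
    rows = rows_pooled,
    exclusions = exclusions,
    entry = entry,
    adjust = adjust,
    call_args = call_args,
    call = match.call()
  ), class = "famagg")
}

#' @export
print.famagg <- function(x, digits = 2, ...) {
  cat("Familial aggregation analysis (", x$entry, " entry)\n", sep = "")
  n_classes <- length(unique(x$estimates$relation))
  cat("  relationship classes analysed:", n_classes, "\n")
  if (!is.null(x$zygosity))
    cat(sprintf("  twin mean resemblance (Weinberg): %.2f\n",
                x$zygosity$mean_resemblance))
  ors <- x$estimates[x$estimates$measure == "OR_adjusted", , drop = FALSE]
  if (nrow(ors)) {
    cat("  adjusted familial ORs:\n")
    for (i in seq_len(nrow(ors)))
      cat(sprintf("    %-13s %.*f (%.*f-%.*f)\n", ors$relation[i], digits,
                  ors$value[i], digits, ors$ci_low[i], digits,
                  ors$ci_high[i]))
  }
  if (!is.null(x$interaction))
    cat(sprintf("  resemblance x family-history interaction OR: %.2f, p = %.3g\n",
                x$interaction$value, x$interaction$p_value))
  invisible(x)
}

#' Summarise a familial-aggregation fit
#'
#' Prints the familial-risk table (rates, incidence rate ratio, crude and
#' adjusted odds ratios, tetrachoric correlation per relationship class),
#' the Weinberg zygosity estimate, the interaction model and the
#' resemblance-risk trends.
#'
#' @param object A `famagg` fit.
#' @param ... Ignored.
#' @return Invisibly, the `estimates` data frame.
#' @export
summary.famagg <- function(object, ...) {
  cat("Familial aggregation analysis —", object$entry, "entry\n\n")
  if (!is.null(object$zygosity)) { print(object$zygosity); cat("\n") }
  wide <- object$estimates
  if (nrow(wide)) {
    wide$value <- round(wide$value, 4)
    wide$ci_low <- round(wide$ci_low, 4)
    wide$ci_high <- round(wide$ci_high, 4)
    print(wide, row.names = FALSE)
  }
  if (!is.null(object$interaction)) {
    cat("\nResemblance x family-history interaction: ")
    print(object$interaction)
  }
  if (!is.null(object$trend_tetrachoric)) {
    cat(sprintf("Pearson trend (resemblance vs tetrachoric): r = %.3f\n",
                object$trend_tetrachoric$value))
  }
  if (!is.null(object$trend_or)) {
    cat(sprintf("Pearson trend (resemblance vs adjusted OR): r = %.3f\n",
                object$trend_or$value))
  }
  invisible(object$estimates)
}

#' Extract familial odds ratios from a fit
#'
#' @param object A `famagg` fit.
#' @param measure Which measure to extract (default the adjusted OR).
#' @param ... Ignored.
#' @return Named numeric vector, one value per relationship class.
#' @export
coef.famagg <- function(object, measure = "OR_adjusted", ...) {
  sub <- object$estimates[object$estimates$measure == measure, , drop = FALSE]
  stats::setNames(sub$value, sub$relation)
}

#' Kaplan-Meier curves from a familial-aggregation fit
#'
#' Plots event-free survival by relative-history status, one panel per
#' relationship class analysed (the four-panel familial-survival layout).
#'
#' @param x A `famagg` fit.
#' @param relations Classes to plot (default: all fitted).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, a named list of `famagg_km` curve tables.
#' @export
plot.famagg <- function(x, relations = names(x$tables), ...) {
  relations <- intersect(relations, names(x$tables))
  if (!length(relations)) stop("no fitted relationship classes to plot")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(relations)))
  on.exit(graphics::par(old))
  curves <- list()
  for (rel in relations) {
    pr <- x$rows[x$rows$relation == rel, , drop = FALSE]
    pairs_tab <- data.frame(index_id = pr$index_id,
                            relative_id = pr$relative_id,
                            relation = rel, resemblance = pr$resemblance,
                            stringsAsFactors = FALSE)
    grp <- relative_history_groups(pairs_tab, x$windows)
    km <- km_curve(x$windows, grp)
    curves[[rel]] <- km
    split_km <- split(km, km$group)
    ylim <- c(min(km$survival) * 0.995, 1)
    graphics::plot(NA, xlim = c(0, max(km$time)), ylim = ylim,
                   xlab = "Years since start of follow-up",
                   ylab = "Event-free survival", main = rel, ...)
    cols <- c("firebrick", "steelblue")
    for (i in seq_along(split_km)) {
      s <- split_km[[i]]
      graphics::lines(stats::stepfun(s$time, c(1, s$survival)),
                      do.points = FALSE, col = cols[i])
    }
    graphics::legend("bottomleft", legend = names(split_km), col = cols,
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(curves)
}

#' Log-rank tests per relationship class from a fit
#'
#' @param fit A `famagg` fit.
#' @return Data frame: `relation`, `chi_square`, `df`, `p_value`.
#' @export
logrank_by_relation <- function(fit) {
  stopifnot(inherits(fit, "famagg"))
  out <- lapply(names(fit$tables), function(rel) {
    pr <- fit$rows[fit$rows$relation == rel, , drop = FALSE]
    pairs_tab <- data.frame(index_id = pr$index_id,
                            relative_id = pr$relative_id,
                            relation = rel, resemblance = pr$resemblance,
                            stringsAsFactors = FALSE)
    grp <- relative_history_groups(pairs_tab, fit$windows)
    lr <- tryCatch(log_rank(fit$windows, grp), error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    data.frame(relation = rel, chi_square = lr$chi_square, df = lr$df,
               p_value = lr$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort descriptive fractions
#'
#' Percentage of a group that is affected (or that a subgroup makes up),
#' reported on the percent scale as in cohort descriptive tables.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimals to round to (default 2).
#' @return Percentage (numeric scalar).
#' @examples
#' affected_fraction(61861, 2694442)  # 2.30
#' @export
affected_fraction <- function(count, total, digits = 2) {
  if (total <= 0) stop("total must be positive")
  round(100 * count / total, digits)
}

#' Cohort descriptives table
#'
#' The descriptive layout of a familial cohort study: per relationship class
#' (and overall), counts and percent affected by sex, onset-age median and
#' IQR, and the distribution of diagnosis sources.
#'
#' @param registry A `famagg_registry`.
#' @param windows Output of [follow_up()] (computed if `NULL`).
#' @param code Diagnosis code of interest.
#' @return Data frame with one row per (group, sex) cell.
#' @export
cohort_descriptives <- function(registry, windows = NULL, code = "R559") {
  if (is.null(windows)) windows <- follow_up(registry, code = code)
  p <- registry$persons
  aff <- windows$event & !windows$excluded
  cell <- function(label, sel) {
    data.frame(group = label,
               n = sum(sel),
               affected = sum(aff & sel),
               pct_affected = affected_fraction(sum(aff & sel),
                                                max(sum(sel), 1)),
               stringsAsFactors = FALSE)
  }
  rows <- list(cell("all", rep(TRUE, nrow(p))),
               cell("male", p$sex == "male"),
               cell("female", p$sex == "female"),
               cell("twin", !is.na(p$twin_group_id)),
               cell("twin_female", !is.na(p$twin_group_id) &
                      p$sex == "female"))
  do.call(rbind, rows)
}
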