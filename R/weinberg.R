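#' Weinberg differential method for twin zygosity composition
#'
#' Dizygotic (DZ) twin pairs have independently assigned sexes, so the
#' expected number of same-sex DZ pairs equals the number of opposite-sex
#' pairs. The Weinberg differential method therefore estimates the DZ pair
#' count as twice the opposite-sex pair count, with monozygotic (MZ) pairs
#' as the remainder, and the mean genetic resemblance of the twin set as the
#' MZ/DZ mixture of 1.0 and 0.5:
#' \deqn{n_{DZ} = 2\,n_{OS}, \quad n_{MZ} = n_{pairs} - n_{DZ}, \quad
#'       \bar g = (n_{MZ} + 0.5\,n_{DZ}) / n_{pairs}.}
#'
#' Counts are of pairs, not double-entered rows (one row per unordered twin
#' pair).
#'
#' @param n_opposite_sex Number of opposite-sex twin pairs.
#' @param n_same_sex Number of same-sex twin pairs.
#' @return An object of class `weinberg`: list with `n_opposite_sex`,
#'   `n_same_sex`, `n_dz`, `n_mz`, `mz_fraction`, `mean_resemblance`.
#' @examples
#' weinberg(4139, 7871)   # 8278 DZ, 3732 MZ, mean resemblance 0.66
#' @export
weinberg <- function(n_opposite_sex, n_same_sex) {
  if (n_opposite_sex < 0 || n_same_sex < 0)
    stop("pair counts must be non-negative")
  n_pairs <- n_opposite_sex + n_same_sex
  if (n_pairs == 0) stop("no twin pairs supplied")
  n_dz <- 2 * n_opposite_sex
  n_mz <- n_pairs - n_dz
  if (n_mz < 0)
    stop("more opposite-sex than same-sex pairs: the equal-sex assumption ",
         "for dizygotic twins is violated (negative MZ estimate)")
  structure(list(
    n_opposite_sex = n_opposite_sex,
    n_same_sex = n_same_sex,
    n_dz = n_dz,
    n_mz = n_mz,
    mz_fraction = n_mz / n_pairs,
    mean_resemblance = (n_mz * 1.0 + n_dz * 0.5) / n_pairs
  ), class = "weinberg")
}

#' @export
print.weinberg <- function(x, ...) {
  cat("Weinberg differential zygosity estimate\n")
  cat(sprintf("  pairs: %d opposite-sex + %d same-sex = %d\n",
              x$n_opposite_sex, x$n_same_sex,
              x$n_opposite_sex + x$n_same_sex))
  cat(sprintf("  estimated DZ pairs: %d, MZ pairs: %d (MZ fraction %.3f)\n",
              x$n_dz, x$n_mz, x$mz_fraction))
  cat(sprintf("  mean genetic resemblance: %.4f (%.2f)\n",
              x$mean_resemblance, round(x$mean_resemblance, 2)))
  invisible(x)
}

#' Weinberg estimate from a twin pair table
#'
#' Counts same- and opposite-sex twin pairs in a (double-entered or
#' single-entry) twin pair table and applies [weinberg()].
#'
#' @param pairs A `famagg_pairs` data frame with `relation == "twin"`.
#' @param registry The registry supplying each person's sex.
#' @return A `weinberg` object.
#' @export
weinberg_from_pairs <- function(pairs, registry) {
  tw <- pairs[pairs$relation == "twin", , drop = FALSE]
  tw <- single_entry(tw)
  if (!nrow(tw)) stop("no twin pairs supplied")
  p <- registry$persons
  s1 <- p$sex[match(tw$index_id, p$person_id)]
  s2 <- p$sex[match(tw$relative_id, p$person_id)]
  weinberg(sum(s1 != s2), sum(s1 == s2))
}
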