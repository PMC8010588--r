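#' @keywords internal
"_PACKAGE"

# Column schemas for the delimited-text registry files. Missing optional
# fields are encoded as empty strings on disk and NA in memory.
PERSON_COLUMNS <- c(
  "person_id", "sex", "birth_year", "death_year", "emigration_year",
  "mother_id", "father_id", "born_in_country", "county", "education_gt11",
  "twin_group_id"
)
DIAGNOSIS_COLUMNS <- c("person_id", "code", "event_year", "source")

#' Read a person registry and its diagnosis table
#'
#' Reads the two delimited text files (tab or comma separated, auto-detected
#' from the header line) that all other functions in the package consume:
#' a person table with one row per individual (identity, sex, birth year,
#' parent links, vital/migration years, covariates, twin group) and an event
#' table of coded diagnoses.
#'
#' Validation enforces the registry invariants: unique person ids, death and
#' emigration years not before birth, co-twins sharing parents and birth
#' year, and diagnosis years not before birth. Diagnosis rows whose person id
#' is unknown are dropped with a warning (they are reported, not fatal).
#'
#' @param person_file Path to the person table
#'   (columns: `person_id, sex, birth_year, death_year, emigration_year,
#'   mother_id, father_id, born_in_country, county, education_gt11,
#'   twin_group_id`).
#' @param diagnosis_file Path to the diagnosis table
#'   (columns: `person_id, code, event_year, source`). May be `NULL` for a
#'   registry without recorded events.
#' @return An object of class `famagg_registry`: a list with data frames
#'   `persons` and `diagnoses`.
#' @seealso [write_registry()], [simulate_registry()]
#' @examples
#' reg <- simulate_registry(liability_params(n_families = 20, seed = 1))$registry
#' dir <- tempfile(); dir.create(dir)
#' write_registry(reg, dir)
#' reg2 <- read_registry(file.path(dir, "persons.tsv"),
#'                       file.path(dir, "diagnoses.tsv"))
#' identical(reg$persons, reg2$persons)
#' @export
read_registry <- function(person_file, diagnosis_file = NULL) {
  persons <- read_delim_auto(person_file, PERSON_COLUMNS)
  persons$birth_year <- as_year(persons$birth_year, person_file, "birth_year")
  persons$death_year <- as_year(persons$death_year, person_file, "death_year")
  persons$emigration_year <- as_year(persons$emigration_year, person_file,
                                     "emigration_year")
  persons$born_in_country <- as_flag(persons$born_in_country)
  persons$education_gt11 <- as_flag(persons$education_gt11)

  diagnoses <- if (is.null(diagnosis_file)) {
    empty_diagnoses()
  } else {
    d <- read_delim_auto(diagnosis_file, DIAGNOSIS_COLUMNS)
    d$event_year <- as_year(d$event_year, diagnosis_file, "event_year")
    d
  }
  new_registry(persons, diagnoses)
}

#' Write a registry to a directory as delimited text
#'
#' Writes `persons.tsv` and `diagnoses.tsv` (tab-separated, header row, UTF-8,
#' missing optional fields as empty strings) such that [read_registry()]
#' restores an identical registry.
#'
#' @param registry A `famagg_registry`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the two files written.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "famagg_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(persons = file.path(dir, "persons.tsv"),
             diagnoses = file.path(dir, "diagnoses.tsv"))
  write_tsv(registry$persons, paths[["persons"]])
  write_tsv(registry$diagnoses, paths[["diagnoses"]])
  invisible(paths)
}

#' Construct and validate a registry from in-memory tables
#'
#' @param persons Data frame with the person-table columns.
#' @param diagnoses Data frame with the diagnosis-table columns.
#' @return A validated `famagg_registry`.
#' @export
new_registry <- function(persons, diagnoses = empty_diagnoses()) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  diagnoses <- as.data.frame(diagnoses, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PERSON_COLUMNS, names(persons))
  if (length(missing_cols))
    stop("person table lacks columns: ", paste(missing_cols, collapse = ", "))
  missing_cols <- setdiff(DIAGNOSIS_COLUMNS, names(diagnoses))
  if (length(missing_cols))
    stop("diagnosis table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  persons <- persons[PERSON_COLUMNS]
  diagnoses <- diagnoses[DIAGNOSIS_COLUMNS]

  dup <- persons$person_id[duplicated(persons$person_id)]
  if (length(dup))
    stop("duplicate person_id in registry: ",
         paste(unique(dup), collapse = ", "))
  if (!all(persons$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  bad <- !is.na(persons$death_year) & persons$death_year < persons$birth_year
  if (any(bad))
    stop("death_year before birth_year for: ",
         paste(persons$person_id[bad], collapse = ", "))
  bad <- !is.na(persons$emigration_year) &
    persons$emigration_year < persons$birth_year
  if (any(bad))
    stop("emigration_year before birth_year for: ",
         paste(persons$person_id[bad], collapse = ", "))

  # co-twins must share both parents and birth year
  tw <- persons[!is.na(persons$twin_group_id), , drop = FALSE]
  if (nrow(tw)) {
    grp <- split(tw, tw$twin_group_id)
    for (g in grp) {
      if (length(unique(g$birth_year)) > 1L ||
          length(unique(paste(g$mother_id, g$father_id))) > 1L)
        stop("twin group ", g$twin_group_id[1],
             " members differ in parents or birth year")
    }
  }

  if (nrow(diagnoses)) {
    orphan <- !(diagnoses$person_id %in% persons$person_id)
    if (any(orphan)) {
      warning(sum(orphan), " diagnosis row(s) with unknown person_id dropped")
      diagnoses <- diagnoses[!orphan, , drop = FALSE]
    }
    by <- persons$birth_year[match(diagnoses$person_id, persons$person_id)]
    if (any(diagnoses$event_year < by))
      stop("diagnosis event_year before the person's birth_year")
  }
  rownames(persons) <- NULL
  rownames(diagnoses) <- NULL
  structure(list(persons = persons, diagnoses = diagnoses),
            class = "famagg_registry")
}

#' @export
print.famagg_registry <- function(x, ...) {
  cat("Multigeneration person registry\n")
  cat("  persons:   ", nrow(x$persons), "\n")
  cat("  diagnoses: ", nrow(x$diagnoses),
      sprintf(" (%d distinct diagnosed persons)\n",
              length(unique(x$diagnoses$person_id))))
  invisible(x)
}

empty_diagnoses <- function() {
  data.frame(person_id = character(), code = character(),
             event_year = integer(), source = character(),
             stringsAsFactors = FALSE)
}

#' Per-person follow-up windows
#'
#' Derives each person's follow-up window on the year grid: follow-up starts
#' at the study start (1997) or at birth if later, and ends at the first
#' qualifying diagnosis, death, emigration, or the administrative end of
#' follow-up (2015), whichever comes first. A person whose window would end
#' before it starts (e.g. died before 1997) is flagged `excluded` rather than
#' raising an error, matching the cohort's exclusion of families with members
#' who died or emigrated before follow-up began.
#'
#' Person-years are `end - start` in whole years, with a floor of 0.5
#' person-years for a person whose event falls in the very first year of
#' follow-up, so that no observed event carries zero exposure.
#'
#' @param registry A `famagg_registry`.
#' @param code Diagnosis code defining the event of interest (default
#'   `"R559"`, unspecified syncope). The first event with this code sets
#'   onset; later events only feed episode counts.
#' @param study_start,study_end Calendar years bounding follow-up.
#' @return Data frame with one row per person: `person_id`, `start`, `end`,
#'   `event` (logical), `event_year`, `person_years`, `excluded`.
#' @examples
#' reg <- simulate_registry(liability_params(n_families = 10, seed = 1))$registry
#' fw <- follow_up(reg)
#' sum(fw$person_years[!fw$excluded])
#' @export
follow_up <- function(registry, code = "R559",
                      study_start = 1997L, study_end = 2015L) {
  stopifnot(inherits(registry, "famagg_registry"))
  p <- registry$persons
  d <- registry$diagnoses
  d <- d[d$code == code, , drop = FALSE]
  first_event <- if (nrow(d)) {
    tapply(d$event_year, d$person_id, min)
  } else {
    integer(0)
  }
  ev_year <- unname(first_event[match(p$person_id, names(first_event))])

  start <- pmax(p$birth_year, study_start)
  end <- pmin(
    ifelse(is.na(ev_year), Inf, ev_year),
    ifelse(is.na(p$death_year), Inf, p$death_year),
    ifelse(is.na(p$emigration_year), Inf, p$emigration_year),
    study_end
  )
  excluded <- end < start
  event <- !is.na(ev_year) & ev_year <= end & ev_year >= start & !excluded
  py <- pmax(end - start, 0)
  py[event & py == 0] <- 0.5
  py[excluded] <- 0
  data.frame(
    person_id = p$person_id,
    start = start,
    end = ifelse(excluded, NA_real_, end),
    event = event,
    event_year = ifelse(event, ev_year, NA_real_),
    person_years = py,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
}

# ---- internal parsing helpers ----

read_delim_auto <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", na.strings = "",
                         quote = "", comment.char = "", fill = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(expected_cols, names(x))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  x[expected_cols]
}

as_year <- function(x, file, col) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(file, ": malformed ", col, " at data line ", bad[1], ": '",
         x[bad[1]], "'")
  out
}

as_flag <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "no")] <- FALSE
  out
}

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    if (is.logical(v)) v <- ifelse(is.na(v), NA, ifelse(v, "1", "0"))
    df2[[j]] <- v
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}
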