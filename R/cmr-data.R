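#' Study window and demographic periods
#'
#' `study_window()` describes the span of annual capture occasions;
#' `period_table()` builds a table of non-overlapping demographic periods
#' used to stratify the records, and `default_periods()` returns the three
#' periods used throughout the package examples: population increase
#' (1999-2006), decline (2007-2014) and low but stable size (2015-2022).
#'
#' @param first_year,last_year First and last calendar year with capture
#'   occasions.
#' @return `study_window()`: a list with `first_year` and `last_year`;
#'   `period_table()`/`default_periods()`: a tibble with columns `label`,
#'   `start_year`, `end_year`.
#' @export
study_window <- function(first_year = 1999, last_year = 2022) {
  stopifnot(first_year < last_year)
  structure(list(first_year = as.integer(first_year),
                 last_year = as.integer(last_year)),
            class = "study_window")
}

#' @rdname study_window
#' @param start_year,end_year Integer vectors of period bounds (inclusive).
#' @param label Optional character labels; default `"start-end"`.
#' @export
period_table <- function(start_year, end_year, label = NULL) {
  stopifnot(length(start_year) == length(end_year), all(start_year <= end_year))
  if (is.null(label)) label <- paste0(start_year, "-", end_year)
  out <- tibble::tibble(label = label,
                        start_year = as.integer(start_year),
                        end_year = as.integer(end_year))
  out <- dplyr::arrange(out, .data$start_year)
  if (any(out$start_year[-1] <= out$end_year[-nrow(out)])) {
    rlang::abort("periods must be non-overlapping", class = "mortraj_config_error")
  }
  out
}

#' @rdname study_window
#' @export
default_periods <- function() {
  period_table(c(1999, 2007, 2015), c(2006, 2014, 2022))
}

# ---- detection-column helpers ------------------------------------------

cmr_meta_cols <- c("id", "sex", "birth_min", "birth_max", "death_min", "death_max")

det_cols <- function(records) {
  nm <- names(records)
  nm[grepl("^[Xy]?[0-9]{4}$", nm)]
}

det_years <- function(records) {
  as.integer(sub("^[Xy]", "", det_cols(records)))
}

det_matrix <- function(records) {
  m <- as.matrix(records[det_cols(records)])
  storage.mode(m) <- "integer"
  colnames(m) <- as.character(det_years(records))
  m
}

cmr_window <- function(records, window = NULL) {
  if (!is.null(window)) return(window)
  yrs <- det_years(records)
  study_window(min(yrs), max(yrs))
}

# first/last detection year and number of detected years per record
det_summary <- function(records) {
  m <- det_matrix(records)
  yrs <- det_years(records)
  idx_first <- apply(m == 1L, 1, function(z) which(z)[1])
  idx_last <- apply(m == 1L, 1, function(z) {
    w <- which(z)
    if (length(w)) w[length(w)] else NA_integer_
  })
  tibble::tibble(
    first_det = yrs[idx_first],
    last_det = yrs[idx_last],
    n_det = as.integer(rowSums(m == 1L))
  )
}

# ---- reading / writing --------------------------------------------------

#' Read and validate a capture-mark-recapture table
#'
#' Reads a comma-separated table with one row per marked individual:
#' columns `id`, `sex` (`female`/`male`, `f`/`m` accepted), calendar-year
#' bounds `birth_min`, `birth_max`, `death_min`, `death_max` (empty or
#' `NA` when unknown), then one 0/1 column per study year (named e.g.
#' `1999` or `X1999`) holding the annual detection indicator. Every record
#' is validated; malformed rows abort with their row numbers.
#'
#' @param path Path to a CSV file (UTF-8, header required).
#' @param window Optional [study_window()]; defaults to the span of the
#'   year columns found in the file.
#' @return A tibble of validated records (year columns renamed to plain
#'   `"1999"`-style names).
#' @export
read_cmr <- function(path, window = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"), name_repair = "minimal")
  names(raw) <- sub("^[Xy]([0-9]{4})$", "\\1", names(raw))
  missing_meta <- setdiff(cmr_meta_cols, names(raw))
  if (length(missing_meta)) {
    rlang::abort(paste("missing required columns:",
                       paste(missing_meta, collapse = ", ")),
                 class = "mortraj_config_error")
  }
  records <- dplyr::mutate(
    tibble::as_tibble(raw),
    id = as.character(.data$id),
    dplyr::across(dplyr::all_of(c("birth_min", "birth_max",
                                  "death_min", "death_max")), as.integer),
    dplyr::across(dplyr::all_of(det_cols(raw)), as.integer)
  )
  validate_cmr(records, window = window)
}

#' @rdname read_cmr
#' @param records A validated records tibble.
#' @export
write_cmr <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Validate capture-mark-recapture records
#'
#' Checks the structural invariants every record must satisfy: unique ids,
#' known sex codes, at least one detection inside the study window,
#' ordered birth/death bounds, and no detection before the earliest
#' possible birth or after the latest possible death. All violations are
#' collected and reported together with row numbers.
#'
#' @inheritParams read_cmr
#' @param records A records tibble (see [read_cmr()] for the layout).
#' @return The records, invisibly unchanged apart from normalised sex
#'   codes, or an error of class `mortraj_validation_error`.
#' @export
validate_cmr <- function(records, window = NULL) {
  sex_map <- c(female = "female", male = "male", f = "female", m = "male")
  records$sex <- unname(sex_map[tolower(as.character(records$sex))])

  yrs <- det_years(records)
  if (!length(yrs)) {
    rlang::abort("no detection-year columns found", class = "mortraj_config_error")
  }
  window <- cmr_window(records, window)
  if (min(yrs) < window$first_year || max(yrs) > window$last_year) {
    rlang::abort("detection columns outside the study window",
                 class = "mortraj_validation_error")
  }

  probs <- character()
  note <- function(rows, msg) {
    if (length(rows)) {
      probs <<- c(probs, paste0(msg, " (rows ", paste(rows, collapse = ", "), ")"))
    }
  }
  note(which(duplicated(records$id)), "duplicate id")
  note(which(is.na(records$sex)), "unknown sex code")

  ds <- det_summary(records)
  note(which(ds$n_det == 0L), "no detections")
  note(which(!is.na(records$birth_min) & !is.na(records$birth_max) &
               records$birth_min > records$birth_max), "birth_min > birth_max")
  note(which(!is.na(records$death_min) & !is.na(records$death_max) &
               records$death_min > records$death_max), "death_min > death_max")
  note(which(!is.na(records$birth_max) & !is.na(records$death_min) &
               records$birth_max > records$death_min), "birth_max > death_min")
  note(which(!is.na(records$birth_min) & ds$first_det < records$birth_min),
       "detection before earliest possible birth")
  note(which(!is.na(records$death_max) & ds$last_det > records$death_max),
       "detection after latest possible death")

  if (length(probs)) {
    rlang::abort(paste0("invalid CMR records:\n  ",
                        paste(probs, collapse = "\n  ")),
                 class = "mortraj_validation_error")
  }
  records
}

# ---- bound construction -------------------------------------------------

#' Impute birth and death bounds for records with unknown times
#'
#' `apply_death_bounds()` implements the bound rule for individuals whose
#' death was never observed: the earliest possible death year is the last
#' recapture year, and the latest is the last recapture year plus
#' `max_gap` years (strong philopatry means an individual missing for
#' `max_gap` consecutive years has died), further capped at the birth year
#' plus the species' maximum longevity. When the last recapture lies
#' within `max_gap` years of the end of the study window the upper bound
#' cannot be asserted and the record is left right-censored (`death_max`
#' stays `NA`). The operation is idempotent and never touches records with
#' an observed death.
#'
#' `apply_birth_bounds()` fills open birth bounds for individuals first
#' marked as adults: latest possible birth is the year before first
#' capture, earliest is `max_longevity` years before first capture.
#'
#' @param records A validated records tibble.
#' @param max_gap Years after the last recapture within which death is
#'   certain (default 2).
#' @param max_longevity Maximum lifespan of the species in years
#'   (default 6).
#' @param window Optional [study_window()]; defaults to the span of the
#'   detection columns.
#' @return The records tibble with bounds filled in.
#' @export
apply_death_bounds <- function(records, max_gap = 2, max_longevity = 6,
                               window = NULL) {
  window <- cmr_window(records, window)
  ds <- det_summary(records)
  open <- is.na(records$death_max)
  dmin <- ifelse(open, ds$last_det, records$death_min)
  censored <- open & (ds$last_det + max_gap > window$last_year)
  cap <- ifelse(is.na(records$birth_max), .Machine$integer.max,
                records$birth_max + max_longevity)
  dmax <- ifelse(open & !censored,
                 pmin(ds$last_det + max_gap, cap),
                 records$death_max)
  bad <- which(!is.na(dmax) & dmax < dmin)
  if (length(bad)) {
    rlang::abort(paste0("death bounds inconsistent after rule application (rows ",
                        paste(bad, collapse = ", "), ")"),
                 class = "mortraj_validation_error")
  }
  records$death_min <- as.integer(dmin)
  records$death_max <- as.integer(dmax)
  records
}

#' @rdname apply_death_bounds
#' @export
apply_birth_bounds <- function(records, max_longevity = 6) {
  ds <- det_summary(records)
  open <- is.na(records$birth_min) | is.na(records$birth_max)
  records$birth_max <- as.integer(ifelse(open, ds$first_det - 1L, records$birth_max))
  records$birth_min <- as.integer(ifelse(open, ds$first_det - max_longevity,
                                         records$birth_min))
  records
}

#' @rdname apply_death_bounds
#' @export
prepare_cmr <- function(records, max_gap = 2, max_longevity = 6, window = NULL) {
  records <- apply_birth_bounds(records, max_longevity = max_longevity)
  records <- apply_death_bounds(records, max_gap = max_gap,
                                max_longevity = max_longevity, window = window)
  validate_cmr(records, window = window)
}

# ---- stratification and counts -----------------------------------------

#' Assign records to sex-by-period strata
#'
#' Adds a `period` column by natal cohort: each individual is assigned to
#' the period containing its birth year (`birth_min` when the birth year
#' is uncertain), so its whole capture history stays in one stratum even
#' when it survives across a period boundary. Records born outside every
#' period get `NA` and a message.
#'
#' @param records A records tibble with birth bounds filled in.
#' @param periods A [period_table()]; defaults to [default_periods()].
#' @return The records with a `period` factor column.
#' @seealso [stratum_sizes()]
#' @export
split_periods <- function(records, periods = default_periods()) {
  birth <- records$birth_min
  idx <- findInterval(birth, periods$start_year)
  ok <- idx >= 1 & idx <= nrow(periods) & birth <= periods$end_year[pmax(idx, 1)]
  lab <- rep(NA_character_, nrow(records))
  lab[ok] <- periods$label[idx[ok]]
  if (any(!ok)) {
    rlang::inform(sprintf("%d record(s) born outside all periods assigned NA",
                          sum(!ok)))
  }
  records$period <- factor(lab, levels = periods$label)
  records
}

#' @rdname split_periods
#' @export
stratum_sizes <- function(records) {
  dplyr::count(records, .data$sex, .data$period, name = "n")
}

#' Basic totals of a CMR record collection
#'
#' @param records A records tibble (possibly empty).
#' @return A one-row tibble: `n_individuals`, `n_detection_years` (number
#'   of individual-year detection events), and `n_captures` (`NA` unless
#'   per-event capture counts are present, which this annual layout does
#'   not carry).
#' @export
count_summary <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(n_individuals = 0L, n_detection_years = 0L,
                          n_captures = NA_integer_))
  }
  tibble::tibble(
    n_individuals = nrow(records),
    n_detection_years = sum(det_matrix(records) == 1L),
    n_captures = NA_integer_
  )
}
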