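# Studbook editing: the data-quality rules that define the training dataset
# (complete six-season careers) and the full dataset (at least three seasons).

#' Editing rules for mare careers
#'
#' @param min_birth_year Mares must be born strictly after this year.
#' @param min_first_event_age,max_first_event_age Age window (months) for the
#'   first registered event; the defaults 36-59 keep the age-3 (36-47) and
#'   age-4 (48-59) first-foaling classes.
#' @param min_foaling_interval,max_foaling_interval Admissible interval
#'   (months) between foalings registered in consecutive breeding seasons;
#'   values outside flag recording errors and discard the mare.
#' @param min_eu_by_records Minimum records per environmental-unit-by-birth-
#'   year (EU-BY) level; sparser levels are removed, iterating to a fixed
#'   point because removals can empty further levels.
#' @param require_both_parents Discard mares with an unknown sire or dam?
#' @param min_seasons Minimum registered breeding seasons: 6 selects the
#'   training dataset of complete careers, 3 the full dataset.
#' @return A validated list of class `"editing_rules"`.
#' @export
editing_rules <- function(min_birth_year = 1990L,
                          min_first_event_age = 36L,
                          max_first_event_age = 59L,
                          min_foaling_interval = 11L,
                          max_foaling_interval = 17L,
                          min_eu_by_records = 2L,
                          require_both_parents = TRUE,
                          min_seasons = 6L) {
  if (min_first_event_age >= max_first_event_age)
    fail("first-event age window must have min < max")
  if (min_foaling_interval >= max_foaling_interval)
    fail("foaling-interval window must have min < max")
  if (!min_seasons %in% 3:6)
    fail("'min_seasons' must be between 3 and 6")
  out <- list(min_birth_year = min_birth_year,
              min_first_event_age = min_first_event_age,
              max_first_event_age = max_first_event_age,
              min_foaling_interval = min_foaling_interval,
              max_foaling_interval = max_foaling_interval,
              min_eu_by_records = min_eu_by_records,
              require_both_parents = require_both_parents,
              min_seasons = as.integer(min_seasons))
  class(out) <- "editing_rules"
  out
}

# Summarize events into one career row per mare.  Foal counts f3..f6 are
# cumulative foalings after 3..6 seasons (NA beyond the registered career).
careers_from_events <- function(events, pedigree) {
  ev <- events[order(events$mare_id, events$event_year), ]
  n <- nrow(ev)
  ev$season <- stats::ave(seq_len(n), ev$mare_id, FUN = seq_along)
  foal <- ev$event_type == "F"
  cumf <- stats::ave(as.integer(foal), ev$mare_id, FUN = cumsum)

  mare <- unique(ev$mare_id)
  m <- length(mare)
  row_of <- function(keep) {             # mare -> row index satisfying keep
    idx <- match(mare, ev$mare_id[keep])
    which(keep)[idx]
  }
  first_row <- row_of(ev$season == 1L)
  L <- as.integer(tapply(ev$season, factor(ev$mare_id, levels = mare), max))

  fk <- function(k) {
    r <- row_of(ev$season == k)
    ifelse(is.na(r), NA_integer_, cumf[r])
  }
  ffr <- row_of(foal)                    # first foaling row per mare
  first_foal_age <- ifelse(is.na(ffr), NA_integer_, ev$age_months[ffr])
  af <- ifelse(is.na(first_foal_age), NA_integer_,
               ifelse(first_foal_age < 48L, 3L, 4L))

  # Consecutive calendar years within a career.
  same <- ev$mare_id[-1] == ev$mare_id[-n]
  gap <- c(same & diff(ev$event_year) != 1L, FALSE)
  has_gap <- tapply(gap, factor(ev$mare_id, levels = mare), any)

  # Intervals between foalings registered in adjacent seasons.
  adj <- c(same, FALSE) & foal & c(foal[-1], FALSE)
  iv <- ev$age_months[which(adj) + 1L] - ev$age_months[adj]
  ivf <- factor(ev$mare_id[adj], levels = mare)
  min_iv <- suppressWarnings(as.integer(tapply(iv, ivf, min)))
  max_iv <- suppressWarnings(as.integer(tapply(iv, ivf, max)))

  pi <- match(mare, pedigree$animal)
  car <- data.frame(
    mare_id = mare,
    birth_year = pedigree$birth_year[pi],
    eu_id = ev$eu_id[first_row],
    n_seasons = L,
    first_event_age = ev$age_months[first_row],
    first_foal_age = first_foal_age,
    af_class = af,
    f3 = fk(3L), f4 = fk(4L), f5 = fk(5L), f6 = fk(6L),
    foals_total = as.integer(tapply(cumf, factor(ev$mare_id, levels = mare), max)),
    min_interval = min_iv,
    max_interval = max_iv,
    years_consecutive = !as.logical(has_gap),
    sire = pedigree$sire[pi],
    dam = pedigree$dam[pi],
    stringsAsFactors = FALSE
  )
  car$eu_by <- paste(car$eu_id, car$birth_year, sep = ":")
  rownames(car) <- NULL
  car
}

#' Apply the editing rules to studbook events
#'
#' Filters mare careers by birth year, first-event age window, consecutive
#' registered seasons, foaling-interval window (between foalings in adjacent
#' seasons), known parents and minimum career length, then removes EU-BY
#' levels with too few records, iterating to a fixed point.  The age-at-
#' first-foaling class (3 or 4 years) is derived from the age at the first
#' foaling event.
#'
#' @param events Event table ([read_studbook()] / [simulate_careers()]).
#' @param pedigree Pedigree table covering the recorded mares.
#' @param rules An [editing_rules()] object.
#' @return A career data frame (one row per retained mare) with foal counts
#'   after 3-6 seasons, `af_class`, `eu_by` and parent columns.  The
#'   attribute `"edit_report"` counts mares removed by each rule.
#' @export
apply_editing <- function(events, pedigree, rules = editing_rules()) {
  stopifnot(inherits(rules, "editing_rules"))
  car <- careers_from_events(events, pedigree)
  report <- c(input = nrow(car))
  drop_step <- function(car, keep, label) {
    report[label] <<- sum(!keep)
    car[keep, , drop = FALSE]
  }
  car <- drop_step(car, !is.na(car$birth_year) &
                     car$birth_year > rules$min_birth_year, "birth_year")
  car <- drop_step(car, car$first_event_age >= rules$min_first_event_age &
                     car$first_event_age <= rules$max_first_event_age,
                   "first_event_age")
  car <- drop_step(car, car$years_consecutive, "non_consecutive_seasons")
  car <- drop_step(car, is.na(car$min_interval) |
                     (car$min_interval >= rules$min_foaling_interval &
                        car$max_interval <= rules$max_foaling_interval),
                   "foaling_interval")
  if (rules$require_both_parents)
    car <- drop_step(car, car$sire != UNKNOWN_PARENT &
                       car$dam != UNKNOWN_PARENT, "unknown_parent")
  car <- drop_step(car, car$n_seasons >= rules$min_seasons, "min_seasons")
  # Mares that never foaled have no age-at-first-foaling class and cannot
  # carry the AF fixed effect.
  car <- drop_step(car, !is.na(car$af_class), "no_foaling")

  # EU-BY minimum-records filter, iterated to a fixed point.
  removed_eu <- 0L
  repeat {
    counts <- table(car$eu_by)
    small <- names(counts)[counts < rules$min_eu_by_records]
    if (length(small) == 0L) break
    removed_eu <- removed_eu + sum(car$eu_by %in% small)
    car <- car[!car$eu_by %in% small, , drop = FALSE]
  }
  report["eu_by_min_records"] <- removed_eu
  report["retained"] <- nrow(car)
  if (nrow(car) == 0L)
    warning("editing removed every mare", call. = FALSE)
  rownames(car) <- NULL
  car$years_consecutive <- NULL
  attr(car, "edit_report") <- report
  car
}

#' Environmental-unit-by-birth-year levels
#'
#' @param careers Career table from [apply_editing()].
#' @return Data frame of EU-BY levels with record counts, plus attributes
#'   `n_levels` and `mean_records`.
#' @export
build_eu_by <- function(careers) {
  if (is.null(careers) || nrow(careers) == 0L) fail("no careers supplied")
  tab <- as.data.frame(table(eu_by = careers$eu_by),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "records"
  attr(tab, "n_levels") <- nrow(tab)
  attr(tab, "mean_records") <- mean(tab$records)
  tab
}
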