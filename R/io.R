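# Reading and writing studbook-style CSV files.
#
# Studbook schema:  mare_id, event_year, event_type (F/A/O), age_months, eu_id
# Pedigree schema:  animal, sire, dam, birth_year, sex (missing parent = 0)

EVENT_TYPES <- c("F", "A", "O")

#' Write reproductive events to a studbook CSV
#'
#' @param events Event table from [simulate_careers()] or [read_studbook()].
#' @param path Output file (UTF-8, header row, comma separated).
#' @export
write_studbook <- function(events, path) {
  cols <- c("mare_id", "event_year", "event_type", "age_months", "eu_id")
  write.csv(events[, cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a pedigree CSV
#'
#' @param pedigree Pedigree table (`animal`, `sire`, `dam`, `birth_year`,
#'   `sex`); missing parents coded 0.
#' @param path Output file.
#' @export
write_pedigree <- function(pedigree, path) {
  cols <- c("animal", "sire", "dam", "birth_year", "sex")
  write.csv(pedigree[, cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a studbook CSV of reproductive events
#'
#' Validates the schema, the event vocabulary (`F` foaling, `A` abortion,
#' `O` open) and uniqueness of (mare, season-year) records; malformed rows
#' are reported with their line numbers.
#'
#' @param path CSV file with columns `mare_id`, `event_year`, `event_type`,
#'   `age_months`, `eu_id`.
#' @return Typed event data frame ordered by mare and year.
#' @export
read_studbook <- function(path) {
  if (!file.exists(path)) fail("studbook file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = c(event_type = "character"))
  need <- c("mare_id", "event_year", "event_type", "age_months", "eu_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fail("studbook is missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(!df$event_type %in% EVENT_TYPES)
  if (length(bad))
    fail("invalid event_type %s at line %d (expected F, A or O)",
         df$event_type[bad[1]], bad[1] + 1L)
  for (col in c("mare_id", "event_year", "age_months", "eu_id")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      fail("malformed value in column '%s' at line %d", col, bad[1] + 1L)
    df[[col]] <- v
  }
  dup <- duplicated(df[, c("mare_id", "event_year")])
  if (any(dup))
    fail("duplicate (mare, season) record at line %d", which(dup)[1] + 1L)
  df <- df[order(df$mare_id, df$event_year), ]
  df$season <- stats::ave(seq_len(nrow(df)), df$mare_id, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Read a pedigree CSV
#'
#' @param path CSV file with columns `animal`, `sire`, `dam`, `birth_year`,
#'   `sex`; missing parents may be coded 0, empty or NA and are normalized
#'   to 0.
#' @return Typed pedigree data frame.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) fail("pedigree file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("animal", "sire", "dam", "birth_year", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fail("pedigree is missing columns: %s", paste(miss, collapse = ", "))
  for (col in c("animal", "sire", "dam", "birth_year")) {
    v <- df[[col]]
    v[is.na(v) | v == ""] <- UNKNOWN_PARENT
    v <- suppressWarnings(as.integer(v))
    bad <- which(is.na(v))
    if (length(bad))
      fail("malformed value in column '%s' at line %d", col, bad[1] + 1L)
    df[[col]] <- v
  }
  if (anyDuplicated(df$animal))
    fail("duplicated animal id: %d", df$animal[anyDuplicated(df$animal)])
  self <- df$animal == df$sire | df$animal == df$dam
  if (any(self & df$animal != UNKNOWN_PARENT))
    fail("animal %d is listed as its own parent", df$animal[which(self)[1]])
  ped_prepare(df[, c("animal", "sire", "dam")])  # cycle guard
  df
}
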