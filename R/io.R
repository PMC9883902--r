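# Readers and writers for the three file shapes the toolkit touches:
# vital-records CSV (death-file-like), registry CSV (cancer-registry-like),
# and surname lists (plain text, one name per line, or CSV with provenance).
# All I/O is UTF-8; column layouts vary by source year, so record readers
# take a dialect mapping from canonical field -> actual column name.

.VITAL_FIELDS <- c(surname = "surname", father_surname = "father_surname",
                   first_name = "first_name", sex = "sex",
                   birthplace = "birthplace", birth_year = "birth_year",
                   death_year = "death_year")

.REGISTRY_FIELDS <- c(surname = "surname", maiden_name = "maiden_name",
                      father_surname = "father_surname",
                      country_of_birth = "country_of_birth",
                      on_reference_list = "on_reference_list")

read_records <- function(path, dialect, canonical, what) {
  if (!file.exists(path)) config_error("cannot read ", what, " file: ", path)
  dialect <- utils::modifyList(as.list(canonical), as.list(dialect))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  if (!dialect$surname %in% names(df)) {
    config_error("required surname column ", sQuote(dialect$surname),
                 " not found in ", path)
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (field in names(canonical)) {
    col <- dialect[[field]]
    out[[field]] <- if (col %in% names(df)) df[[col]] else rep(NA, nrow(df))
  }
  out$surname <- trimws(as.character(out$surname))
  keep <- !is.na(out$surname) & nzchar(out$surname)
  skipped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  attr(out, "source_file") <- path
  out
}

#' Read vital records (death-file-style CSV)
#'
#' Reads a CSV with one row per death record into a canonical data.frame with
#' columns `surname`, `father_surname`, `first_name`, `sex`, `birthplace`,
#' `birth_year`, `death_year`. Columns absent from the file come back as `NA`;
#' rows with an empty surname are skipped and counted in the `n_skipped`
#' attribute. A missing birthplace is the "unknown" stratum downstream.
#'
#' @param path path to the CSV file (header row required).
#' @param dialect named list mapping canonical field names to the column names
#'   actually used in the file, e.g. `list(surname = "LAST_NAME")`. Unmapped
#'   fields use the canonical name.
#' @return data.frame of vital records with attribute `n_skipped`.
#' @seealso [read_registry_records()], [read_surname_list()]
#' @export
read_vital_records <- function(path, dialect = list()) {
  rec <- read_records(path, dialect, .VITAL_FIELDS, "vital records")
  for (f in c("birth_year", "death_year")) {
    rec[[f]] <- suppressWarnings(as.integer(rec[[f]]))
  }
  bad <- !is.na(rec$birth_year) & !is.na(rec$death_year) &
    rec$birth_year > rec$death_year
  if (any(bad)) {
    warning(sum(bad), " record(s) with birth_year > death_year",
            call. = FALSE)
  }
  rec
}

#' Read registry records (cancer-registry-style CSV)
#'
#' Canonical columns: `surname`, `maiden_name`, `father_surname`,
#' `country_of_birth`, `on_reference_list` (tri-state: `TRUE`/`FALSE`/`NA`).
#'
#' @inheritParams read_vital_records
#' @return data.frame of registry records with attribute `n_skipped`.
#' @export
read_registry_records <- function(path, dialect = list()) {
  rec <- read_records(path, dialect, .REGISTRY_FIELDS, "registry")
  rec$on_reference_list <- as.logical(rec$on_reference_list)
  rec
}

#' Read a surname list from disk
#'
#' Accepts either plain text (one surname per line) or a CSV with a `surname`
#' column plus optional `source`, `truncated`, `evidence` provenance columns
#' (as written by [write_surname_list()]). Input order is preserved; exact
#' duplicate spellings (after uppercasing and trimming) are collapsed with a
#' warning. An empty file yields an empty list with a warning, not an error.
#'
#' @param path path to the file.
#' @param format `"auto"` (sniff a CSV header), `"plain"` or `"csv"`.
#' @param name optional list name.
#' @return a [surname_list].
#' @export
read_surname_list <- function(path, format = c("auto", "plain", "csv"),
                              name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) config_error("cannot read surname list: ", path)
  if (is.null(name)) name <- basename(path)
  first <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (format == "auto") {
    format <- if (length(first) && grepl("^surname([,].*)?$", first))
      "csv" else "plain"
  }
  if (length(first) == 0L) {
    warning("empty surname list file: ", path, call. = FALSE)
    return(surname_list(name = name))
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    df <- df[!is.na(df$surname) & nzchar(trimws(df$surname)), , drop = FALSE]
    if ("evidence" %in% names(df)) {  # all-empty column reads back as NA
      df$evidence <- as.character(df$evidence)
      df$evidence[is.na(df$evidence)] <- ""
    }
    as_surname_list(df, name = name)
  } else {
    lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      warning("empty surname list file: ", path, call. = FALSE)
    }
    surname_list(lines, name = name)
  }
}

#' Write a surname list to disk
#'
#' Plain format writes one surname per line; CSV format adds the `source`,
#' `truncated` and `evidence` provenance columns. Output is sorted
#' lexicographically by uppercased surname (C collation) so repeated runs are
#' byte-identical, and `read_surname_list(write_surname_list(x))` preserves
#' the set of (surname, source) pairs.
#'
#' @param x a [surname_list] (or anything [as_surname_list()] accepts).
#' @param path output path.
#' @param format `"plain"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_surname_list <- function(x, path, format = c("plain", "csv")) {
  format <- match.arg(format)
  x <- as_surname_list(x)
  ord <- order(toupper(x$surname), method = "radix")
  x <- x[ord, , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "plain") {
    writeLines(enc2utf8(x$surname), con, useBytes = TRUE)
  } else {
    df <- as.data.frame(x)[, c("surname", "source", "truncated", "evidence")]
    lines <- c(
      "surname,source,truncated,evidence",
      paste(csv_quote(df$surname), df$source, tolower(df$truncated),
            csv_quote(df$evidence), sep = ","))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(path)
}

csv_quote <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}
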