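# surname_list: a named, ordered, deduplicated collection of surname entries
# with provenance. Internally a data.frame with columns surname, source,
# truncated, evidence; uniqueness key is the uppercased exact spelling
# (punctuation preserved, so 'Ter-Minasyan' and 'Ter Minasyan' stay distinct).

.SOURCES <- c("reference_linked", "birthplace_added", "reference_retained",
              "external")

#' Create a surname list
#'
#' @param surname character vector of surnames as spelled.
#' @param source provenance of each entry: one of `"reference_linked"`,
#'   `"birthplace_added"`, `"reference_retained"`, `"external"` (recycled).
#' @param truncated logical; whether the spelling is a truncated form (only
#'   reference-derived or external entries may be truncated; recycled).
#' @param evidence free-text provenance note (recycled).
#' @param name optional list name used in printing.
#' @param warn warn when duplicate spellings (after uppercasing and trimming)
#'   are collapsed.
#' @return an object of class `surname_list`: a data.frame with columns
#'   `surname`, `source`, `truncated`, `evidence`, input order preserved,
#'   duplicates collapsed (first occurrence wins) with the number dropped in
#'   `attr(, "n_duplicates")`.
#' @examples
#' surname_list(c("Mahtesyan", "Mahtesian"))
#' @export
surname_list <- function(surname = character(), source = "external",
                         truncated = FALSE, evidence = "",
                         name = NULL, warn = TRUE) {
  surname <- trimws(as.character(surname))
  stopifnot(all(nzchar(surname)))
  source <- rep_len(as.character(source), length(surname))
  if (length(surname) && !all(source %in% .SOURCES)) {
    stop("unknown source tag(s): ",
         paste(unique(setdiff(source, .SOURCES)), collapse = ", "),
         call. = FALSE)
  }
  truncated <- rep_len(as.logical(truncated), length(surname))
  bad <- truncated & source == "birthplace_added"
  if (any(bad)) {
    stop("birthplace_added entries cannot be truncated: ",
         paste(sQuote(surname[bad]), collapse = ", "), call. = FALSE)
  }
  evidence <- rep_len(as.character(evidence), length(surname))
  key <- toupper(surname)
  dup <- duplicated(key)
  if (any(dup) && warn) {
    warning(sum(dup), " duplicate spelling(s) collapsed", call. = FALSE)
  }
  out <- data.frame(surname = surname[!dup], source = source[!dup],
                    truncated = truncated[!dup], evidence = evidence[!dup],
                    stringsAsFactors = FALSE)
  structure(out, class = c("surname_list", "data.frame"),
            list_name = name, n_duplicates = sum(dup))
}

#' Test for / coerce to a surname list
#'
#' @param x object to test or coerce (character vectors and data.frames with a
#'   `surname` column are accepted).
#' @param ... passed to [surname_list()].
#' @return `is_surname_list`: logical. `as_surname_list`: a `surname_list`.
#' @export
is_surname_list <- function(x) inherits(x, "surname_list")

#' @rdname is_surname_list
#' @export
as_surname_list <- function(x, ...) {
  if (is_surname_list(x)) return(x)
  if (is.character(x)) return(surname_list(x, ...))
  if (is.data.frame(x) && "surname" %in% names(x)) {
    return(surname_list(
      x$surname,
      source    = if ("source" %in% names(x)) x$source else "external",
      truncated = if ("truncated" %in% names(x)) x$truncated else FALSE,
      evidence  = if ("evidence" %in% names(x)) x$evidence else "", ...))
  }
  stop("cannot coerce object of class ", class(x)[1], " to surname_list",
       call. = FALSE)
}

# uppercased spelling set of a list (or character vector) -- the membership key
surname_key <- function(x) {
  if (is_surname_list(x) || is.data.frame(x)) x <- x$surname
  unique(toupper(trimws(as.character(x))))
}

#' @export
print.surname_list <- function(x, n = 10, ...) {
  nm <- attr(x, "list_name")
  cat("surname_list", if (!is.null(nm)) paste0(" '", nm, "'"), ": ",
      nrow(x), " entries\n", sep = "")
  if (nrow(x)) {
    tab <- table(x$source)
    cat("  sources:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
    if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  }
  invisible(x)
}
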