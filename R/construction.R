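# End-to-end surname-list assembly, mirroring the two-step construction:
#   Step 1  link the reference extract to surnames harvested from vital
#           records (Soundex-blocked, not restricted by birthplace) -- linked
#           record-side spellings (and, by default, the reference spellings)
#           enter the list as reference_linked;
#   Step 2  harvest surnames from records with the target birthplace that did
#           not link in Step 1, filter them by the suffix/length deletion
#           rules, and add the survivors as birthplace_added;
#   finally reference surnames neither linked nor re-found by birthplace are
#           retained verbatim as reference_retained.
# Every output entry carries exactly one source tag and the build returns a
# full audit of the counts at each stage.

#' Build configuration
#'
#' @param target_birthplace country whose birthplace records feed Step 2
#'   (compared case-insensitively after trimming).
#' @param linkage a [linkage_config()].
#' @param filter a [filter_config()].
#' @param harvest_father_surname also harvest the father's surname field
#'   (default `TRUE`): catches families whose last name drifted to another
#'   naming convention while the patronymic line kept the original.
#' @param emit_truncated_reference also emit the reference-side spelling of a
#'   truncation match (default `TRUE`, so truncated reference forms are
#'   retained alongside the full record-side spelling).
#' @param collapse_punctuation_variants treat spellings that normalize
#'   identically (hyphen vs space) as one entry (default `FALSE`: spelling
#'   variants are kept as distinct surnames).
#' @return an object of class `build_config`.
#' @export
build_config <- function(target_birthplace = "Armenia",
                         linkage = linkage_config(),
                         filter = filter_config(),
                         harvest_father_surname = TRUE,
                         emit_truncated_reference = TRUE,
                         collapse_punctuation_variants = FALSE) {
  stopifnot(is.character(target_birthplace), nzchar(target_birthplace),
            inherits(linkage, "linkage_config"),
            inherits(filter, "filter_config"))
  structure(list(target_birthplace = target_birthplace,
                 linkage = linkage, filter = filter,
                 harvest_father_surname = isTRUE(harvest_father_surname),
                 emit_truncated_reference = isTRUE(emit_truncated_reference),
                 collapse_punctuation_variants =
                   isTRUE(collapse_punctuation_variants)),
            class = "build_config")
}

#' Harvest unique surnames from vital records
#'
#' Unique (uppercased-exact) surnames from the `surname` field and, when
#' configured, the `father_surname` field; each entry notes the field(s) it
#' came from.
#'
#' @param records vital-records data.frame (see [read_vital_records()]).
#' @param config a [build_config()].
#' @return a [surname_list] with source `"external"`.
#' @export
harvest_surnames <- function(records, config = build_config()) {
  vals <- c(clean_names(records$surname))
  origin <- rep("surname", length(vals))
  if (config$harvest_father_surname && "father_surname" %in% names(records)) {
    f <- clean_names(records$father_surname)
    vals <- c(vals, f)
    origin <- c(origin, rep("father_surname", length(f)))
  }
  if (!length(vals)) return(surname_list())
  key <- toupper(vals)
  ev <- vapply(split(origin, key), function(o)
    paste(sort(unique(o)), collapse = "+"), character(1))
  first <- !duplicated(key)
  surname_list(vals[first], source = "external",
               evidence = unname(ev[key[first]]), warn = FALSE)
}

clean_names <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & nzchar(x)]
}

#' Birthplace-derived candidate surnames
#'
#' Surnames harvested from records carrying the target birthplace, minus any
#' spelling already linked in Step 1. Records with a missing birthplace are
#' the "unknown" stratum and never contribute candidates.
#'
#' @param records vital-records data.frame.
#' @param linked character vector of spellings already linked (uppercased
#'   comparison).
#' @param config a [build_config()].
#' @return a [surname_list] of candidates.
#' @export
birthplace_candidates <- function(records, linked, config = build_config()) {
  sel <- birthplace_stratum(records$birthplace,
                            config$target_birthplace) == "target"
  cand <- harvest_surnames(records[sel, , drop = FALSE], config)
  keep <- !(toupper(cand$surname) %in% toupper(linked))
  if (!any(keep)) return(surname_list())
  surname_list(cand$surname[keep], source = "external",
               evidence = cand$evidence[keep], warn = FALSE)
}

# target / other / unknown stratum of a birthplace field
birthplace_stratum <- function(birthplace, target) {
  bp <- trimws(as.character(birthplace))
  out <- rep("other", length(bp))
  out[is.na(bp) | !nzchar(bp)] <- "unknown"
  out[!is.na(bp) & toupper(bp) == toupper(target)] <- "target"
  out
}

#' Build a surname list from a reference extract and vital records
#'
#' Runs the full two-step construction and returns the assembled list plus an
#' audit of every stage. Review-category linkage pairs are resolved by the
#' linkage config's `default_review_decision` (use [link_lists()] directly
#' with [export_review()] / [import_review()] for an interactive review).
#' Spelling variants matched across the two sources are both retained as
#' distinct entries.
#'
#' @param reference the reference surname extract ([surname_list] or
#'   coercible); spellings may be truncated.
#' @param records vital-records data.frame (see [read_vital_records()]).
#' @param config a [build_config()].
#' @param review_decisions optional manual review decisions passed to
#'   [resolve_reviews()].
#' @return an object of class `asl_build`: list with elements `list` (the
#'   built [surname_list], sorted by uppercased surname), `audit` (named
#'   counts: `n_reference_input`, `n_linked`, `n_birthplace_candidates`,
#'   `n_removed_by_filter`, `n_birthplace_added`, `n_reference_retained`,
#'   `n_total_unique`), `linkage` (resolved `linkage_result`),
#'   `filter_decisions`, and `config`.
#' @examples
#' recs <- data.frame(surname = c("Mahtesian", "Smith"),
#'                    father_surname = NA, birthplace = c("Armenia", NA))
#' build_surname_list(c("Mahtesyan"), recs)
#' @export
build_surname_list <- function(reference, records,
                               config = build_config(),
                               review_decisions = NULL) {
  reference <- as_surname_list(reference)
  if (nrow(reference) == 0L || NROW(records) == 0L) {
    warning("empty reference list or record set; build proceeds",
            call. = FALSE)
  }
  harvested <- harvest_surnames(records, config)

  lr <- if (nrow(reference) && nrow(harvested)) {
    resolve_reviews(link_lists(reference, harvested, config$linkage),
                    review_decisions)
  } else {
    structure(list(pairs = data.frame(left = character(), right = character(),
                                      block = character(), score = numeric(),
                                      basis = character(),
                                      category = character(),
                                      stringsAsFactors = FALSE),
                   left_unmatched = sort(reference$surname, method = "radix"),
                   right_unmatched = sort(harvested$surname, method = "radix"),
                   config = config$linkage),
              class = "linkage_result")
  }
  mp <- linkage_matches(lr)

  # Step 1 entries: record-side spellings, plus the reference spelling
  linked_left <- unique(mp$left)
  linked_right <- unique(mp$right)
  entries <- data.frame(surname = linked_right,
                        source = rep("reference_linked",
                                     length(linked_right)),
                        truncated = rep(FALSE, length(linked_right)),
                        evidence = rep("linked record spelling",
                                       length(linked_right)),
                        stringsAsFactors = FALSE)
  if (config$emit_truncated_reference && length(linked_left)) {
    trunc_left <- unique(mp$left[mp$basis == "truncation_prefix" &
                                   nchar(normalize_surname(mp$left)) <
                                   nchar(normalize_surname(mp$right))])
    entries <- rbind(entries, data.frame(
      surname = linked_left, source = "reference_linked",
      truncated = linked_left %in% trunc_left,
      evidence = "reference spelling", stringsAsFactors = FALSE))
  }
  linked_spellings <- unique(toupper(c(mp$left, mp$right)))

  # Step 2: birthplace-derived candidates, filtered
  cand <- birthplace_candidates(records, linked_spellings, config)
  filt <- apply_surname_filter(cand, config$filter)
  if (nrow(filt$kept)) {
    entries <- rbind(entries, data.frame(
      surname = filt$kept$surname, source = "birthplace_added",
      truncated = FALSE,
      evidence = paste0("birthplace=", config$target_birthplace),
      stringsAsFactors = FALSE))
  }

  # retained: reference surnames neither linked nor re-found by birthplace
  retained <- reference$surname[
    !(toupper(reference$surname) %in% linked_spellings) &
      !(toupper(reference$surname) %in% toupper(filt$kept$surname))]
  if (length(retained)) {
    entries <- rbind(entries, data.frame(
      surname = retained, source = "reference_retained",
      truncated = reference$truncated[match(retained, reference$surname)],
      evidence = "retained from reference extract",
      stringsAsFactors = FALSE))
  }

  if (config$collapse_punctuation_variants) {
    entries <- entries[!duplicated(normalize_surname(entries$surname)), ,
                       drop = FALSE]
  }
  entries <- entries[!duplicated(toupper(entries$surname)), , drop = FALSE]
  entries <- entries[order(toupper(entries$surname), method = "radix"), ,
                     drop = FALSE]
  out <- surname_list(entries$surname, source = entries$source,
                      truncated = entries$truncated,
                      evidence = entries$evidence,
                      name = "built", warn = FALSE)

  audit <- list(
    n_reference_input = nrow(reference),
    n_linked = sum(out$source == "reference_linked"),
    n_birthplace_candidates = nrow(cand),
    n_removed_by_filter = nrow(filt$removed),
    n_birthplace_added = nrow(filt$kept),
    n_reference_retained = sum(out$source == "reference_retained"),
    n_total_unique = nrow(out))

  structure(list(list = out, audit = audit, linkage = lr,
                 filter_decisions = filt$decisions, config = config),
            class = "asl_build")
}

#' @export
print.asl_build <- function(x, ...) {
  a <- x$audit
  cat("Surname-list build\n")
  cat("  reference input:        ", a$n_reference_input, "\n")
  cat("  linked (step 1):        ", a$n_linked, "\n")
  cat("  birthplace candidates:  ", a$n_birthplace_candidates, "\n")
  cat("  removed by filter:      ", a$n_removed_by_filter, "\n")
  cat("  birthplace added:       ", a$n_birthplace_added, "\n")
  cat("  reference retained:     ", a$n_reference_retained, "\n")
  cat("  total unique surnames:  ", a$n_total_unique, "\n")
  invisible(x)
}

#' @export
summary.asl_build <- function(object, ...) {
  print(object)
  cat("\nfilter reasons:\n")
  print(table(object$filter_decisions$reason))
  cat("\nlinkage bases (matches):\n")
  print(table(linkage_matches(object$linkage)$basis))
  invisible(object$audit)
}
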