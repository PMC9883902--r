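# Deletion rules for birthplace-derived surname candidates, and the
# suffix-convention classifier used in evaluation.
#
# A candidate harvested from target-birthplace records is deleted when it
#   1) has fewer than `min_length` letters, or
#   2) carries neither an Armenian patronymic suffix (ian, yan, ians, yans,
#      iants, yants) nor a Russian one (ov, ova) AND has fewer than
#      `long_name_exempt_length` letters.
# Rule 1 is evaluated first, so a 4-letter name ending in "yan" (e.g. 'Ryan')
# is removed as too short, not rescued by its suffix. Long names without a
# listed suffix (>= 12 letters) are kept: rare Armenian suffixes exist.
# Lengths count letters only (see normalize_surname); the suffix test applies
# to the final token of compound names, since particles like 'Ter-' precede
# the inheritable stem.

.ARMENIAN_SUFFIXES <- c("ian", "yan", "ians", "yans", "iants", "yants")
.RUSSIAN_SUFFIXES <- c("ov", "ova")

#' Filter configuration for birthplace-derived candidates
#'
#' @param armenian_suffixes lowercase Armenian patronymic suffixes.
#' @param russian_suffixes lowercase Russian patronymic suffixes (retained
#'   because many surnames were russified during the Soviet period).
#' @param min_length minimum letter count below which a candidate is always
#'   deleted (default 5).
#' @param long_name_exempt_length letter count at or above which a candidate
#'   is kept even without a listed suffix (default 12).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(armenian_suffixes = .ARMENIAN_SUFFIXES,
                          russian_suffixes = .RUSSIAN_SUFFIXES,
                          min_length = 5L,
                          long_name_exempt_length = 12L) {
  suffixes <- c(armenian_suffixes, russian_suffixes)
  stopifnot(
    length(suffixes) > 0, all(nzchar(suffixes)),
    all(grepl("^[a-z]+$", suffixes)),
    min_length >= 1, long_name_exempt_length > min_length)
  structure(list(armenian_suffixes = armenian_suffixes,
                 russian_suffixes = russian_suffixes,
                 min_length = as.integer(min_length),
                 long_name_exempt_length = as.integer(long_name_exempt_length)),
            class = "filter_config")
}

# lowercase letters of the final token (after the last hyphen or space)
final_token <- function(surname) {
  tok <- sub(".*[-\\s]", "", trimws(surname), perl = TRUE)
  tolower(normalize_surname(tok))
}

#' Match a surname against the configured patronymic suffixes
#'
#' Case-insensitive test on the letters of the final token of the name (text
#' after the last hyphen or space, punctuation stripped). Returns the longest
#' matching suffix among the Armenian and Russian sets, or `NA` when none
#' matches.
#'
#' @param surname character vector of surnames.
#' @param config a [filter_config()].
#' @return character vector: the matched suffix or `NA_character_`.
#' @examples
#' suffix_match(c("Danielian", "Oganesov", "Weatherford"))
#' @export
suffix_match <- function(surname, config = filter_config()) {
  suffixes <- c(config$armenian_suffixes, config$russian_suffixes)
  suffixes <- suffixes[order(nchar(suffixes), decreasing = TRUE)]
  toks <- vapply(surname, final_token, character(1), USE.NAMES = FALSE)
  vapply(toks, function(tok) {
    for (sfx in suffixes) {
      if (endsWith(tok, sfx)) return(sfx)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Apply the deletion criteria to one or more surnames
#'
#' @inheritParams suffix_match
#' @return data.frame with one row per surname and columns `surname`, `keep`,
#'   `reason` (`too_short`, `no_suffix_and_short`, `kept_suffix`,
#'   `kept_long`), `matched_suffix`, `letters`.
#' @examples
#' filter_decide(c("Smith", "Abad", "Ryan", "Weatherford",
#'                 "Hambartsumanz", "Ter-Prakhourany"))
#' @export
filter_decide <- function(surname, config = filter_config()) {
  surname <- as.character(surname)
  letters_n <- surname_letters(surname)
  sfx <- suffix_match(surname, config)
  reason <- ifelse(
    letters_n < config$min_length, "too_short",
    ifelse(is.na(sfx) & letters_n < config$long_name_exempt_length,
           "no_suffix_and_short",
           ifelse(is.na(sfx), "kept_long", "kept_suffix")))
  keep <- reason %in% c("kept_suffix", "kept_long")
  # a suffix match is only reported for decisions it could have influenced
  sfx[reason == "too_short"] <- NA_character_
  data.frame(surname = surname, keep = keep, reason = reason,
             matched_suffix = sfx, letters = letters_n,
             stringsAsFactors = FALSE)
}

#' Filter a candidate surname list
#'
#' Splits candidates into kept and removed lists per the deletion criteria;
#' every candidate receives a decision and `|kept| + |removed|` equals the
#' number of candidates.
#'
#' @param candidates a [surname_list] (or coercible) of birthplace-derived
#'   candidate surnames.
#' @param config a [filter_config()].
#' @return list with elements `kept` and `removed` ([surname_list]s) and
#'   `decisions` (the [filter_decide()] data.frame).
#' @export
apply_surname_filter <- function(candidates, config = filter_config()) {
  candidates <- as_surname_list(candidates)
  dec <- if (nrow(candidates)) filter_decide(candidates$surname, config)
         else data.frame(surname = character(), keep = logical(),
                         reason = character(), matched_suffix = character(),
                         letters = integer(), stringsAsFactors = FALSE)
  keep_idx <- which(dec$keep)
  drop_idx <- which(!dec$keep)
  subset_list <- function(idx) {
    if (!length(idx)) return(surname_list())
    surname_list(candidates$surname[idx],
                 source = candidates$source[idx],
                 truncated = candidates$truncated[idx],
                 evidence = candidates$evidence[idx], warn = FALSE)
  }
  list(kept = subset_list(keep_idx), removed = subset_list(drop_idx),
       decisions = dec)
}

#' Classify a surname by suffix convention
#'
#' Buckets a surname by the naming convention of its (longest-matching)
#' patronymic suffix: `I_convention` (-ian, -ians, -iants), `Y_convention`
#' (-yan, -yans, -yants), `russian` (-ov, -ova) or `other`. The spelling of
#' the suffix varies systematically with where the bearer was born, which
#' makes this distribution a useful evaluation stratifier.
#'
#' @param surname character vector of surnames.
#' @return character vector with levels `I_convention`, `Y_convention`,
#'   `russian`, `other`.
#' @examples
#' suffix_class(c("Martirosyan", "Danielian", "Mikhailov", "Smith"))
#' @export
suffix_class <- function(surname) {
  sfx <- suffix_match(surname, filter_config())
  out <- rep("other", length(surname))
  out[sfx %in% .ARMENIAN_SUFFIXES & startsWith(sfx, "i")] <- "I_convention"
  out[sfx %in% .ARMENIAN_SUFFIXES & startsWith(sfx, "y")] <- "Y_convention"
  out[sfx %in% .RUSSIAN_SUFFIXES] <- "russian"
  out
}
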