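# Soundex-blocked linkage of two surname lists.
#
# Candidate pairs are generated only within shared Soundex blocks, then each
# pair is scored on a three-tier basis:
#   exact_normalized  -- normalized spellings identical (score 1, match);
#   truncation_prefix -- one normalized form is a proper prefix of the other
#                        and the shorter has at least `truncation_length`
#                        letters (score 1, match): recovers reference-list
#                        names cut at a fixed character length;
#   similarity        -- Jaro-Winkler on the normalized forms, categorized
#                        match / review / non_match by thresholds.
# The review category emulates a manual-review stage as a file round-trip:
# export the undecided pairs, edit decisions, import them back.

#' Linkage configuration
#'
#' @param match_threshold similarity at or above which a pair is an automatic
#'   match (default 0.95).
#' @param review_low similarity at or above which a pair is flagged for
#'   manual review (default 0.85); below it the pair is a non-match.
#' @param truncation_length minimum length of the shorter name for a prefix
#'   pair to count as a truncation match (default 10, the length reference
#'   lists are commonly cut at).
#' @param default_review_decision how undecided review pairs resolve:
#'   `"non_match"` (conservative default) or `"match"`.
#' @param asymmetric_truncation if `TRUE`, only the left (reference) name may
#'   be the truncated, shorter side of a truncation match.
#' @return an object of class `linkage_config`.
#' @export
linkage_config <- function(match_threshold = 0.95, review_low = 0.85,
                           truncation_length = 10L,
                           default_review_decision = c("non_match", "match"),
                           asymmetric_truncation = FALSE) {
  stopifnot(match_threshold <= 1, review_low <= match_threshold,
            review_low >= 0, truncation_length >= 1)
  structure(list(match_threshold = match_threshold, review_low = review_low,
                 truncation_length = as.integer(truncation_length),
                 default_review_decision = match.arg(default_review_decision),
                 asymmetric_truncation = isTRUE(asymmetric_truncation)),
            class = "linkage_config")
}

#' Generate candidate pairs within shared Soundex blocks
#'
#' Every cross-pair of a left and a right surname coding to the same Soundex
#' block, and no pair across different blocks. Ordered by
#' (block, left, right) for determinism.
#'
#' @param left,right [surname_list]s (or coercibles).
#' @return data.frame with columns `block`, `left`, `right`.
#' @export
generate_candidates <- function(left, right) {
  lnames <- as_surname_list(left)$surname
  rnames <- as_surname_list(right)$surname
  lblk <- soundex(lnames)
  rblk <- soundex(rnames)
  shared <- intersect(lblk, rblk)
  if (!length(shared)) {
    return(data.frame(block = character(), left = character(),
                      right = character(), stringsAsFactors = FALSE))
  }
  pieces <- lapply(sort(shared), function(b) {
    expand.grid(left = sort(lnames[lblk == b], method = "radix"),
                right = sort(rnames[rblk == b], method = "radix"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- data.frame(block = rep(sort(shared), vapply(pieces, nrow, 0L)),
                    left = out$left, right = out$right,
                    stringsAsFactors = FALSE)
  out <- out[order(out$block, out$left, out$right, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one candidate pair
#'
#' @param left,right the two surnames (scalars).
#' @param config a [linkage_config()].
#' @return one-row data.frame with columns `left`, `right`, `block`, `score`,
#'   `basis` (`exact_normalized`, `truncation_prefix`, `similarity`) and
#'   `category` (`match`, `review`, `non_match`).
#' @examples
#' score_pair("Ter-Minasyan", "Ter Minasyan")  # exact_normalized, score 1
#' score_pair("Haroutunia", "Haroutunian")     # truncation_prefix match
#' @export
score_pair <- function(left, right, config = linkage_config()) {
  nl <- normalize_surname(left)
  nr <- normalize_surname(right)
  if (nl == nr) {
    basis <- "exact_normalized"; score <- 1; category <- "match"
  } else if (is_truncation_pair(nl, nr, config)) {
    basis <- "truncation_prefix"; score <- 1; category <- "match"
  } else {
    basis <- "similarity"
    score <- jaro_winkler(nl, nr)
    category <- if (score >= config$match_threshold) "match"
      else if (score >= config$review_low) "review" else "non_match"
  }
  data.frame(left = left, right = right, block = soundex(nl),
             score = score, basis = basis, category = category,
             stringsAsFactors = FALSE)
}

is_truncation_pair <- function(nl, nr, config) {
  shorter <- if (nchar(nl) <= nchar(nr)) nl else nr
  longer <- if (nchar(nl) <= nchar(nr)) nr else nl
  if (nchar(shorter) == nchar(longer)) return(FALSE)
  if (nchar(shorter) < config$truncation_length) return(FALSE)
  if (config$asymmetric_truncation && !identical(shorter, nl)) return(FALSE)
  startsWith(longer, shorter)
}

#' Link two surname lists
#'
#' Blocks by Soundex, scores every candidate pair, and partitions left
#' surnames into matched, under-review and unmatched. Deterministic given the
#' inputs and config.
#'
#' @param left reference-side [surname_list] (possibly truncated spellings).
#' @param right record-side [surname_list].
#' @param config a [linkage_config()].
#' @return an object of class `linkage_result`: list with `pairs` (scored
#'   candidate data.frame), `left_unmatched`, `right_unmatched` (spellings in
#'   no match or review pair), and the `config`.
#' @seealso [resolve_reviews()], [export_review()], [import_review()]
#' @export
link_lists <- function(left, right, config = linkage_config()) {
  left <- as_surname_list(left)
  right <- as_surname_list(right)
  cand <- generate_candidates(left, right)
  pairs <- if (nrow(cand)) {
    do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      score_pair(cand$left[i], cand$right[i], config)
    }))
  } else {
    data.frame(left = character(), right = character(), block = character(),
               score = numeric(), basis = character(), category = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs,
                 left_unmatched = unlinked(left$surname, pairs, "left"),
                 right_unmatched = unlinked(right$surname, pairs, "right"),
                 config = config),
            class = "linkage_result")
}

unlinked <- function(names, pairs, side) {
  active <- pairs[[side]][pairs$category %in% c("match", "review")]
  sort(setdiff(names, active), method = "radix")
}

#' Matched / review pairs of a linkage result
#'
#' @param result a [link_lists()] result.
#' @return data.frame of scored pairs in that category.
#' @export
linkage_matches <- function(result) {
  result$pairs[result$pairs$category == "match", , drop = FALSE]
}

#' @rdname linkage_matches
#' @export
linkage_reviews <- function(result) {
  result$pairs[result$pairs$category == "review", , drop = FALSE]
}

#' Resolve review pairs into match / non_match
#'
#' Applies explicit decisions where given; remaining review pairs resolve to
#' `config$default_review_decision`. Unmatched sets are recomputed.
#'
#' @param result a `linkage_result`.
#' @param decisions optional data.frame with columns `left`, `right`,
#'   `decision` (`"match"` or `"non_match"`), each row referring to an
#'   existing review pair.
#' @return the updated `linkage_result` with no review pairs left.
#' @export
resolve_reviews <- function(result, decisions = NULL) {
  pairs <- result$pairs
  rev_idx <- which(pairs$category == "review")
  if (!is.null(decisions) && nrow(decisions)) {
    stopifnot(all(c("left", "right", "decision") %in% names(decisions)),
              all(decisions$decision %in% c("match", "non_match")))
    key <- paste(pairs$left, pairs$right, sep = "\r")
    dkey <- paste(decisions$left, decisions$right, sep = "\r")
    hit <- match(dkey, key[rev_idx])
    if (anyNA(hit)) {
      stop("review decision(s) for unknown pair(s): ",
           paste(paste(decisions$left[is.na(hit)],
                       decisions$right[is.na(hit)], sep = " / "),
                 collapse = "; "), call. = FALSE)
    }
    pairs$category[rev_idx[hit]] <- decisions$decision
  }
  still <- pairs$category == "review"
  pairs$category[still] <- result$config$default_review_decision
  result$pairs <- pairs
  all_left <- unique(c(pairs$left, result$left_unmatched))
  all_right <- unique(c(pairs$right, result$right_unmatched))
  result$left_unmatched <- unlinked(all_left, pairs, "left")
  result$right_unmatched <- unlinked(all_right, pairs, "right")
  result
}

#' Export / import the manual-review file
#'
#' `export_review()` writes all review-category pairs as a CSV with columns
#' `left,right,score,basis,decision` (decision left blank for the reviewer).
#' `import_review()` reads such a file back, applies rows whose `decision`
#' column is filled in, and resolves the remainder per the config default.
#'
#' @param result a `linkage_result`.
#' @param path CSV path.
#' @return `export_review`: `path` invisibly. `import_review`: the resolved
#'   `linkage_result`.
#' @export
export_review <- function(result, path) {
  rev <- linkage_reviews(result)
  df <- data.frame(left = rev$left, right = rev$right, score = rev$score,
                   basis = rev$basis, decision = rep("", nrow(rev)),
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("left,right,score,basis,decision",
             if (nrow(df)) paste(csv_quote(df$left), csv_quote(df$right),
                                 formatC(df$score, digits = 6, format = "f"),
                                 df$basis, df$decision, sep = ","))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_review
#' @export
import_review <- function(result, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  df <- df[!is.na(df$decision) & nzchar(trimws(df$decision)), , drop = FALSE]
  if (nrow(df) && !all(df$decision %in% c("match", "non_match"))) {
    stop("invalid review decision value(s): ",
         paste(unique(setdiff(df$decision, c("match", "non_match"))),
               collapse = ", "), call. = FALSE)
  }
  resolve_reviews(result, df)
}

#' @export
print.linkage_result <- function(x, ...) {
  tab <- table(factor(x$pairs$category,
                      levels = c("match", "review", "non_match")))
  cat("linkage_result:", nrow(x$pairs), "candidate pair(s) in",
      length(unique(x$pairs$block)), "block(s)\n")
  cat("  match:", tab[["match"]], " review:", tab[["review"]],
      " non_match:", tab[["non_match"]], "\n")
  cat("  left unmatched:", length(x$left_unmatched),
      " right unmatched:", length(x$right_unmatched), "\n")
  invisible(x)
}
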