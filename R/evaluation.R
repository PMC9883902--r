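# Evaluation of a built surname list against registry-style records:
# pairwise overlap, three-set Venn region counts, coverage gain over a
# baseline list, a birthplace contingency table, and suffix-convention
# distributions. All set operations work on uppercased-exact spellings;
# membership tests optionally become truncation-aware (a list entry also
# matches when one side is a sufficiently long prefix of the other), since
# retained reference entries may be truncated forms.

as_set <- function(x) surname_key(x)

# is each element of `x` covered by the set `members`?
member_of <- function(x, members, match_mode = c("exact", "truncation_aware"),
                      truncation_length = 10L) {
  match_mode <- match.arg(match_mode)
  hit <- x %in% members
  if (match_mode == "truncation_aware" && any(!hit) && length(members)) {
    long_enough <- members[nchar(members) >= truncation_length]
    hit[!hit] <- vapply(x[!hit], function(s) {
      if (nchar(s) >= truncation_length &&
          any(startsWith(long_enough, s))) return(TRUE)
      any(startsWith(s, long_enough))
    }, logical(1))
  }
  hit
}

#' Pairwise overlap of two surname lists
#'
#' Counts of surnames unique to each list and shared between them, on
#' uppercased-exact spellings, plus the Jaccard index and the percentage of
#' list `b` covered by list `a`.
#'
#' @param a,b [surname_list]s or character vectors.
#' @param match_mode `"exact"` (default) or `"truncation_aware"`, in which
#'   case a `b` surname also counts as shared when it is, or extends, a
#'   `>= truncation_length`-letter prefix of an `a` surname.
#' @param truncation_length prefix length for truncation-aware matching.
#' @return object of class `overlap_report`: list with `only_a`, `only_b`,
#'   `both`, `jaccard` (`NA` when both lists are empty) and `pct_of_b_in_a`.
#' @examples
#' overlap(c("X", "Y"), c("Y", "Z"))
#' @export
overlap <- function(a, b, match_mode = c("exact", "truncation_aware"),
                    truncation_length = 10L) {
  match_mode <- match.arg(match_mode)
  A <- as_set(a); B <- as_set(b)
  in_a <- member_of(B, A, match_mode, truncation_length)
  in_b <- member_of(A, B, match_mode, truncation_length)
  both <- sum(in_a)
  only_a <- sum(!in_b)
  only_b <- sum(!in_a)
  denom <- only_a + only_b + both
  structure(list(
    only_a = only_a, only_b = only_b, both = both,
    jaccard = if (denom > 0) both / denom else NA_real_,
    pct_of_b_in_a = if (length(B)) 100 * both / (only_b + both) else NA_real_),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap: only_a", x$only_a, "| both", x$both, "| only_b", x$only_b,
      "\n  jaccard", round(x$jaccard, 4),
      "| pct of b in a", round(x$pct_of_b_in_a, 1), "%\n")
  invisible(x)
}

#' Three-set Venn region counts
#'
#' Counts of unique surnames in each of the 7 regions of three lists; the
#' regions are disjoint and sum to the size of the union, and each list's
#' marginal is the sum of its four regions.
#'
#' @param a,b,c [surname_list]s or character vectors.
#' @param labels labels for printing/plotting.
#' @return object of class `venn3_report`: list with `regions` (named vector
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`), `marginals` and
#'   `union_size`.
#' @export
venn3 <- function(a, b, c, labels = c("A", "B", "C")) {
  A <- as_set(a); B <- as_set(b); C <- as_set(c)
  u <- unique(c(A, B, C))
  ia <- u %in% A; ib <- u %in% B; ic <- u %in% C
  regions <- c(
    a_only = sum(ia & !ib & !ic), b_only = sum(!ia & ib & !ic),
    c_only = sum(!ia & !ib & ic), ab = sum(ia & ib & !ic),
    ac = sum(ia & !ib & ic), bc = sum(!ia & ib & ic),
    abc = sum(ia & ib & ic))
  structure(list(regions = regions,
                 marginals = c(length(A), length(B), length(C)),
                 union_size = length(u), labels = labels),
            class = "venn3_report")
}

#' @export
print.venn3_report <- function(x, ...) {
  cat("venn3 (", paste(x$labels, collapse = ", "), "): union ",
      x$union_size, "\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' @describeIn venn3 simple base-graphics three-circle diagram with region
#'   counts.
#' @param x a `venn3_report`.
#' @param ... ignored.
#' @export
plot.venn3_report <- function(x, ...) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(-2, 2), ylim = c(-2, 2), asp = 1)
  centers <- list(c(-0.5, 0.4), c(0.5, 0.4), c(0, -0.5))
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in 1:3) {
    graphics::lines(centers[[i]][1] + cos(th), centers[[i]][2] + sin(th))
    graphics::text(centers[[i]][1] * 2.2, centers[[i]][2] * 2.2, x$labels[i])
  }
  pos <- list(a_only = c(-1, 0.6), b_only = c(1, 0.6), c_only = c(0, -1.1),
              ab = c(0, 0.7), ac = c(-0.55, -0.25), bc = c(0.55, -0.25),
              abc = c(0, 0.1))
  for (r in names(pos)) {
    graphics::text(pos[[r]][1], pos[[r]][2], x$regions[[r]])
  }
  invisible(x)
}

#' Coverage gain of a new list over a baseline
#'
#' Among reference surnames captured by the new list, how many the baseline
#' list misses: `gain_count = |reference %in% new, not in baseline|` and
#' `gain_pct = 100 * gain_count / |reference %in% new|`.
#'
#' @param new_list,baseline,reference [surname_list]s or character vectors;
#'   `reference` is the ground-truth-like list (e.g. birthplace-derived).
#' @inheritParams overlap
#' @return list with `gain_count` and `gain_pct` (`NA` with a flag when the
#'   new list captures no reference surnames).
#' @examples
#' coverage_gain(new_list = c("A", "B", "C"), baseline = "A",
#'               reference = c("A", "B", "C"))
#' @export
coverage_gain <- function(new_list, baseline, reference,
                          match_mode = c("exact", "truncation_aware"),
                          truncation_length = 10L) {
  match_mode <- match.arg(match_mode)
  ref <- as_set(reference)
  in_new <- member_of(ref, as_set(new_list), match_mode, truncation_length)
  in_base <- member_of(ref, as_set(baseline), match_mode, truncation_length)
  captured <- sum(in_new)
  gain <- sum(in_new & !in_base)
  list(gain_count = gain,
       gain_pct = if (captured > 0) 100 * gain / captured else NA_real_,
       n_captured = captured)
}

#' Birthplace contingency table for a surname list
#'
#' Cross-tabulates list membership (yes/no) against birthplace stratum
#' (target / other / unknown) at the unique (surname, stratum) level: a
#' surname seen with several birthplaces counts once in each stratum it
#' appears in. Percentages are computed within columns (birthplace strata).
#'
#' @param records vital-records or registry data.frame; the birthplace comes
#'   from a `birthplace` or `country_of_birth` column, surnames from
#'   `surname` plus `maiden_name`/`father_surname` when present.
#' @param list the surname list whose membership defines the rows.
#' @param target_birthplace the target country.
#' @inheritParams overlap
#' @return object of class `contingency_table`: list with integer matrix
#'   `counts` (rows `yes`/`no`, columns `target`/`other`/`unknown`),
#'   `percent` (column percentages) and `n_units`.
#' @export
contingency_table <- function(records, list, target_birthplace,
                              match_mode = c("exact", "truncation_aware"),
                              truncation_length = 10L) {
  match_mode <- match.arg(match_mode)
  bp_col <- intersect(c("birthplace", "country_of_birth"), names(records))[1]
  if (is.na(bp_col)) stop("records have no birthplace/country_of_birth column",
                          call. = FALSE)
  stratum <- birthplace_stratum(records[[bp_col]], target_birthplace)
  units <- NULL
  for (col in intersect(c("surname", "maiden_name", "father_surname"),
                        names(records))) {
    v <- toupper(trimws(as.character(records[[col]])))
    ok <- !is.na(v) & nzchar(v)
    units <- rbind(units, data.frame(surname = v[ok], stratum = stratum[ok],
                                     stringsAsFactors = FALSE))
  }
  units <- unique(units)
  members <- as_set(list)
  in_list <- member_of(units$surname, members, match_mode, truncation_length)
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(identified = c("yes", "no"),
                                   birthplace = c("target", "other",
                                                  "unknown")))
  for (s in colnames(counts)) {
    counts["yes", s] <- sum(in_list & units$stratum == s)
    counts["no", s] <- sum(!in_list & units$stratum == s)
  }
  totals <- colSums(counts)
  percent <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  percent[, totals == 0] <- NA_real_
  structure(list(counts = counts, percent = percent,
                 n_units = nrow(units),
                 target_birthplace = target_birthplace),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Surnames identified by list vs birthplace (target = ",
      x$target_birthplace, "); ", x$n_units, " surname-stratum units\n",
      sep = "")
  disp <- matrix(sprintf("%d (%.2f)", x$counts, x$percent),
                 nrow = 2, dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Suffix-convention distribution of a surname list
#'
#' Proportions of `I_convention` / `Y_convention` / `russian` / `other`
#' suffix classes (see [suffix_class()]), overall or within birthplace
#' strata. Proportions within a stratum sum to 1; empty strata are omitted.
#'
#' @param list a [surname_list] or character vector.
#' @param strata optional named character vector mapping uppercased surname
#'   to a stratum label; unmapped surnames fall in `"unstratified"`.
#' @return data.frame with columns `stratum`, `class`, `n`, `proportion`.
#' @export
suffix_distribution <- function(list, strata = NULL) {
  s <- as_set(list)
  if (!length(s)) {
    return(data.frame(stratum = character(), class = character(),
                      n = integer(), proportion = numeric()))
  }
  cls <- factor(suffix_class(s),
                levels = c("I_convention", "Y_convention", "russian", "other"))
  grp <- if (is.null(strata)) rep("all", length(s)) else {
    g <- unname(strata[s])
    g[is.na(g)] <- "unstratified"
    g
  }
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    tab <- table(cls[grp == g])
    data.frame(stratum = g, class = names(tab), n = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Origin-ranker adapter contract and demo ranker
#'
#' External name-origin services rank, for one surname, the most likely
#' countries of origin. The toolkit only defines the adapter contract: an
#' origin ranker is a function taking a character scalar surname and
#' returning a data.frame with columns `country` and `rank` (1 = most
#' likely, at most 10 rows). `demo_origin_ranker()` returns a toy ranker
#' driven solely by [suffix_class()]; it exists to exercise pipelines in
#' tests and demos and has no scientific validity as a classifier.
#'
#' @return a ranker function as described.
#' @export
demo_origin_ranker <- function() {
  function(surname) {
    top <- switch(suffix_class(surname)[1],
                  I_convention = c("Armenia", "Iran"),
                  Y_convention = c("Armenia", "Georgia"),
                  russian = c("Russia", "Armenia"),
                  other = c("Unknown", "Unknown"))
    data.frame(country = top, rank = seq_along(top),
               stringsAsFactors = FALSE)
  }
}
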