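# Ground-truth-labelled synthetic worlds: a reference surname extract, a
# vital-records file and a registry file with known target / non-target
# labels, so the whole construction and evaluation pipeline is testable
# without access-restricted data.
#
# Stems are built from consonant-vowel syllable templates (no real-name
# dictionary ships with the package); target surnames get a patronymic
# suffix per the configured convention mix. Design guarantees (documented in
# the methods vignette):
#   * every target surname is observable through at least one pathway --
#     it appears in the reference extract and/or on at least one vital
#     record with the target birthplace (missing birthplace only affects
#     additional records);
#   * non-target surnames never carry the target birthplace, except
#     deliberate filter-trap names (short no-suffix 'Smith'-style and
#     <5-letter '-yan'-ending 'Ryan'-style), which the deletion rules remove;
#   * spelling variants (-ian/-yan swaps, hyphen/space toggles) and
#     truncated reference forms are labelled target in the truth table.

#' Synthetic-world configuration
#'
#' Defaults describe the study conditions the generator emulates: a few
#' hundred target-population surnames dominated by the Y-spelling
#' convention, a larger pool of unrelated surnames, 10% truncated reference
#' spellings, 10% spelling variants and 10% birthplace missingness.
#'
#' @param n_target_stems number of target-population surname stems.
#' @param n_other_surnames number of unrelated (non-target) surnames.
#' @param convention_mix named proportions over `Y_convention`,
#'   `I_convention`, `russian`, `no_suffix_long`; must sum to 1.
#' @param p_in_reference probability a target surname is in the reference
#'   extract.
#' @param p_reference_only probability a reference surname never appears in
#'   the vital records at all (it ends up retained verbatim).
#' @param p_truncated_in_reference probability a reference spelling longer
#'   than `truncation_length` characters is truncated.
#' @param p_variant_spelling probability a target surname also appears under
#'   a variant spelling in the records.
#' @param p_target_birthplace_missing probability the birthplace of an
#'   additional target record is missing ("unknown" stratum).
#' @param birthplace_mix named proportions over `other`, `unknown` for
#'   non-target records.
#' @param p_particle probability of a `Ter-` particle on a target surname.
#' @param n_trap_short number of `Ryan`-style traps (under 5 letters, `-yan`
#'   ending) planted on target-birthplace records.
#' @param n_trap_nosuffix number of `Smith`-style traps (5-11 letters, no
#'   listed suffix) planted on target-birthplace records.
#' @param truncation_length reference truncation length (characters).
#' @param target_birthplace target country name used on records.
#' @param seed integer seed; a fixed seed reproduces the world exactly.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_target_stems = 300L,
                         n_other_surnames = 500L,
                         convention_mix = c(Y_convention = 0.55,
                                            I_convention = 0.25,
                                            russian = 0.10,
                                            no_suffix_long = 0.10),
                         p_in_reference = 0.6,
                         p_reference_only = 0.05,
                         p_truncated_in_reference = 0.10,
                         p_variant_spelling = 0.10,
                         p_target_birthplace_missing = 0.10,
                         birthplace_mix = c(other = 0.85, unknown = 0.15),
                         p_particle = 0.05,
                         n_trap_short = 10L,
                         n_trap_nosuffix = 10L,
                         truncation_length = 10L,
                         target_birthplace = "Armenia",
                         seed = 1L) {
  probs <- c(p_in_reference, p_reference_only, p_truncated_in_reference,
             p_variant_spelling, p_target_birthplace_missing, p_particle)
  stopifnot(
    n_target_stems >= 1, n_other_surnames >= 0,
    all(probs >= 0), all(probs <= 1),
    abs(sum(convention_mix) - 1) < 1e-8,
    all(names(convention_mix) %in% c("Y_convention", "I_convention",
                                     "russian", "no_suffix_long")),
    abs(sum(birthplace_mix) - 1) < 1e-8,
    truncation_length >= 1, nzchar(target_birthplace))
  structure(list(n_target_stems = as.integer(n_target_stems),
                 n_other_surnames = as.integer(n_other_surnames),
                 convention_mix = convention_mix,
                 p_in_reference = p_in_reference,
                 p_reference_only = p_reference_only,
                 p_truncated_in_reference = p_truncated_in_reference,
                 p_variant_spelling = p_variant_spelling,
                 p_target_birthplace_missing = p_target_birthplace_missing,
                 birthplace_mix = birthplace_mix,
                 p_particle = p_particle,
                 n_trap_short = as.integer(n_trap_short),
                 n_trap_nosuffix = as.integer(n_trap_nosuffix),
                 truncation_length = as.integer(truncation_length),
                 target_birthplace = target_birthplace,
                 seed = as.integer(seed)),
            class = "world_config")
}

.CONSONANTS <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t",
                 "v", "z")
.VOWELS <- c("a", "e", "i", "o", "u")

# one CV(C) syllable
syllable <- function(coda_p = 0.25) {
  paste0(sample(.CONSONANTS, 1), sample(.VOWELS, 1),
         if (stats::runif(1) < coda_p) sample(.CONSONANTS, 1) else "")
}

# stem of n_syll CV(C) syllables, capitalized
make_stem <- function(n_syll = sample(2:4, 1)) {
  s <- paste(vapply(seq_len(n_syll), function(i) syllable(), character(1)),
             collapse = "")
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

.CONVENTION_SUFFIXES <- list(
  Y_convention = c(yan = 0.80, yans = 0.15, yants = 0.05),
  I_convention = c(ian = 0.80, ians = 0.15, iants = 0.05),
  russian = c(ov = 0.6, ova = 0.4))

#' Compose a surname from a stem and a suffix convention
#'
#' Appends a suffix drawn from the convention's suffix family
#' (`Y_convention`: -yan/-yans/-yants; `I_convention`: -ian/-ians/-iants;
#' `russian`: -ov/-ova), or, for `no_suffix_long`, extends the stem with
#' extra syllables until it has at least 12 letters and no listed suffix.
#' A `Ter-` particle is prepended with probability `p_particle`.
#'
#' @param stem a capitalized stem of at least 3 letters.
#' @param convention one of `Y_convention`, `I_convention`, `russian`,
#'   `no_suffix_long`.
#' @param p_particle probability of a `Ter-` particle.
#' @return a single surname string.
#' @export
make_surname <- function(stem, convention, p_particle = 0) {
  stopifnot(nchar(stem) >= 3)
  convention <- match.arg(convention,
                          c("Y_convention", "I_convention", "russian",
                            "no_suffix_long"))
  if (convention == "no_suffix_long") {
    name <- stem
    repeat {
      if (nchar(name) >= 12 && is.na(suffix_match(name))) break
      name <- paste0(name, syllable())
    }
  } else {
    w <- .CONVENTION_SUFFIXES[[convention]]
    name <- paste0(stem, sample(names(w), 1, prob = w))
  }
  if (stats::runif(1) < p_particle) name <- paste0("Ter-", name)
  name
}

# swap the suffix convention (ian<->yan) or toggle particle punctuation;
# returns NA when no variant applies
variant_spelling <- function(name) {
  if (grepl("ian(s)?$", name)) return(sub("ian(s?)$", "yan\\1", name))
  if (grepl("yan(s)?$", name) && !grepl("^R?yan", name)) {
    return(sub("yan(s?)$", "ian\\1", name))
  }
  if (grepl("-", name, fixed = TRUE)) return(sub("-", " ", name))
  NA_character_
}

#' Generate a synthetic labelled world
#'
#' Builds the reference extract, vital records, registry records and a truth
#' table from a [world_config()]. Deterministic given the config's seed; the
#' caller's RNG state is left untouched.
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_world`: list with `truth`
#'   (data.frame `surname` (uppercase), `label`), `reference_extract`
#'   ([surname_list]), `vital_records`, `registry_records` (data.frames in
#'   the reader layouts), `target_surnames`, `trap_surnames`, and `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  # unique target surnames
  conventions <- sample(names(config$convention_mix), config$n_target_stems,
                        replace = TRUE, prob = config$convention_mix)
  target <- character(0)
  for (cv in conventions) {
    repeat {
      nm <- make_surname(make_stem(), cv, config$p_particle)
      if (!(toupper(nm) %in% toupper(target))) break
    }
    target <- c(target, nm)
  }

  # non-target pool: generic surnames plus deliberate filter traps
  other <- character(0)
  while (length(other) < config$n_other_surnames) {
    nm <- make_stem(sample(2:4, 1))
    while (surname_letters(nm) < 5 || !is.na(suffix_match(nm)) ||
           surname_letters(nm) >= 12) {
      nm <- make_stem(sample(2:4, 1))
    }
    if (!(toupper(nm) %in% toupper(c(target, other)))) other <- c(other, nm)
  }
  trap_short <- character(0)
  while (length(trap_short) < config$n_trap_short) {
    nm <- paste0(toupper(sample(.CONSONANTS, 1)), "yan")  # 4 letters, -yan
    nm <- paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 4)))
    if (!(toupper(nm) %in% toupper(c(target, other, trap_short)))) {
      trap_short <- c(trap_short, nm)
    }
    if (length(unique(trap_short)) >= min(config$n_trap_short,
                                          length(.CONSONANTS))) break
  }
  trap_nosuffix <- character(0)
  while (length(trap_nosuffix) < config$n_trap_nosuffix) {
    nm <- make_stem(sample(2:3, 1))
    while (surname_letters(nm) < 5 || surname_letters(nm) >= 12 ||
           !is.na(suffix_match(nm))) {
      nm <- make_stem(sample(2:3, 1))
    }
    if (!(toupper(nm) %in%
          toupper(c(target, other, trap_short, trap_nosuffix)))) {
      trap_nosuffix <- c(trap_nosuffix, nm)
    }
  }
  traps <- c(trap_short, trap_nosuffix)

  # reference extract: subset of target surnames, possibly truncated
  in_ref <- stats::runif(length(target)) < config$p_in_reference
  if (!any(in_ref)) in_ref[1] <- TRUE
  ref_spelling <- target[in_ref]
  truncd <- nchar(ref_spelling) > config$truncation_length &
    stats::runif(length(ref_spelling)) < config$p_truncated_in_reference
  ref_spelling[truncd] <- substr(ref_spelling[truncd], 1,
                                 config$truncation_length)
  dup <- duplicated(toupper(ref_spelling))
  reference <- surname_list(ref_spelling[!dup], source = "external",
                            truncated = truncd[!dup],
                            name = "reference_extract", warn = FALSE)

  # vital records for target surnames; reference-only surnames (retained
  # pathway) get no records at all
  ref_only <- in_ref & stats::runif(length(target)) < config$p_reference_only
  other_countries <- c("United States", "Mexico", "Ireland", "England",
                       "Italy", "Philippines")
  recs <- list()
  variants <- character(0)
  for (i in seq_along(target)) {
    if (ref_only[i]) next
    nm <- target[i]
    k <- sample(1:3, 1)
    bp <- rep(config$target_birthplace, k)
    miss <- stats::runif(k) < config$p_target_birthplace_missing
    # guarantee one observable pathway for surnames not in the reference
    if (!in_ref[i]) miss[1] <- FALSE
    bp[miss] <- NA
    father <- rep(NA_character_, k)
    if (stats::runif(1) < 0.3) father[1] <- sample(target, 1)
    recs[[length(recs) + 1L]] <- data.frame(
      surname = nm, father_surname = father, birthplace = bp,
      birth_year = sample(1900:1990, k, replace = TRUE),
      stringsAsFactors = FALSE)
    if (stats::runif(1) < config$p_variant_spelling) {
      v <- variant_spelling(nm)
      if (!is.na(v) && !(toupper(v) %in% toupper(c(target, other, traps,
                                                   variants)))) {
        variants <- c(variants, v)
        recs[[length(recs) + 1L]] <- data.frame(
          surname = v, father_surname = NA_character_,
          birthplace = config$target_birthplace,
          birth_year = sample(1900:1990, 1), stringsAsFactors = FALSE)
      }
    }
  }
  # non-target records: never the target birthplace
  for (nm in other) {
    k <- sample(1:2, 1)
    bp <- ifelse(stats::runif(k) < config$birthplace_mix[["unknown"]],
                 NA_character_,
                 sample(other_countries, k, replace = TRUE))
    recs[[length(recs) + 1L]] <- data.frame(
      surname = nm, father_surname = NA_character_, birthplace = bp,
      birth_year = sample(1900:1990, k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  # traps: planted on target-birthplace records so they reach the filter
  for (nm in traps) {
    recs[[length(recs) + 1L]] <- data.frame(
      surname = nm, father_surname = NA_character_,
      birthplace = config$target_birthplace,
      birth_year = sample(1900:1990, 1), stringsAsFactors = FALSE)
  }
  vital <- do.call(rbind, recs)
  vital <- vital[sample(nrow(vital)), , drop = FALSE]
  rownames(vital) <- NULL

  # registry records
  reg <- list()
  ref_keys <- toupper(reference$surname)
  for (nm in c(target, variants)) {
    if (stats::runif(1) >= 0.5) next
    cob <- if (stats::runif(1) < 0.85) config$target_birthplace else
      sample(c(other_countries, NA_character_), 1)
    on_ref <- member_of(toupper(nm), ref_keys, "truncation_aware",
                        config$truncation_length)
    reg[[length(reg) + 1L]] <- data.frame(
      surname = nm, maiden_name = NA_character_,
      father_surname = NA_character_, country_of_birth = cob,
      on_reference_list = on_ref, stringsAsFactors = FALSE)
  }
  for (nm in c(other, traps)) {
    if (stats::runif(1) >= 0.2) next
    reg[[length(reg) + 1L]] <- data.frame(
      surname = nm, maiden_name = NA_character_,
      father_surname = NA_character_,
      country_of_birth = sample(c(other_countries, NA_character_), 1),
      on_reference_list = FALSE, stringsAsFactors = FALSE)
  }
  registry <- if (length(reg)) do.call(rbind, reg) else
    data.frame(surname = character(), maiden_name = character(),
               father_surname = character(), country_of_birth = character(),
               on_reference_list = logical(), stringsAsFactors = FALSE)

  truth <- data.frame(
    surname = toupper(c(target, variants, reference$surname, other, traps)),
    label = c(rep("target", length(target) + length(variants) +
                    nrow(reference)),
              rep("non_target", length(other) + length(traps))),
    stringsAsFactors = FALSE)
  truth <- truth[!duplicated(truth$surname), , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(truth = truth, reference_extract = reference,
                 vital_records = vital, registry_records = registry,
                 target_surnames = toupper(c(target, variants)),
                 trap_surnames = toupper(traps),
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world (seed ", x$config$seed, ")\n", sep = "")
  cat("  truth:", sum(x$truth$label == "target"), "target /",
      sum(x$truth$label == "non_target"), "non-target surnames\n")
  cat("  reference extract:", nrow(x$reference_extract), "entries (",
      sum(x$reference_extract$truncated), "truncated )\n")
  cat("  vital records:", nrow(x$vital_records),
      "| registry records:", nrow(x$registry_records), "\n")
  invisible(x)
}

#' Score a built list against the synthetic ground truth
#'
#' Sensitivity is the share of target surnames present in any input source
#' (reference extract or vital records) that the built list recovers;
#' membership is truncation-aware, so a truncated reference form and its full
#' spelling count as the same name. False inclusions are built entries that
#' match no target surname.
#'
#' @param built a [surname_list] (e.g. `build_surname_list()$list`).
#' @param world a [generate_world()] result.
#' @return list with `sensitivity`, `false_inclusions`, `n_target_present`,
#'   `false_surnames`.
#' @export
score_against_truth <- function(built, world) {
  built_keys <- surname_key(built)
  tl <- world$config$truncation_length
  present <- c(surname_key(world$reference_extract),
               surname_key(world$vital_records$surname),
               surname_key(world$vital_records$father_surname))
  target_truth <- world$truth$surname[world$truth$label == "target"]
  target_present <- intersect(target_truth, present)
  recovered <- member_of(target_present, built_keys, "truncation_aware", tl)
  false_hit <- !member_of(built_keys, target_truth, "truncation_aware", tl)
  list(sensitivity = if (length(target_present))
         mean(recovered) else NA_real_,
       false_inclusions = sum(false_hit),
       n_target_present = length(target_present),
       false_surnames = built_keys[false_hit])
}

#' Write the fixture files of a synthetic world
#'
#' Writes `reference.txt` (plain surname list), `deaths.csv`, `registry.csv`
#' and `truth.csv` into a directory, in the layouts the readers expect.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surname_list(world$reference_extract,
                     file.path(dir, "reference.txt"), "plain")
  write_csv_lf(world$vital_records, file.path(dir, "deaths.csv"))
  write_csv_lf(world$registry_records, file.path(dir, "registry.csv"))
  write_csv_lf(world$truth[order(world$truth$surname, method = "radix"), ],
               file.path(dir, "truth.csv"))
  invisible(dir)
}

# deterministic, LF-only CSV writer (byte-identical across runs)
write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cells <- vapply(df, function(col) {
    out <- csv_quote(ifelse(is.na(col), "", as.character(col)))
    out
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) apply(cells, 1, paste, collapse = ","))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
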