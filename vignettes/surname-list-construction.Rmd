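---
title: "Constructing and evaluating ethnicity surname lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating ethnicity surname lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surnamekit)
```

## The problem

Many ethnic populations — Armenian-Americans among them — are folded into
broad census race categories ("White", "Some Other Race"), so
population-based health research cannot see them. When self-reported
ethnicity is unavailable, a curated *surname list* is the standard
identification tool: a registry record whose surname appears on the list is
flagged as probably belonging to the population of interest.

`surnamekit` implements the whole life cycle of such a list:

1. **Linkage** of an existing reference surname extract against the
   surnames in a large vital-records file (death records), using phonetic
   blocking so spelling variants and truncated forms are compared at all;
2. **Harvesting** of additional surnames from records whose birthplace is
   the target country, filtered by patronymic-suffix and length rules;
3. **Retention** of reference surnames that never appear in the records;
4. **Evaluation** of the assembled list against registry-style records:
   overlap counts, three-set Venn regions, coverage gain over a baseline
   list, birthplace contingency tables, and suffix-convention
   distributions.

Birthplace in the target country serves as a proxy truth signal throughout:
there is no gold standard of self-reported ethnicity, so a list is judged
by how well it recovers surnames independently tied to the target
birthplace.

## The construction procedure

### Step 1: phonetically blocked linkage

The reference extract and the record surnames are both coded with
**American Soundex** (first letter + three consonant-class digits; vowels
and Y dropped; runs of equal codes collapsed; letters separated only by H
or W treated as adjacent). Only pairs sharing a code are ever compared —
this is the *blocking* step that makes linkage tractable and, more
importantly, lets variant spellings meet: `Mahtesyan` and `Mahtesian` share
`M325`, and a reference form truncated at 10 characters (`Haroutunia`)
shares `H635` with its full spelling (`Haroutunian`).

Each candidate pair is then scored on a three-tier basis:

* **exact_normalized** — the normalized spellings (uppercased, punctuation
  and diacritics stripped) are identical. `Ter-Minasyan` vs
  `Ter Minasyan` is a perfect match; hyphens, spaces and case never
  separate a pair. Score 1, automatic match.
* **truncation_prefix** — one normalized form is a proper prefix of the
  other and the shorter has at least `truncation_length` letters
  (default 10). This recovers names cut at a fixed field width. Score 1,
  automatic match.
* **similarity** — otherwise, Jaro–Winkler similarity of the normalized
  forms, categorized by two thresholds: `match_threshold` (default 0.95)
  and `review_low` (default 0.85). Pairs in between land in a **review**
  band that emulates a manual-review stage as a file round-trip
  (`export_review()` / `import_review()`); undecided review pairs resolve
  to the config's `default_review_decision`, which defaults to `non_match`
  — the conservative reading of a manual process that existed to discard
  false hits.

The internal weighting of the commercial linkage software this emulates is
unpublished, so the three-tier basis above is this package's own
re-specification; the thresholds are exposed in `linkage_config()` rather
than baked in. Matching is at the *surname* (type) level, not the record
level. Pairs are ordered by (block, left, right), which makes every
downstream artifact byte-reproducible.

### Step 2: birthplace-derived candidates and the deletion rules

Surnames harvested from records with the target birthplace that did not
link in Step 1 become candidates, and are deleted when they

1. have fewer than `min_length` letters (default 5), **or**
2. carry none of the listed patronymic suffixes — Armenian
   *ian, yan, ians, yans, iants, yants* or Russian *ov, ova* — **and** have
   fewer than `long_name_exempt_length` letters (default 12).

The Russian suffixes are retained deliberately: during the Soviet period
many Armenian families russified their surname endings, so an `-ov`/`-ova`
name on a target-birthplace record is evidence, not noise. The second rule
is a conjunction — a long name is kept even without a listed suffix
(`Hambartsumanz`, `Ter-Prakhourany`), because rare suffixes exist; a short
suffix-less name (`Smith`, `Weatherford`) is deleted. Rule 1 is evaluated
first, so a four-letter `-yan` ending (`Ryan`) is removed as too short and
never suffix-rescued; the decision's reason code records this ordering.

Two conventions needed a choice the sources leave open:

* **Lengths count letters only.** Punctuation should neither rescue nor
  doom a name under a length threshold, and every documented example is
  consistent with letters-only counting.
* **The suffix test applies to the final token** of a compound name
  (`Ter-Prakhourany` tests `Prakhourany`): particles such as `Ter-`
  precede the inheritable stem.

### Assembly and audit

The final list is the deduplicated union of three disjoint provenance
sets — `reference_linked` (record-side spellings of matched pairs, plus by
default the reference spelling when it differs, so both members of a
variant pair survive), `birthplace_added` (filter survivors), and
`reference_retained` (reference names found nowhere). The uniqueness key is
the *uppercased exact spelling* with punctuation preserved: `Mahtesyan` and
`Mahtesian` are distinct entries, which is the point of the exercise; a
`collapse_punctuation_variants` switch (default off) is available for users
who want hyphen/space forms merged. The filter applies **only** to Step-2
candidates — a reference surname that would fail it is still retained,
because reference membership is itself evidence.

`build_surname_list()` returns the list plus a `BuildAudit`-style count of
every stage (`n_linked`, `n_birthplace_candidates`, `n_removed_by_filter`,
`n_birthplace_added`, `n_reference_retained`, `n_total_unique`), with the
conservation identity `candidates = added + removed` guaranteed.

## Evaluation

`overlap()`, `venn3()` and `coverage_gain()` are set arithmetic on
uppercased spellings; `contingency_table()` cross-tabulates list membership
against birthplace stratum (target / other / unknown) at the unique
(surname, stratum) level — a surname seen with several birthplaces counts
once per stratum, and percentages are computed within columns, i.e. within
birthplace strata. A surname whose birthplace is missing falls in an
explicit "unknown" stratum rather than being dropped.

Membership tests default to exact spelling; `match_mode =
"truncation_aware"` also credits a pair where one side is a ≥10-letter
prefix of the other, which matters when the evaluated list contains
truncated reference forms. Exact is the default because it is the
conservative, reproducible choice.

`suffix_distribution()` classifies names into the *I*-convention
(*-ian/-ians/-iants*), *Y*-convention (*-yan/-yans/-yants*), Russian
(*-ov/-ova*) and *other* buckets. The spelling convention varies
systematically with the bearer's country of birth, which makes this a
useful diagnostic of what sub-population a list actually captures.

External country-of-origin ranking services are out of scope: the package
only fixes the adapter contract (surname in, ≤10 ranked countries out) and
ships `demo_origin_ranker()`, a suffix-heuristic toy for pipeline tests
with no scientific validity.

## The synthetic world

Real death files, registries and reference extracts are access-restricted,
so the package carries its own ground-truth-labelled generator,
`generate_world()`. It emulates the *structure* of those sources, not their
content:

* **Stems** come from consonant–vowel syllable templates — no real-name
  dictionary ships with the package; documented real surnames appear only
  as unit-test fixtures.
* **Target surnames** (default 300 stems) draw a suffix convention from a
  mix of 55% Y-convention, 25% I-convention, 10% Russian and 10% long
  suffix-less names — a default motivated by the observation that the
  Y-convention dominates among target-country births, documented here as a
  generator default, not an empirical estimate. 5% carry a `Ter-` particle.
* **The reference extract** holds each target surname with probability
  0.6; spellings longer than 10 characters are truncated at 10 with
  probability 0.1. 5% of reference names appear on no record at all,
  exercising the retention pathway.
* **Vital records** give each target surname 1–3 records with the target
  birthplace; 10% of birthplaces are blanked to "unknown". Spelling
  variants (ian↔yan swap, hyphen↔space) are injected on 10% of names.
  Father's surnames are populated on ~30% of target records.
* **Non-target surnames** (default 500) never carry the target birthplace
  — with one deliberate exception: trap names emulating the documented
  false-positive classes (ten `Ryan`-style short `-yan` names, ten
  `Smith`-style short suffix-less names) are planted *on* target-birthplace
  records precisely so the deletion rules are exercised.
* **Registry records** sample the target and non-target pools and carry an
  `on_reference_list` flag consistent with truncation-aware membership of
  the reference extract.

One structural guarantee matters for interpreting the tests: every target
surname is observable through at least one pathway (reference extract, or a
target-birthplace record — missingness only affects additional records).
Noise-free recovery of 100% of the ground truth with zero foreign names is
therefore a *structural* property of a correct implementation, not a lucky
draw, and the test suite asserts exactly that. With the default noise the
suite requires sensitivity ≥ 0.95 and all traps excluded — engineering
targets of this generator design.

What the generator does **not** model — and hence what passing tests do not
show about real data: real-world surname frequency distributions (every
synthetic surname is roughly equally common), transliteration drift beyond
the two injected variant classes, marriage-driven surname change beyond the
father-surname field, OCR/transcription errors, and the ethnic overlap of
suffix conventions across neighbouring populations. Results on the
synthetic world validate the *machinery*, not the epidemiological
performance of any particular list.

## Numerical and engineering choices

* **Soundex variant**: American Soundex with the H/W adjacency rule,
  verified against the published reference vectors (`Robert→R163`,
  `Ashcraft→A261`, `Tymczak→T522`, `Pfister→P236`, ...). Coding applies to
  the punctuation-stripped name; whether the emulated software strips
  first is undocumented, and the stripped convention is what makes
  `Ter-Minasyan`/`Ter Minasyan` a perfect match.
* **String similarity**: Jaro–Winkler (prefix scale 0.1, prefix cap 4),
  implemented in the package and checked against the classic worked
  examples (`MARTHA/MARHTA = 0.9611`, `DIXON/DICKSONX = 0.8133`).
* **Determinism**: there is no randomness outside the generator, which
  draws everything from one integer seed and restores the caller's RNG
  state. All writers emit LF line endings and sorted rows, so a pipeline
  rerun is byte-identical — asserted in the suite down to file hashes.
* **Degenerate inputs**: a surname with no letters is an error, not a
  silent empty code; empty lists and empty files warn and propagate as
  zero-row objects; a contingency column with no units reports `NA`
  percentages rather than dividing by zero.
* **Problem sizes**: the shipped tests and the acceptance script run on
  worlds of 300 target stems / 500 non-target surnames (≈1,300 vital
  records) and a 2,000-stem world for mixture recovery — large enough for
  stable proportions, small enough that the full suite runs in well under
  a minute on one core. The linkage-vs-brute-force oracle comparisons use
  100×350-name slices, bounding the all-pairs oracle at ~35,000 scored
  pairs.

## Known limitations

* The review policy (thresholds, default decision) is a configurable
  stand-in for an undocumented manual process; treat the defaults as a
  starting point, not as a reconstruction of any published rule set.
* Blocking by Soundex means a pair in *different* blocks is never scored,
  no matter how similar; that is inherent to the method being modelled
  (and is why its truncation behaviour is a feature).
* Single-field linkage only: no first names, no dates of birth, no
  Fellegi–Sunter weights. The surname-type level is the unit throughout.
* `match_mode = "truncation_aware"` can over-credit very long shared
  prefixes between genuinely different names; it is off by default.
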