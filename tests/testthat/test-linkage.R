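test_that("printed match examples score on the expected basis", {
  perfect <- score_pair("Ter-Minasyan", "Ter Minasyan")
  expect_equal(perfect$basis, "exact_normalized")
  expect_equal(perfect$score, 1)
  expect_equal(perfect$category, "match")

  for (pair in list(c("Haroutunia", "Haroutunian"),
                    c("Martirosya", "Martirosyan"))) {
    trunc <- score_pair(pair[1], pair[2])
    expect_equal(trunc$basis, "truncation_prefix")
    expect_equal(trunc$category, "match")
  }

  ident <- score_pair("Smith", "Smith")
  expect_equal(ident$basis, "exact_normalized")
  expect_equal(ident$category, "match")

  # a 9-letter prefix is below the truncation length: similarity basis
  short <- score_pair("Terminas", "Terminasyan")
  expect_equal(short$basis, "similarity")
})

test_that("candidate generation pairs only within shared blocks", {
  one <- generate_candidates(c("Haroutunia"), c("Haroutunian", "Smith"))
  expect_equal(nrow(one), 1)
  expect_equal(one$right, "Haroutunian")

  variant <- generate_candidates(c("Ter-Minasyan"), c("Ter Minasyan"))
  expect_equal(nrow(variant), 1)

  refl <- generate_candidates(c("Smith"), c("Smith"))
  expect_equal(nrow(refl), 1)

  none <- generate_candidates(c("Martirosyan"), c("Weatherford"))
  expect_equal(nrow(none), 0)

  # ordering contract: (block, left, right)
  multi <- generate_candidates(c("Smith", "Smythe", "Lee"),
                               c("Smith", "Smyth", "Leigh"))
  expect_identical(multi,
                   multi[order(multi$block, multi$left, multi$right,
                               method = "radix"), ],
                   ignore_attr = TRUE)
})

test_that("blocked linkage equals the brute-force all-pairs oracle", {
  w <- cached_world()
  left <- w$reference_extract$surname[1:80]
  right <- harvest_surnames(w$vital_records, build_config())$surname[1:250]
  cfg <- linkage_config()
  res <- resolve_reviews(link_lists(left, right, cfg))
  expect_identical(pair_keys(linkage_matches(res)),
                   brute_force_matches(left, right, cfg))
})

test_that("every left surname lands in matches, reviews or unmatched", {
  w <- cached_world()
  left <- w$reference_extract$surname[1:60]
  right <- harvest_surnames(w$vital_records, build_config())$surname[1:200]
  res <- link_lists(left, right)
  active <- res$pairs[res$pairs$category %in% c("match", "review"), ]
  covered <- union(unique(active$left), res$left_unmatched)
  expect_setequal(covered, left)
  # no pair appears twice
  expect_false(any(duplicated(paste(res$pairs$left, res$pairs$right))))
})

test_that("swapping the lists transposes the result", {
  w <- cached_world()
  left <- w$reference_extract$surname[1:60]
  right <- harvest_surnames(w$vital_records, build_config())$surname[1:200]
  ab <- link_lists(left, right)
  ba <- link_lists(right, left)
  expect_setequal(paste(linkage_matches(ab)$left, linkage_matches(ab)$right),
                  paste(linkage_matches(ba)$right, linkage_matches(ba)$left))
  expect_identical(ab$left_unmatched, ba$right_unmatched)
  expect_identical(ab$right_unmatched, ba$left_unmatched)
})

test_that("raising the match threshold never adds similarity matches", {
  w <- cached_world()
  left <- w$reference_extract$surname[1:100]
  right <- harvest_surnames(w$vital_records, build_config())$surname[1:300]
  n_sim_matches <- function(th) {
    res <- link_lists(left, right,
                      linkage_config(match_threshold = th,
                                     review_low = min(0.85, th)))
    sum(linkage_matches(res)$basis == "similarity")
  }
  counts <- vapply(c(0.85, 0.90, 0.95, 0.99), n_sim_matches, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical lists link fully with no reviews", {
  nms <- c("Martirosyan", "Danielian", "Oganesov")
  res <- link_lists(nms, nms)
  expect_equal(nrow(linkage_reviews(res)), 0)
  expect_length(res$left_unmatched, 0)
  expect_true(all(nms %in% linkage_matches(res)$left))
})

test_that("disjoint blocks leave everything unmatched", {
  res <- link_lists(c("Martirosyan"), c("Weatherford"))
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$left_unmatched, "Martirosyan")
  expect_equal(res$right_unmatched, "Weatherford")
})

test_that("review export/import round-trips and applies decisions", {
  # construct a pair landing in the review band
  left <- c("Mahtesyan", "Galstyan")
  right <- c("Mahtesian", "Galostian")
  cfg <- linkage_config(match_threshold = 0.99, review_low = 0.80)
  res <- link_lists(left, right, cfg)
  expect_gt(nrow(linkage_reviews(res)), 0)

  f <- withr::local_tempfile(fileext = ".csv")
  export_review(res, f)
  exported <- utils::read.csv(f, colClasses = "character")
  expect_equal(nrow(exported), nrow(linkage_reviews(res)))

  # no edits: import equals auto-resolution by the default (non_match)
  auto <- resolve_reviews(res)
  imported <- import_review(res, f)
  expect_identical(imported$pairs, auto$pairs)
  expect_equal(nrow(linkage_reviews(imported)), 0)

  # decide one pair 'match': it moves into the match set
  exported$decision[1] <- "match"
  write.csv(exported, f, row.names = FALSE)
  decided <- import_review(res, f)
  expect_true(paste(exported$left[1], exported$right[1]) %in%
                paste(linkage_matches(decided)$left,
                      linkage_matches(decided)$right))

  # a decision for an unknown pair is a validation error
  expect_error(resolve_reviews(res, data.frame(left = "Nope", right = "Nor",
                                               decision = "match")),
               "unknown pair")
})

test_that("empty review sets export an empty file and import is identity", {
  res <- link_lists(c("Smith"), c("Smith"))
  f <- withr::local_tempfile(fileext = ".csv")
  export_review(res, f)
  back <- import_review(res, f)
  expect_identical(back$pairs, resolve_reviews(res)$pairs)
})

test_that("linkage output is byte-deterministic", {
  w <- cached_world()
  left <- w$reference_extract$surname[1:50]
  right <- harvest_surnames(w$vital_records, build_config())$surname[1:150]
  cfg <- linkage_config(match_threshold = 0.99, review_low = 0.80)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_review(link_lists(left, right, cfg), f1)
  export_review(link_lists(left, right, cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
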