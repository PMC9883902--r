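test_that("pairwise overlap counts match hand tallies", {
  r <- overlap(c("X", "Y"), c("Y", "Z"))
  expect_equal(r$only_a, 1); expect_equal(r$only_b, 1)
  expect_equal(r$both, 1); expect_equal(r$jaccard, 1 / 3)
  expect_equal(r$pct_of_b_in_a, 50)

  same <- overlap(c("A", "B"), c("b", "a"))
  expect_equal(same$only_a, 0); expect_equal(same$only_b, 0)
  expect_equal(same$jaccard, 1)

  disj <- overlap(c("A"), c("B"))
  expect_equal(disj$both, 0); expect_equal(disj$jaccard, 0)

  zero <- overlap(character(0), character(0))
  expect_true(is.na(zero$jaccard))
})

test_that("truncation-aware overlap credits 10-letter prefixes", {
  r <- overlap(c("MARTIROSYA"), c("MARTIROSYAN"),
               match_mode = "truncation_aware")
  expect_equal(r$both, 1)
  expect_equal(overlap(c("MARTIROSYA"), c("MARTIROSYAN"))$both, 0)
})

test_that("venn3 regions agree with a per-element membership oracle", {
  v <- venn3(c("X"), c("Y"), c("Z"))
  expect_equal(unname(v$regions[c("a_only", "b_only", "c_only")]),
               c(1, 1, 1))
  expect_equal(sum(v$regions), 3)

  all_same <- venn3("X", "x", "X")
  expect_equal(unname(all_same$regions[["abc"]]), 1)
  expect_equal(sum(all_same$regions), 1)

  set.seed(42)
  pool <- sprintf("N%03d", 1:60)
  for (i in 1:10) {
    a <- sample(pool, 25); b <- sample(pool, 25); c <- sample(pool, 25)
    v <- venn3(a, b, c)
    u <- unique(c(a, b, c))
    tally <- table(factor(paste0(as.integer(u %in% a), as.integer(u %in% b),
                                 as.integer(u %in% c)),
                          levels = c("100", "010", "001", "110", "101",
                                     "011", "111")))
    expect_equal(unname(v$regions),
                 unname(as.integer(tally)))
    expect_equal(v$union_size, length(u))
    # marginals equal the pairwise overlap results
    ab <- overlap(a, b)
    expect_equal(ab$both, unname(v$regions[["ab"]] + v$regions[["abc"]]))
  }
})

test_that("coverage gain equals brute-force set arithmetic", {
  g <- coverage_gain(new_list = c("A", "B", "C", "Q"), baseline = "A",
                     reference = c("A", "B", "C"))
  expect_equal(g$gain_count, 2)
  expect_equal(g$gain_pct, 100 * 2 / 3, tolerance = 1e-10)

  sub <- coverage_gain(new_list = c("A"), baseline = c("A", "B"),
                       reference = c("A", "B"))
  expect_equal(sub$gain_count, 0)

  none <- coverage_gain(new_list = "Z", baseline = "A", reference = "B")
  expect_true(is.na(none$gain_pct))

  set.seed(42)
  pool <- sprintf("N%03d", 1:80)
  for (i in 1:10) {
    new <- sample(pool, 30); base <- sample(pool, 30); ref <- sample(pool, 30)
    g <- coverage_gain(new, base, ref)
    cap <- intersect(ref, new)
    expect_equal(g$gain_count, length(setdiff(cap, base)))
    if (length(cap)) {
      expect_equal(g$gain_pct, 100 * length(setdiff(cap, base)) / length(cap))
    }
  }
})

test_that("coverage gain is zero whenever the new list adds nothing", {
  set.seed(42)
  pool <- sprintf("N%03d", 1:40)
  for (i in 1:5) {
    base <- sample(pool, 30)
    new <- sample(base, 10)
    expect_equal(coverage_gain(new, base, sample(pool, 20))$gain_count, 0)
  }
})

test_that("contingency table counts, percentages and units check out", {
  rec <- data.frame(
    surname = c("Aivazyan", "Barsamian", "Carstyan", "Dunno"),
    birthplace = c("Armenia", "Armenia", "Armenia", NA),
    stringsAsFactors = FALSE)
  ct <- contingency_table(rec, c("Aivazyan", "Barsamian"), "Armenia")
  expect_equal(unname(ct$counts["yes", "target"]), 2)
  expect_equal(unname(ct$counts["no", "target"]), 1)
  expect_equal(unname(ct$counts["no", "unknown"]), 1)
  expect_equal(unname(ct$percent["yes", "target"]), 200 / 3,
               tolerance = 1e-10)
  expect_equal(unname(colSums(ct$percent)[c("target", "unknown")]),
               c(100, 100))
  expect_equal(ct$n_units, 4)

  empty_list <- contingency_table(rec, character(0), "Armenia")
  expect_equal(sum(empty_list$counts["yes", ]), 0)
})

test_that("contingency counts each surname once per stratum it appears in", {
  rec <- data.frame(surname = c("Aivazyan", "Aivazyan", "Aivazyan"),
                    birthplace = c("Armenia", "Armenia", "Ireland"),
                    stringsAsFactors = FALSE)
  ct <- contingency_table(rec, "Aivazyan", "Armenia")
  expect_equal(ct$n_units, 2)
  expect_equal(unname(ct$counts["yes", "target"]), 1)
  expect_equal(unname(ct$counts["yes", "other"]), 1)
})

test_that("contingency matches a brute-force tally on a synthetic world", {
  w <- cached_world()
  built <- build_surname_list(w$reference_extract, w$vital_records)
  ct <- contingency_table(w$vital_records, built$list, "Armenia")
  # independent tally
  rec <- w$vital_records
  units <- unique(rbind(
    data.frame(s = toupper(rec$surname),
               g = ifelse(is.na(rec$birthplace), "unknown",
                          ifelse(rec$birthplace == "Armenia", "target",
                                 "other"))),
    data.frame(s = toupper(rec$father_surname),
               g = ifelse(is.na(rec$birthplace), "unknown",
                          ifelse(rec$birthplace == "Armenia", "target",
                                 "other")))))
  units <- units[!is.na(units$s), ]
  members <- toupper(built$list$surname)
  for (g in c("target", "other", "unknown")) {
    expect_equal(unname(ct$counts["yes", g]),
                 sum(units$g == g & units$s %in% members))
    expect_equal(unname(ct$counts["no", g]),
                 sum(units$g == g & !units$s %in% members))
  }
  expect_equal(sum(ct$counts), nrow(units))
  expect_equal(unname(colSums(ct$percent)), c(100, 100, 100))
})

test_that("suffix distributions sum to one and match hand counts", {
  d <- suffix_distribution(c("Danielian", "Martirosyan"))
  expect_equal(d$proportion[d$class == "I_convention"], 0.5)
  expect_equal(d$proportion[d$class == "Y_convention"], 0.5)
  expect_equal(sum(d$proportion), 1)

  all_other <- suffix_distribution(c("Smith", "Jones"))
  expect_equal(all_other$proportion[all_other$class == "other"], 1)

  strat <- suffix_distribution(
    c("DANIELIAN", "MARTIROSYAN", "SMITH"),
    strata = c(DANIELIAN = "russia", MARTIROSYAN = "armenia",
               SMITH = "armenia"))
  for (g in unique(strat$stratum)) {
    expect_equal(sum(strat$proportion[strat$stratum == g]), 1,
                 tolerance = 1e-3)
  }
})

test_that("the generator's convention mixture is recovered within 3 points", {
  mix <- c(Y_convention = 0.55, I_convention = 0.25, russian = 0.10,
           no_suffix_long = 0.10)
  w <- generate_world(world_config(n_target_stems = 2000,
                                   n_other_surnames = 0,
                                   n_trap_short = 0, n_trap_nosuffix = 0,
                                   p_particle = 0, p_variant_spelling = 0,
                                   p_truncated_in_reference = 0, seed = 42))
  d <- suffix_distribution(w$truth$surname[w$truth$label == "target"])
  got <- stats::setNames(d$proportion, d$class)
  expect_lt(abs(got[["Y_convention"]] - mix[["Y_convention"]]), 0.03)
  expect_lt(abs(got[["I_convention"]] - mix[["I_convention"]]), 0.03)
  expect_lt(abs(got[["russian"]] - mix[["russian"]]), 0.03)
  # no_suffix_long names classify as 'other' by construction
  expect_lt(abs(got[["other"]] - mix[["no_suffix_long"]]), 0.03)
})

test_that("set operations ignore input order and case", {
  a <- c("Aivazyan", "BARSAMIAN"); b <- c("barsamian", "Carstyan")
  expect_equal(overlap(a, b)$both, overlap(rev(toupper(a)), rev(b))$both)
  v1 <- venn3(a, b, a); v2 <- venn3(toupper(rev(a)), rev(b), tolower(a))
  expect_equal(v1$regions, v2$regions)
})

test_that("the demo origin ranker honours the adapter contract", {
  rk <- demo_origin_ranker()
  out <- rk("Martirosyan")
  expect_true(is.data.frame(out))
  expect_named(out, c("country", "rank"))
  expect_lte(nrow(out), 10)
  expect_equal(out$rank, seq_len(nrow(out)))
  expect_equal(out$country[1], "Armenia")
})
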