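vital_df <- function(surname, father = NA_character_, birthplace = NA) {
  data.frame(surname = surname,
             father_surname = rep_len(father, length(surname)),
             birthplace = rep_len(birthplace, length(surname)),
             stringsAsFactors = FALSE)
}

test_that("harvesting collects both the surname and the father's surname", {
  rec <- vital_df("Danielson", father = "Danielian")
  h <- harvest_surnames(rec, build_config())
  expect_setequal(h$surname, c("Danielson", "Danielian"))

  two <- harvest_surnames(vital_df(c("Smith", "Smith")), build_config())
  expect_equal(nrow(two), 1)

  no_father <- harvest_surnames(vital_df("Smith"), build_config())
  expect_equal(no_father$surname, "Smith")

  off <- build_config(harvest_father_surname = FALSE)
  expect_equal(harvest_surnames(rec, off)$surname, "Danielson")
})

test_that("birthplace candidates subtract linked names and unknown strata", {
  rec <- vital_df(c("Aivazyan", "Barsamian", "Carstyan", "Dilanyan",
                    "Egoyan", "Farrell"),
                  birthplace = c("Armenia", "Armenia", "Armenia", "Armenia",
                                 NA, "Ireland"))
  cfg <- build_config()
  all5 <- birthplace_candidates(rec, character(0), cfg)
  expect_setequal(all5$surname,
                  c("Aivazyan", "Barsamian", "Carstyan", "Dilanyan"))

  minus2 <- birthplace_candidates(rec, c("AIVAZYAN", "BARSAMIAN"), cfg)
  expect_equal(nrow(minus2), 2)

  none <- birthplace_candidates(
    rec, c("AIVAZYAN", "BARSAMIAN", "CARSTYAN", "DILANYAN"), cfg)
  expect_equal(nrow(none), 0)
})

test_that("spelling variants matched across sources are both retained", {
  rec <- vital_df(c("Mahtesian", "Jones"), birthplace = "United States")
  built <- build_surname_list(c("Mahtesyan"), rec)
  expect_true(all(c("Mahtesian", "Mahtesyan") %in% built$list$surname))
  expect_true(all(built$list$source[built$list$surname %in%
                                      c("Mahtesian", "Mahtesyan")] ==
                    "reference_linked"))
})

test_that("reference surnames absent everywhere are retained verbatim", {
  rec <- vital_df("Jones", birthplace = "United States")
  built <- build_surname_list(c("Ter-Galoustian"), rec)
  expect_equal(built$list$surname, "Ter-Galoustian")
  expect_equal(built$list$source, "reference_retained")
  expect_equal(built$audit$n_reference_retained, 1)
})

test_that("a known-composition fixture reproduces its audit counts", {
  # 10 reference names appearing verbatim in records (linked), 3 reference
  # names appearing nowhere (retained), 5 suffixed target-birthplace names
  # (added) and 4 filter-removable target-birthplace names (removed)
  linked_ref <- paste0(c("Abel", "Bagrat", "Caren", "Davit", "Eduard",
                         "Gagik", "Hovik", "Karen", "Levon", "Mamik"), "yan")
  retained_ref <- c("Ter-Galoustian", "Ambartsumi", "Nersesmanu")
  added <- c("Ohanian", "Petrosyan", "Rubenyants", "Sargsov",
             "Torosmelikounz")
  removed <- c("Smith", "Abad", "Ryan", "Weatherford")
  rec <- rbind(
    vital_df(linked_ref, birthplace = "United States"),
    vital_df(c(added, removed), birthplace = "Armenia"))
  built <- build_surname_list(c(linked_ref, retained_ref), rec)

  expect_equal(built$audit$n_reference_input, 13)
  expect_equal(built$audit$n_linked, 10)
  expect_equal(built$audit$n_birthplace_candidates, 9)
  expect_equal(built$audit$n_removed_by_filter, 4)
  expect_equal(built$audit$n_birthplace_added, 5)
  expect_equal(built$audit$n_reference_retained, 3)
  expect_equal(built$audit$n_total_unique, 18)
  expect_equal(built$audit$n_total_unique, nrow(built$list))
  # brute-force union of the three disjoint sets
  expect_setequal(built$list$surname, c(linked_ref, retained_ref, added))
})

test_that("every entry carries exactly one source tag and sets partition", {
  w <- cached_world()
  built <- build_surname_list(w$reference_extract, w$vital_records)
  expect_false(any(duplicated(toupper(built$list$surname))))
  expect_true(all(built$list$source %in%
                    c("reference_linked", "birthplace_added",
                      "reference_retained")))
  a <- built$audit
  expect_equal(a$n_birthplace_candidates,
               a$n_birthplace_added + a$n_removed_by_filter)
  expect_equal(a$n_total_unique, nrow(built$list))
  expect_equal(sum(built$list$source == "birthplace_added"),
               a$n_birthplace_added)
})

test_that("the filter never touches linked or retained reference names", {
  # a reference name that would fail the filter must still be retained
  rec <- vital_df("Jones", birthplace = "United States")
  built <- build_surname_list(c("Abad"), rec)
  expect_equal(built$list$surname, "Abad")
  expect_equal(built$list$source, "reference_retained")
})

test_that("an empty reference or record set warns but still builds", {
  rec <- vital_df("Aivazyan", birthplace = "Armenia")
  expect_warning(b <- build_surname_list(surname_list(), rec), "empty")
  expect_equal(b$audit$n_reference_input, 0)
  expect_equal(b$audit$n_birthplace_added, 1)
  expect_warning(b2 <- build_surname_list(c("Mahtesyan"), rec[0, ]), "empty")
  expect_equal(b2$audit$n_reference_retained, 1)
})

test_that("builds are deterministic down to the output bytes", {
  w <- cached_world()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_surname_list(build_surname_list(w$reference_extract,
                                        w$vital_records)$list, f1, "csv")
  write_surname_list(build_surname_list(w$reference_extract,
                                        w$vital_records)$list, f2, "csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
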