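test_that("effects parsing maps code tokens and phrases to categories", {
  expect_identical(as.character(parse_effects("Del, or Abs")), c("DELAYED", "ABSENT"))
  expect_identical(as.character(parse_effects("Norm")), "NORMAL")
  expect_identical(as.character(parse_effects("Dysarthric, Abs; Imp")),
                   c("DYSARTHRIC", "IMPAIRED", "ABSENT"))
  expect_identical(as.character(parse_effects("No significant anomaly reports")), "NORMAL")
  expect_identical(as.character(parse_effects("Sensorineural hearing loss")), "NORMAL")
  # token order in the text does not matter
  expect_identical(parse_effects("Abs or Del"), parse_effects("Del, or Abs"))
  # word boundaries: "Delete" is not a Del token
  expect_false("DELAYED" %in% parse_effects("Deletion of speech-unrelated genes, Norm"))
})

test_that("uncategorizable effects are flagged, not errored", {
  e <- parse_effects("")
  expect_length(e, 0)
  expect_true(attr(e, "uncategorizable"))
  na <- parse_effects("-Not available-")
  expect_length(na, 0)
  expect_true(attr(na, "uncategorizable"))
  ok <- parse_effects("Del")
  expect_false(attr(ok, "uncategorizable"))
})

test_that("idiosyncratic folds into apraxic unless kept separate", {
  expect_identical(as.character(parse_effects("Apr or Idio")), "APRAXIC")
  kept <- parse_effects("Apr or Idio", fold_idiosyncratic = FALSE)
  expect_setequal(kept, c("APRAXIC", "IDIOSYNCRATIC"))
  expect_identical(as.character(parse_effects("Del; Idio")), c("APRAXIC", "DELAYED"))
})

test_that("cohort construction merges duplicate regions and drops unannotated rows", {
  cohort <- build_cohort(syndrome_records())
  expect_identical(attr(cohort, "n_merged"), 74L)   # 76 rows, 2 merges
  expect_identical(nrow(cohort), 73L)               # 16q22 has no speech info
  expect_false("16q22" %in% cohort$name)
  m <- cohort[cohort$name == "15q11-q13", ]
  expect_identical(nrow(m), 1L)
  expect_length(m$merged_names[[1]], 2)
  expect_identical(m$vn2_count, 30L)                # counts kept once
  expect_true(all(c("DELAYED", "IMPAIRED", "ABSENT") %in% m$categories[[1]]))
  x <- cohort[cohort$name == "Xq28", ]
  expect_identical(x$vn2_count, 64L)                # inherited by "same as above"
  expect_true(all(c("NORMAL", "ABSENT", "DELAYED") %in% x$categories[[1]]))
})

test_that("a fully annotated duplicate-free table passes through unchanged", {
  recs <- syndrome_records()
  sub <- recs[1:10, ]
  cohort <- build_cohort(sub)
  expect_identical(nrow(cohort), 10L)
  expect_identical(cohort$name, sub$name)
  expect_identical(cohort$vn2_count, sub$vn2_count)
})

test_that("duplicate regions with conflicting counts are an ambiguous merge", {
  recs <- syndrome_records()[1:2, ]
  recs$name <- c("dup", "dup")
  recs$same_as_above <- c(FALSE, FALSE)
  expect_error(build_cohort(recs), "ambiguous merge")
})

test_that("co-occurrence summary matches the packaged cohort", {
  co <- cooccurrence_stats(build_cohort(syndrome_records()))
  expect_identical(co$n, 73L)
  expect_identical(co$n_level1, 17L)
  expect_identical(co$n_level2_only, 56L)
  expect_identical(co$pct_level1_with_anomaly, 100)
  expect_identical(co$pct_level2_with_anomaly, 91.8)
  expect_identical(co$n_normal_only, 6L)
})

test_that("a one-syndrome normal cohort has zero anomaly co-occurrence", {
  recs <- data.frame(
    name = "toy", implicated = I(list(character())),
    vn1_count = 0L, vn1_connectivity = 0L,
    vn2_count = 4L, vn2_connectivity = 9L,
    effects = "Norm", same_as_above = FALSE, stringsAsFactors = FALSE
  )
  co <- cooccurrence_stats(build_cohort(recs))
  expect_identical(co$n_level1, 0L)
  expect_true(is.na(co$pct_level1_with_anomaly))
  expect_identical(co$pct_level2_with_anomaly, 0)
})

test_that("category statistics use level-2 counts with midpoint medians", {
  st <- category_stats(build_cohort(syndrome_records()))
  absent <- st[st$category == "ABSENT", ]
  expect_identical(absent$n, 19L)
  expect_identical(absent$mean_count_reported, 60)
  expect_identical(absent$median_count, 46)
  expect_identical(absent$mean_connectivity_reported, 902)
  expect_identical(absent$median_connectivity, 718)
  # dysarthric group is also fully determined by the printed codes
  dys <- st[st$category == "DYSARTHRIC", ]
  expect_identical(dys$n, 11L)
  expect_identical(dys$median_count, 36)
  expect_identical(dys$median_connectivity, 737)
})

test_that("hand-built cohorts give exact means and medians", {
  mk <- function(counts) data.frame(
    name = paste0("s", seq_along(counts)),
    implicated = I(rep(list(character()), length(counts))),
    vn1_count = 0L, vn1_connectivity = 0L,
    vn2_count = counts, vn2_connectivity = counts * 10L,
    effects = "Abs", same_as_above = FALSE, stringsAsFactors = FALSE
  )
  st <- category_stats(build_cohort(mk(c(2L, 4L, 6L))))
  absent <- st[st$category == "ABSENT", ]
  expect_identical(absent$mean_count, 4)
  expect_identical(absent$median_count, 4)
  # even count: midpoint of the middle two
  st4 <- category_stats(build_cohort(mk(c(1L, 2L, 10L, 20L))))
  expect_identical(st4[st4$category == "ABSENT", "median_count"], 6)
  # single syndrome: mean equals median equals its own value
  st1 <- category_stats(build_cohort(mk(c(7L, 7L))[1, ]))
  expect_identical(st1[st1$category == "ABSENT", "mean_count"], 7)
  # empty categories report NA statistics
  expect_true(is.na(st1[st1$category == "NORMAL", "mean_count"]))
})

test_that("category membership is non-exclusive (counts sum >= cohort size)", {
  cohort <- build_cohort(syndrome_records())
  st <- category_stats(cohort)
  expect_gte(sum(st$n), nrow(cohort))
})

test_that("extremes of the severity ordering are normal and absent", {
  st <- category_stats(build_cohort(syndrome_records()))
  ord <- attr(st, "ordering")
  expect_identical(ord[1], "NORMAL")
  expect_identical(ord[length(ord)], "ABSENT")
  expect_match(category_ordering(st), "^normal\\(.*< absent\\(60,902\\)$")
})

test_that("category count sets carry the per-syndrome level-2 values", {
  cohort <- build_cohort(syndrome_records())
  sets <- category_count_sets(cohort, "count")
  st <- category_stats(cohort)
  expect_identical(lengths(sets)[st$category], structure(st$n, names = st$category))
  expect_identical(sort(sets$ABSENT)[1:3], c(5L, 7L, 9L))
  conn <- category_count_sets(cohort, "connectivity")
  expect_identical(stats::median(conn$ABSENT), 718L)
})
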