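test_that("percent_int rounds halves away from zero and handles den = 0", {
  expect_identical(percent_int(83, 887), 9L)
  expect_identical(percent_int(0, 887), 0L)
  expect_identical(percent_int(426, 476), 89L)
  expect_identical(percent_int(1, 200), 1L)     # 0.5 -> 1, away from zero
  expect_identical(percent_int(3, 200), 2L)     # 1.5 -> 2
  expect_identical(percent_int(5, 0), NA_integer_)
  expect_identical(percent_int(c(83, 275), c(887, 887)), c(9L, 31L))
  # bounded and weakly increasing in the numerator
  p <- percent_int(0:887, 887)
  expect_true(all(p >= 0 & p <= 100))
  expect_true(all(diff(p) >= 0))
  expect_error(percent_int(-1, 10))
})

test_that("funnel reports annotate stage and full-sample percents", {
  rep <- build_funnel_report(
    c(base = 887, inclusion = 153, amyloid = 136, eligible = 83),
    c(full_sample = 887))
  expect_identical(rep$pct_of_previous, c(NA_integer_, 17L, 89L, 61L))
  expect_identical(rep$pct_of_full_sample, c(100L, 17L, 15L, 9L))

  rep2 <- build_funnel_report(
    c(base = 887, inclusion = 425, amyloid = 387, eligible = 172),
    c(full_sample = 887))
  expect_identical(rep2$pct_of_previous[2:3], c(48L, 91L))
  expect_identical(rep2$pct_of_full_sample[3:4], c(44L, 19L))

  all100 <- build_funnel_report(c(a = 100, b = 100, c = 100, d = 100),
                                c(full_sample = 100))
  expect_true(all(all100$pct_of_full_sample == 100L))
  expect_error(build_funnel_report(c(a = 10, b = 12), c(full_sample = 10)),
               "not weakly decreasing")
  expect_error(build_funnel_report(c(a = 10, b = 9), c(whole = 10)),
               "full_sample")
})

test_that("euler_regions partitions the union by membership signature", {
  out <- euler_regions(list(A = c("1", "2"), B = c("2", "3")))
  counts <- setNames(out$count, out$region)
  expect_identical(counts[["A"]], 1L)
  expect_identical(counts[["B"]], 1L)
  expect_identical(counts[["A&B"]], 1L)
  expect_identical(attr(out, "union_size"), 3L)

  same <- euler_regions(list(A = c("1", "2"), B = c("1", "2")))
  expect_identical(setNames(same$count, same$region),
                   c(A = 0L, B = 0L, `A&B` = 2L))

  # invariants on random instances: regions partition the union, and the
  # regions containing a set sum to that set's size
  set.seed(99)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(as.character(1:50), sample(0:30, 1)))
    names(sets) <- c("A", "B", "C")
    out <- euler_regions(sets)
    expect_identical(sum(out$count), attr(out, "union_size"))
    for (nm in names(sets)) {
      in_region <- vapply(strsplit(out$region, "&", fixed = TRUE),
                          function(r) nm %in% r, logical(1))
      expect_identical(sum(out$count[in_region]), length(unique(sets[[nm]])))
    }
  }
})

test_that("co-pathology prevalence counts tri-states without imputing", {
  ids <- paste0("P", 1:4)
  co <- new_cohort(make_clinical(ids),
                   make_neuropath(ids, lewy = c("present", "present",
                                                "absent", "not_reported")))
  tab <- copathology_prevalence(ids, co)
  lewy <- tab[tab$copathology == "lewy_body", ]
  expect_identical(lewy$present, 2L)
  expect_identical(lewy$not_reported, 1L)
  expect_identical(lewy$percent_present, 50L)
  # complete-case denominator for sensitivity: 2/3 -> 67
  cc <- copathology_prevalence(ids, co, complete_case = TRUE)
  expect_identical(cc$percent_present[cc$copathology == "lewy_body"], 67L)
  # empty group: undefined-percent markers, no crash
  empty <- copathology_prevalence(character(0), co)
  expect_true(all(is.na(empty$percent_present)))
})

test_that("CDR composition and full-AD-pathology shares on fixtures", {
  ids <- paste0("P", 1:3)
  co <- new_cohort(make_clinical(ids, cdr = c(0.5, 1, 1)), make_neuropath(ids))
  comp <- cdr_composition(ids, co)
  expect_identical(comp$percent_cdr_05, 33L)
  expect_identical(comp$n_cdr_1, 2L)

  ids5 <- paste0("Q", 1:5)
  co5 <- new_cohort(make_clinical(ids5),
                    make_neuropath(ids5, thal = c(4L, 4L, 3L, 5L, 1L),
                                   braak = c(5L, 6L, 4L, 5L, 1L),
                                   cerad = c(3L, 2L, 2L, 3L, 0L)))
  fad <- full_ad_pathology_share(ids5, co5)
  expect_identical(fad$n_full_ad, 4L)
  expect_identical(fad$percent_full_ad, 80L)

  all_not <- new_cohort(make_clinical(ids),
                        make_neuropath(ids, thal = 0L, braak = 0L, cerad = 0L))
  expect_identical(full_ad_pathology_share(ids, all_not)$percent_full_ad, 0L)
  # missing staging is counted separately, not guessed
  co5$neuropath$cerad_score[2] <- NA_integer_
  expect_identical(full_ad_pathology_share(ids5, co5)$n_unstaged, 1L)
})
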