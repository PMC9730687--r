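test_that("measurability filter keeps lesions at or above 10 mm", {
  expect_length(filter_measurable(fake_lesion_set(c(12, 40)))$lesions, 2L)
  expect_length(filter_measurable(fake_lesion_set(c(6, 8)))$lesions, 0L)
  kept <- filter_measurable(fake_lesion_set(c(9.9, 10.0, 10.1)))$lesions
  expect_equal(sort(vapply(kept, `[[`, 0, "longest_axial_diameter_mm")),
               c(10.0, 10.1))
  # threshold is configurable
  cfg <- recist_config(min_measurable_diameter_mm = 15)
  expect_length(filter_measurable(fake_lesion_set(c(12, 40)), cfg)$lesions, 1L)
})

test_that("target selection caps at five and breaks ties deterministically", {
  eight <- fake_lesion_set(c(40, 35, 30, 25, 20, 15, 12, 11))
  tgt <- select_targets(filter_measurable(eight))
  expect_identical(nrow(tgt$targets), 5L)
  expect_equal(tgt$sum_of_diameters_mm, 40 + 35 + 30 + 25 + 20)

  three <- select_targets(filter_measurable(fake_lesion_set(c(30, 20, 12))))
  expect_identical(nrow(three$targets), 3L)

  tied <- fake_lesion_set(c(30, 20, 20, 15, 12, 11),
                          volumes_mm3 = c(900, 500, 800, 200, 100, 90))
  tgt2 <- select_targets(filter_measurable(tied))
  expect_equal(tgt2$sum_of_diameters_mm, 30 + 20 + 20 + 15 + 12)
  # the larger-volume 20 mm lesion (id 3) ranks ahead of the other (id 2)
  pos <- match(c(3L, 2L), tgt2$targets$lesion_id)
  expect_lt(pos[1], pos[2])

  empty <- select_targets(filter_measurable(fake_lesion_set(c(4, 6))))
  expect_identical(nrow(empty$targets), 0L)
  expect_identical(empty$sum_of_diameters_mm, 0)
})

test_that("percent change is baseline-referenced and guards against zero baseline", {
  expect_equal(percent_change(100, 70), -30)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(50, 0), -100)
  expect_error(percent_change(0, 10), "no measurable baseline disease")
  # scale invariance: rescaling both sums leaves the change unchanged
  set.seed(5)
  for (i in 1:20) {
    b <- runif(1, 10, 150); f <- runif(1, 0, 200); s <- runif(1, 0.1, 10)
    expect_equal(percent_change(s * b, s * f), percent_change(b, f))
  }
})

test_that("new lesions are flagged on a target-count increase only", {
  expect_true(detect_new_lesions(3, 4))
  expect_false(detect_new_lesions(5, 5))
  expect_false(detect_new_lesions(4, 2))
})

fake_targets <- function(sum_mm, n = 1L) {
  structure(list(targets = data.frame(lesion_id = seq_len(n),
                                      diameter_mm = rep(sum_mm / n, n),
                                      volume_mm3 = rep(1, n)),
                 sum_of_diameters_mm = sum_mm),
            class = "target_set")
}

test_that("rule order yields the four categories and new lesions force PD", {
  cr <- classify_response(fake_targets(100), fake_targets(0, 0L), FALSE)
  expect_identical(cr$category, "CR")
  pr <- classify_response(fake_targets(100), fake_targets(65), FALSE)
  expect_identical(pr$category, "PR")
  sd_ <- classify_response(fake_targets(100), fake_targets(112), FALSE)
  expect_identical(sd_$category, "SD")
  pd <- classify_response(fake_targets(100), fake_targets(130), FALSE)
  expect_identical(pd$category, "PD")
  # shrinkage plus new lesions is still PD
  forced <- classify_response(fake_targets(100), fake_targets(50), TRUE)
  expect_identical(forced$category, "PD")
  expect_match(forced$rule_trace[1], "new lesions")
  # percent change is consistent with the sums on every assessment
  for (r in list(cr, pr, sd_, pd))
    expect_equal(r$percent_change,
                 100 * (r$followup_targets$sum_of_diameters_mm - 100) / 100)
})

test_that("the 5 mm absolute-increase clause gates PD and can be disabled", {
  # +25% but only +4.5 mm: SD under the default clause
  sd_ <- classify_response(fake_targets(18), fake_targets(22.5), FALSE)
  expect_identical(sd_$category, "SD")
  # same change with the clause disabled: PD
  off <- recist_config(pd_min_absolute_increase_mm = 0)
  pd <- classify_response(fake_targets(18), fake_targets(22.5), FALSE, off)
  expect_identical(pd$category, "PD")
  # +25% and +5 mm: PD under the default clause
  pd2 <- classify_response(fake_targets(20), fake_targets(25), FALSE)
  expect_identical(pd2$category, "PD")
})

test_that("assess_pair composes the pipeline deterministically", {
  cs <- make_longitudinal_case(random_longitudinal_spec("PR", seed = 77))
  r1 <- assess_pair(cs$baseline$tumor, cs$baseline$liver,
                    cs$followup$tumor, cs$followup$liver)
  r2 <- assess_pair(cs$baseline$tumor, cs$baseline$liver,
                    cs$followup$tumor, cs$followup$liver)
  expect_identical(r1$category, "PR")
  expect_identical(r1$rule_trace, r2$rule_trace)
  expect_identical(r1$percent_change, r2$percent_change)

  # identical masks at both timepoints: SD with zero change
  same <- assess_pair(cs$baseline$tumor, cs$baseline$liver,
                      cs$baseline$tumor, cs$baseline$liver)
  expect_identical(same$category, "SD")
  expect_equal(same$percent_change, 0)

  # a follow-up gaining one measurable lesion classifies PD by the count rule
  spec <- phantom_spec(lesions = list(list(center_mm = c(55, 70, 44),
                                           diameter_mm = 20)))
  lsp <- longitudinal_spec(spec, scale_factors = 1,
                           lesions_added = list(list(center_mm = c(95, 70, 44),
                                                     diameter_mm = 15)))
  cs2 <- make_longitudinal_case(lsp)
  r3 <- assess_pair(cs2$baseline$tumor, cs2$baseline$liver,
                    cs2$followup$tumor, cs2$followup$liver)
  expect_identical(r3$category, "PD")
  expect_true(r3$new_lesions)
})

test_that("a baseline without measurable disease is not assessable", {
  spec <- phantom_spec(lesions = list(list(center_mm = c(70, 70, 44),
                                           diameter_mm = 6)))
  ph <- make_phantom(spec)
  expect_error(
    assess_pair(ph$tumor, ph$liver, ph$tumor, ph$liver),
    "not assessable")
})
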