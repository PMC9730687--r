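test_that("confusion matrix counts pairs in fixed category order", {
  all_sd <- data.frame(reference = rep("SD", 10), rater = rep("SD", 10))
  m <- response_confusion(all_sd)
  expect_equal(diag(m), c(CR = 0, PR = 0, SD = 10, PD = 0))
  expect_equal(sum(m), 10)

  mixed <- data.frame(reference = c("PR", "PR", "PD"),
                      rater = c("PR", "SD", "PD"))
  m2 <- response_confusion(mixed)
  expect_equal(m2["PR", "PR"], 1)
  expect_equal(m2["PR", "SD"], 1)
  expect_equal(m2["PD", "PD"], 1)
  expect_equal(sum(m2), 3)

  set.seed(101)
  rnd <- data.frame(reference = sample(RECIST_CATEGORIES, 200, TRUE),
                    rater = sample(RECIST_CATEGORIES, 200, TRUE))
  m3 <- response_confusion(rnd)
  expect_equal(rowSums(m3),
               c(CR = sum(rnd$reference == "CR"), PR = sum(rnd$reference == "PR"),
                 SD = sum(rnd$reference == "SD"), PD = sum(rnd$reference == "PD")))
  # labels are case-insensitive, unknown labels name the case
  expect_equal(sum(response_confusion(data.frame(reference = "pr", rater = "Pr"))), 1)
  expect_error(response_confusion(data.frame(case_id = "c7", reference = "XX",
                                             rater = "SD")), "c7")
})

test_that("accuracy and its exact interval behave like the binomial they are", {
  set.seed(111)
  ref <- sample(RECIST_CATEGORIES, 31, TRUE)
  rat <- ref
  wrong <- sample(31, 8)
  rat[wrong] <- vapply(rat[wrong], function(x)
    sample(setdiff(RECIST_CATEGORIES, x), 1), "")
  res <- accuracy_ci(response_confusion(data.frame(reference = ref, rater = rat)))
  expect_equal(res$accuracy, 23 / 31, tolerance = 1e-12)
  # independent exact oracle: Clopper-Pearson bounds via beta quantiles
  lo <- qbeta(0.025, 23, 31 - 23 + 1)
  hi <- qbeta(0.975, 23 + 1, 31 - 23)
  expect_equal(res$ci, c(lo, hi), tolerance = 1e-9)

  perfect <- accuracy_ci(response_confusion(data.frame(reference = ref, rater = ref)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$ci[2], 1)

  # interval width shrinks with n at fixed proportion
  widths <- vapply(c(20, 80, 320), function(n) {
    m <- matrix(0, 4, 4); m[1, 1] <- n / 2; m[2, 1] <- n / 2
    ci <- accuracy_ci(m)$ci
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(accuracy_ci(matrix(0, 4, 4)), "empty")
})

test_that("kappa matches direct evaluation, the e1071 cross-check, and edge cases", {
  set.seed(121)
  ref <- sample(RECIST_CATEGORIES, 60, TRUE)
  rat <- ifelse(runif(60) < 0.6, ref, sample(RECIST_CATEGORIES, 60, TRUE))
  pairs <- data.frame(reference = ref, rater = rat)
  res <- cohen_kappa_ci(pairs)
  expect_equal(res$kappa, oracle_kappa(ref, rat), tolerance = 1e-12)
  expect_true(res$ci[1] <= res$kappa && res$kappa <= res$ci[2])
  skip_if_not_installed("e1071")
  expect_equal(res$kappa,
               e1071::classAgreement(table(ref, rat))$kappa, tolerance = 1e-9)
})

test_that("kappa is 1 on perfect agreement, below chance on a derangement, 0 for constant disagreement", {
  mixed <- data.frame(reference = rep(RECIST_CATEGORIES, 3),
                      rater = rep(RECIST_CATEGORIES, 3))
  expect_equal(cohen_kappa_ci(mixed)$kappa, 1)

  # cyclic derangement over balanced labels: po = 0, pe = 1/4, kappa = -1/3
  ref <- rep(RECIST_CATEGORIES, each = 2)
  rot <- c(PR = "SD", SD = "PD", PD = "CR", CR = "PR")
  der <- data.frame(reference = ref, rater = unname(rot[ref]))
  expect_equal(cohen_kappa_ci(der)$kappa, -1 / 3, tolerance = 1e-12)

  # two constant, different raters: po = 0 and pe = 0 give kappa 0
  const <- data.frame(reference = rep("SD", 6), rater = rep("PD", 6))
  expect_equal(cohen_kappa_ci(const)$kappa, 0)

  # two constant identical raters: degenerate, kappa defined as 1
  expect_warning(
    degen <- cohen_kappa_ci(data.frame(reference = rep("SD", 6),
                                       rater = rep("SD", 6))),
    "degenerate")
  expect_equal(degen$kappa, 1)
})

test_that("kappa is invariant under a relabeling applied to both raters", {
  set.seed(131)
  ref <- sample(RECIST_CATEGORIES, 40, TRUE)
  rat <- sample(RECIST_CATEGORIES, 40, TRUE)
  relab <- c(CR = "PD", PR = "SD", SD = "PR", PD = "CR")
  k1 <- cohen_kappa_ci(data.frame(reference = ref, rater = rat))$kappa
  k2 <- cohen_kappa_ci(data.frame(reference = unname(relab[ref]),
                                  rater = unname(relab[rat])))$kappa
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("ordinal AUC equals exhaustive pair counting", {
  # perfect rater on mixed classes
  perfect <- data.frame(reference = c("CR", "PR", "SD", "PD", "PR", "PD"),
                        rater = c("CR", "PR", "SD", "PD", "PR", "PD"))
  expect_equal(response_auc(perfect), 1)

  # small worked set with a tie across the responder boundary
  worked <- data.frame(reference = c("CR", "PR", "SD", "PD", "PR"),
                       rater = c("CR", "PR", "PD", "PD", "PD"))
  sev <- match(worked$rater, RECIST_CATEGORIES)
  expect_equal(response_auc(worked),
               oracle_auc(sev, worked$reference %in% c("SD", "PD")))
  expect_equal(response_auc(worked), 5 / 6, tolerance = 1e-12)

  set.seed(141)
  for (rep in 1:10) {
    ref <- sample(RECIST_CATEGORIES, 25, TRUE)
    rat <- sample(RECIST_CATEGORIES, 25, TRUE)
    if (length(unique(ref %in% c("SD", "PD"))) < 2) next
    pairs <- data.frame(reference = ref, rater = rat)
    expect_equal(response_auc(pairs),
                 oracle_auc(match(rat, RECIST_CATEGORIES),
                            ref %in% c("SD", "PD")),
                 tolerance = 1e-9)
  }
  expect_error(response_auc(data.frame(reference = rep("SD", 4),
                                       rater = RECIST_CATEGORIES)),
               "AUC undefined")
})

test_that("ordinal AUC is invariant under monotone severity re-mapping", {
  set.seed(151)
  ref <- sample(RECIST_CATEGORIES, 30, TRUE)
  rat <- sample(RECIST_CATEGORIES, 30, TRUE)
  base <- response_auc(data.frame(reference = ref, rater = rat))
  # severity ranks 1,2,3,4 -> 1,5,6,40 (strictly monotone) leaves pair
  # orderings, hence the concordance, unchanged
  mono <- c(1, 5, 6, 40)[match(rat, RECIST_CATEGORIES)]
  expect_equal(base, oracle_auc(mono, ref %in% c("SD", "PD")), tolerance = 1e-9)
})

test_that("macro one-vs-rest mode averages per-category discrimination", {
  perfect <- data.frame(reference = rep(RECIST_CATEGORIES, 4),
                        rater = rep(RECIST_CATEGORIES, 4))
  expect_equal(response_auc(perfect, mode = "macro_ovr"), 1)
  expect_error(response_auc(data.frame(reference = rep("PD", 4),
                                       rater = rep("PD", 4)),
                            mode = "macro_ovr"), "AUC undefined")
})

test_that("agreement_summary is internally consistent", {
  set.seed(161)
  ref <- sample(RECIST_CATEGORIES, 40, TRUE)
  rat <- ifelse(runif(40) < 0.7, ref, sample(RECIST_CATEGORIES, 40, TRUE))
  s <- agreement_summary(data.frame(reference = ref, rater = rat))
  expect_equal(s$accuracy$accuracy, sum(diag(s$confusion)) / sum(s$confusion))
  expect_true(s$kappa$ci[1] <= s$kappa$kappa & s$kappa$kappa <= s$kappa$ci[2])
  expect_true(s$auc >= 0 && s$auc <= 1)
})
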