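test_that("conformal p-values follow the rank-counting formula", {
  # calibration scores {0.1, 0.2, 0.3}, query score 0.25:
  # (#{>= 0.25} + 1) / (3 + 1) = (1 + 1) / 4 = 0.5
  expect_equal(toxtriage:::p_value_from_scores(0.25, c(0.1, 0.2, 0.3)), 0.5)
  # score above all calibration scores -> 1 / (n + 1)
  expect_equal(toxtriage:::p_value_from_scores(0.9, c(0.1, 0.2, 0.3)), 0.25)
  # score below all -> 1
  expect_equal(toxtriage:::p_value_from_scores(0.05, c(0.1, 0.2, 0.3)), 1)
  # ties count as greater-or-equal
  expect_equal(toxtriage:::p_value_from_scores(0.2, c(0.1, 0.2, 0.3)), 0.75)
})

test_that("label assignment applies the prediction-set inclusion rule", {
  expect_equal(assign_label(0.750, 0.003, 0.8), "negative")
  expect_equal(assign_label(0.002, 0.836, 0.8), "positive")
  expect_equal(assign_label(0.30, 0.25, 0.8), "uncertain")  # both included
  expect_equal(assign_label(0.05, 0.10, 0.8), "uncertain")  # empty set
  # vectorised
  expect_equal(assign_label(c(0.75, 0.002), c(0.003, 0.836), 0.8),
               c("negative", "positive"))
  # strict inequality at the boundary: p = 1 - level is excluded
  expect_equal(assign_label(0.2, 0.9, 0.8), "positive")
})

test_that("significance and confidence summarise the p-value pair", {
  sc <- significance_confidence(0.750, 0.003)
  expect_equal(sc$significance, 0.997)
  expect_equal(sc$confidence_pct, 75.0)
  sc2 <- significance_confidence(0.910, 0.003)
  expect_equal(sc2$significance, 0.997)
  expect_equal(sc2$confidence_pct, 91.0)
  sc3 <- significance_confidence(0.5, 0.5)
  expect_equal(sc3$significance, 0.5)
  expect_equal(sc3$confidence_pct, 50.0)
})

test_that("majority voting counts prediction-set membership", {
  expect_equal(ensemble_vote(c("positive", "positive", "negative")),
               "positive")
  expect_equal(ensemble_vote(c("positive", "negative", "uncertain")),
               "uncertain")  # 2-2 tie
  expect_equal(ensemble_vote(c("negative", "negative", "negative")),
               "negative")
  # explicit prediction sets: an empty set votes for neither class
  expect_equal(ensemble_vote(list("1", character(0), character(0))),
               "positive")
  expect_equal(ensemble_vote(list(c("0", "1"), "0", "1")), "uncertain")
  # permutation invariance
  set.seed(5)
  labs <- c("positive", "negative", "uncertain", "positive", "negative")
  for (k in 1:10) {
    expect_equal(ensemble_vote(sample(labs)), ensemble_vote(labs))
  }
})

test_that("metrics separate coverage from definite-only accuracy", {
  # all definite and correct
  m <- toxtriage:::metrics_from_predictions(
    c("positive", "negative"), c(1L, 0L))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$conformal_coverage, 1)
  expect_equal(m$conformal_accuracy, 1)
  # 8 queries, 5 definite, TP=2 TN=2 FP=1 FN=0:
  # coverage 5/8; MCC = (2*2 - 1*0) / sqrt(3*2*3*2) = 4/6
  lab <- c("positive", "positive", "negative", "negative", "positive",
           "uncertain", "uncertain", "uncertain")
  y <- c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L)
  m2 <- toxtriage:::metrics_from_predictions(lab, y)
  expect_equal(m2$conformal_coverage, 0.625)
  expect_equal(m2$mcc, 4 / 6)
  expect_equal(m2$conformal_accuracy, 4 / 5)
  # all uncertain: coverage 0, everything else undefined
  m3 <- toxtriage:::metrics_from_predictions(rep("uncertain", 3),
                                             c(1L, 0L, 1L))
  expect_equal(m3$conformal_coverage, 0)
  expect_true(is.na(m3$conformal_accuracy))
  expect_true(is.na(m3$mcc))
})

test_that("fitting is seed-deterministic and guards its preconditions", {
  ds <- generate_binary_structure_dataset(25, 25, noise = 0.1, seed = 3)
  m1 <- fit_conformal(ds, seed = 11, num_trees = 100L)
  m2 <- fit_conformal(ds, seed = 11, num_trees = 100L)
  expect_identical(m1$calibration, m2$calibration)
  q <- generate_binary_structure_dataset(5, 5, noise = 0.1, seed = 4)
  expect_identical(predict(m1, q[, c("cas", "smiles")]),
                   predict(m2, q[, c("cas", "smiles")]))
  # one-class input is refused
  one <- ds[ds$y == 1L, ]
  expect_error(fit_conformal(one, num_trees = 50L), "per class")
})

test_that("the ensemble pipeline predicts via member voting", {
  ds <- generate_binary_structure_dataset(45, 15, noise = 0.1, seed = 6)
  part <- partition_ensemble(ds, seed = 2)
  ens <- fit_conformal_ensemble(part, seed = 7, num_trees = 100L)
  expect_length(ens$members, 3L)
  q <- generate_binary_structure_dataset(10, 10, noise = 0.1, seed = 8)
  pred <- predict(ens, q[, c("cas", "smiles")])
  expect_setequal(setdiff(unique(pred$label),
                          c("positive", "negative", "uncertain")),
                  character(0))
  expect_true(all(pred$significance >= 0 & pred$significance <= 1))
  expect_true(all(pred$confidence_pct >= 0 & pred$confidence_pct <= 100))
})
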