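test_that("candidate ranking orders by significance, then confidence, then CAS", {
  preds <- data.frame(
    cas = c("94-47-3", "107-36-8", "513-42-8", "2210-25-5"),
    label = "negative",
    significance = c(0.978, 0.997, 0.997, 0.997),
    confidence_pct = c(42.4, 75.0, 91.0, 84.9)
  )
  r <- rank_candidates(preds, "negative")
  # higher significance first; equal significance ranked by confidence
  expect_equal(r$cas, c("513-42-8", "2210-25-5", "107-36-8", "94-47-3"))
  # full ties break on CAS ascending for reproducibility
  ties <- data.frame(cas = c("b", "a"), label = "positive",
                     significance = 0.9, confidence_pct = 50)
  expect_equal(rank_candidates(ties, "positive")$cas, c("a", "b"))
  expect_equal(nrow(rank_candidates(preds, "positive")), 0L)
})

test_that("validation selection takes top and bottom strata per class", {
  mk <- function(n, label) data.frame(
    cas = sprintf("%03d-00-0", seq_len(n)), label = label,
    significance = seq(0.99, 0.5, length.out = n),
    confidence_pct = seq(99, 50, length.out = n)
  )
  sel <- select_validation_set(rank_candidates(mk(25, "positive"), "positive"),
                               rank_candidates(mk(25, "negative"), "negative"))
  expect_equal(nrow(sel), 40L)
  expect_equal(sum(sel$stratum == "top"), 20L)
  expect_equal(sum(sel$stratum == "bottom"), 20L)
  # a class with 12 entries: strata overlap is deduplicated -> all 12
  sel2 <- select_validation_set(rank_candidates(mk(12, "positive"), "positive"),
                                mk(3, "negative")[0, ])
  expect_equal(nrow(sel2), 12L)
  expect_false(any(duplicated(sel2$cas)))
  # n = 0 selects nothing
  expect_equal(nrow(select_validation_set(mk(5, "positive"),
                                          mk(5, "negative"), n = 0L)), 0L)
})

test_that("assay combination is OR for CMR and AND for PBT", {
  expect_equal(combine_assays("CMR", c(carcinogenicity = TRUE,
                                       micronucleus = FALSE,
                                       reprotoxicity = TRUE)), "positive")
  expect_equal(combine_assays("CMR", c(FALSE, FALSE, FALSE)), "negative")
  # a positive decides OR even with gaps; a gap otherwise blocks it
  expect_equal(combine_assays("CMR", c(TRUE, NA, NA)), "positive")
  expect_equal(combine_assays("CMR", c(FALSE, NA, FALSE)), "incomplete")
  expect_equal(combine_assays("PBT", c(persistent = TRUE,
                                       bioaccumulative = FALSE,
                                       toxic = TRUE)), "negative")
  expect_equal(combine_assays("PBT", c(TRUE, TRUE, TRUE)), "positive")
  # AND needs all three observed unless a negative already decides it
  expect_equal(combine_assays("PBT", c(TRUE, NA, TRUE)), "incomplete")
  expect_equal(combine_assays("PBT", c(FALSE, NA, NA)), "negative")
})

test_that("assay combination is monotone in added evidence", {
  set.seed(31)
  for (k in 1:50) {
    base <- sample(c(TRUE, FALSE, NA), 3, replace = TRUE)
    # CMR: adding a positive outcome never flips positive -> negative
    before <- combine_assays("CMR", base)
    after <- combine_assays("CMR", c(base, TRUE))
    expect_equal(after, "positive")
    if (before == "positive") expect_equal(after, "positive")
    # PBT: adding a negative outcome can never yield positive
    after_pbt <- combine_assays("PBT", c(base, FALSE))
    expect_equal(after_pbt, "negative")
  }
})

test_that("prediction/experiment comparison stratifies and keeps incompletes", {
  preds <- data.frame(
    cas = c("104-75-6", "877-38-3", "5502-75-0", "999-99-5"),
    label = c("positive", "positive", "negative", "positive"),
    confidence_pct = c(90, 85, 40, 70)
  )
  exper <- data.frame(
    cas = c("104-75-6", "877-38-3", "5502-75-0", "111-11-6"),
    outcome = c("positive", "incomplete", "positive", "negative")
  )
  cmp <- compare_predictions(exper, preds)
  tab <- cmp$table
  expect_equal(tab$result[tab$cas == "104-75-6"], "agreement")
  # incomplete experiments are not disagreements
  expect_equal(tab$result[tab$cas == "877-38-3"], "incomplete")
  expect_equal(tab$result[tab$cas == "5502-75-0"], "disagreement")
  expect_equal(tab$stratum[tab$cas == "104-75-6"], "high")
  expect_equal(tab$stratum[tab$cas == "5502-75-0"], "low")
  expect_setequal(cmp$unmatched, c("111-11-6", "999-99-5"))
  high <- cmp$summary[cmp$summary$stratum == "high", ]
  expect_equal(high$agreements, 1L)
  expect_equal(high$disagreements, 0L)
  expect_equal(high$incompletes, 1L)
})
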