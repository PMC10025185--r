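test_that("accounting percentages recompute exactly from integer counts", {
  before <- c(YES = 10L, NO = 5L, Pending = 2L, NoInformation = 83L)
  preds <- data.frame(
    label = c(rep("positive", 20), rep("negative", 30), rep("uncertain", 10)),
    confidence_pct = c(rep(90, 5), rep(60, 15), rep(85, 10), rep(40, 20),
                       rep(NA, 10)),
    new = TRUE
  )
  rep <- account(before, preds)
  expect_equal(rep$coverage_pct, round(100 * 50 / 60, 2))
  expect_equal(rep$filled_pct, round(100 * 50 / 83, 2))
  expect_equal(rep$filled_highconf_pct, round(100 * 15 / 83, 2))
  expect_equal(rep$positive_share_pct, round(100 * 20 / 50, 2))
  # order-invariance over prediction rows
  set.seed(2)
  rep2 <- account(before, preds[sample.int(nrow(preds)), ])
  expect_equal(rep2$filled_pct, rep$filled_pct)
  expect_equal(rep2$coverage_pct, rep$coverage_pct)
  # empty prediction table: ratios are zero, not NaN
  rep0 <- account(before, preds[0, ])
  expect_equal(rep0$filled_pct, 0)
  expect_equal(rep0$coverage_pct, 0)
})

test_that("the high-confidence stratum is inclusive at the threshold", {
  before <- c(YES = 0L, NO = 0L, Pending = 0L, NoInformation = 10L)
  preds <- data.frame(label = c("positive", "positive"),
                      confidence_pct = c(80, 79.99), new = TRUE)
  rep <- account(before, preds, threshold_pct = 80)
  expect_equal(rep$new_highconf, 1L)
})

test_that("tally expansion reproduces every determined percentage", {
  preds <- predictions_from_tally(
    total = 3312, positive = 1423, negative = 813,
    new_positive = 691, new_negative = 505,
    highconf_new_positive = 119, highconf_new_negative = 3)
  expect_equal(nrow(preds), 3312L)
  before <- c(YES = 1362L, NO = 477L, Pending = 39L, NoInformation = 2756L)
  rep <- account(before, preds)
  expect_equal(rep$predicted_uncertain, 1076L)
  expect_equal(rep$new_definite, 1196L)
  expect_equal(rep$new_highconf, 122L)
  expect_equal(rep$coverage_pct, round(100 * 2236 / 3312, 2))
  expect_error(predictions_from_tally(10, 8, 5, 1, 1, 0, 0))
})

test_that("annotated share uses the 4-slots-per-compound universe", {
  sh <- annotated_share(9156, 4634)
  expect_equal(sh$total_possible, 18536L)
  expect_equal(sh$annotated_share_pct, round(100 * 9156 / 18536, 2))
  expect_equal(annotated_share(0, 10)$annotated_share_pct, 0)
})

test_that("merging predictions never touches integrated labels", {
  labels <- data.frame(
    cas = rep(c("64-17-5", "71-43-2", "71-36-3"), each = 4),
    endpoint = rep(ENDPOINTS, 3),
    value = "NoInformation", provenance = "integrated",
    stringsAsFactors = FALSE
  )
  labels$value[labels$cas == "64-17-5" & labels$endpoint == "CMR"] <- "YES"
  preds <- data.frame(
    cas = c("64-17-5", "71-43-2", "71-36-3"),
    label = c("negative", "positive", "uncertain"),
    confidence_pct = c(95, 90, NA)
  )
  merged <- merge_predictions(labels, preds, "CMR")
  # the integrated YES survives a contradictory prediction
  expect_equal(
    merged$value[merged$cas == "64-17-5" & merged$endpoint == "CMR"], "YES")
  expect_equal(
    merged$provenance[merged$cas == "64-17-5" & merged$endpoint == "CMR"],
    "integrated")
  # the definite prediction fills its NoInformation slot
  expect_equal(
    merged$value[merged$cas == "71-43-2" & merged$endpoint == "CMR"], "YES")
  expect_equal(
    merged$provenance[merged$cas == "71-43-2" & merged$endpoint == "CMR"],
    "predicted")
  # uncertain predictions fill nothing
  expect_equal(
    merged$value[merged$cas == "71-36-3" & merged$endpoint == "CMR"],
    "NoInformation")
  # a confidence cutoff can restrict the merge
  merged80 <- merge_predictions(labels, preds, "CMR", min_confidence = 99)
  expect_equal(
    merged80$value[merged80$cas == "71-43-2" & merged80$endpoint == "CMR"],
    "NoInformation")
})

test_that("uninformed prediction routes failures with reasons", {
  reg <- registry()
  reg <- register_substance(reg, "64-17-5", "ethanol", "CCO")
  reg <- register_substance(reg, "7647-14-5", "salt", "[Na+].[Cl-]")
  reg <- register_substance(reg, "1310-73-2", "no structure")
  curation <- curate_registry(reg)
  report <- select_modelable(curation)
  labels <- integrate_all(reg, NULL)
  ds <- generate_binary_structure_dataset(20, 20, noise = 0, seed = 5)
  model <- fit_conformal(ds, num_trees = 50L, seed = 1)
  out <- predict_uninformed(labels, curation, report, model, "CMR")
  expect_equal(out$predictions$cas, "64-17-5")
  expect_equal(out$predictions$provenance, "predicted")
  expect_setequal(out$failures$reason[out$failures$cas == "1310-73-2"],
                  "no_structure")
  expect_setequal(out$failures$reason[out$failures$cas == "7647-14-5"],
                  "discarded_category")
})
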