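test_that("hazard codes map to endpoints; unknown codes map to nothing", {
  expect_equal(map_hazard_to_endpoint("ECHA_CLP", "H350"), "CMR")
  expect_equal(map_hazard_to_endpoint("ECHA_REACH", "PBT_Annex_XIII"), "PBT")
  expect_equal(map_hazard_to_endpoint("PHAROS", "ED"), "ED")
  expect_length(map_hazard_to_endpoint("ECHA_CLP", "X999"), 0L)
})

test_that("the label decision workflow honours its five precedence cases", {
  one <- function(...) integrate_endpoint_label(rbind(...))
  # ECHA-core positive -> YES
  expect_equal(one(ann_row("x", "ECHA_CLP", "H350", "positive")), "YES")
  # dossier-only positive -> Pending
  expect_equal(one(ann_row("x", "ECHA_REGDOSSIER", "H350", "positive")),
               "Pending")
  # no annotation -> NoInformation
  expect_equal(integrate_endpoint_label(NULL), "NoInformation")
  # Pharos negative -> NO
  expect_equal(one(ann_row("x", "PHAROS", "CMR", "negative")), "NO")
  # ECHA-core positive beats a Pharos negative
  expect_equal(one(ann_row("x", "PHAROS", "CMR", "negative"),
                   ann_row("x", "ECHA_CLP", "H350", "positive")), "YES")
  # reference database sits between the dossier tier and Pharos
  expect_equal(one(ann_row("x", "REFERENCE_DB", "CMR", "negative"),
                   ann_row("x", "PHAROS", "CMR", "positive")), "NO")
  # within a tier, positive beats negative (conservative)
  expect_equal(one(ann_row("x", "PHAROS", "CMR", "negative"),
                   ann_row("x", "PHAROS", "CMR", "positive")), "YES")
})

test_that("integration is total, order-invariant and idempotent", {
  reg <- tiny_registry()
  ann <- rbind(
    ann_row("64-17-5", "ECHA_CLP", "H350", "positive"),
    ann_row("64-17-5", "PHAROS", "PBT", "negative"),
    ann_row("71-43-2", "ECHA_REGDOSSIER", "H340", "positive"),
    ann_row("127-09-3", "PHAROS", "ED", "positive")
  )
  lab <- integrate_all(reg, ann)
  expect_equal(nrow(lab), 4L * nrow(reg$substances))
  expect_equal(lab$value[lab$cas == "64-17-5" & lab$endpoint == "CMR"], "YES")
  expect_equal(lab$value[lab$cas == "64-17-5" & lab$endpoint == "PBT"], "NO")
  expect_equal(lab$value[lab$cas == "71-43-2" & lab$endpoint == "CMR"],
               "Pending")
  expect_equal(lab$value[lab$cas == "127-09-3" & lab$endpoint == "ED"], "YES")
  # permuting annotation rows changes nothing
  set.seed(1)
  for (k in 1:5) {
    lab2 <- integrate_all(reg, ann[sample.int(nrow(ann)), ])
    expect_equal(lab2$value, lab$value)
  }
  # idempotence: integrating again from the same inputs is a no-op
  expect_equal(integrate_all(reg, ann)$value, lab$value)
  # no annotations at all -> every slot NoInformation
  lab0 <- integrate_all(reg, NULL)
  expect_true(all(lab0$value == "NoInformation"))
})

test_that("annotations for unknown CAS are rejected, not dropped silently", {
  reg <- tiny_registry()
  ann <- rbind(ann_row("64-17-5", "ECHA_CLP", "H350", "positive"),
               ann_row("50-78-2", "ECHA_CLP", "H350", "positive"))
  lab <- integrate_all(reg, ann)
  rej <- attr(lab, "rejects")
  expect_equal(rej$cas, "50-78-2")
  expect_error(integrate_all(reg, ann_row("64-17-5", "BOGUS", "H350",
                                          "positive")),
               "unknown annotation sources")
})

test_that("adding an ECHA-core positive only ever moves labels toward YES", {
  reg <- tiny_registry()
  base_anns <- list(
    NULL,
    ann_row("64-17-5", "PHAROS", "CMR", "negative"),
    ann_row("64-17-5", "ECHA_REGDOSSIER", "H350", "positive"),
    ann_row("64-17-5", "REFERENCE_DB", "CMR", "negative")
  )
  boost <- ann_row("64-17-5", "ECHA_CLP", "H350", "positive")
  rank <- c(NoInformation = 0, NO = 0, Pending = 1, YES = 2)
  for (ann in base_anns) {
    before <- integrate_all(reg, ann)
    after <- integrate_all(reg, rbind(ann, boost))
    v_b <- before$value[before$cas == "64-17-5" & before$endpoint == "CMR"]
    v_a <- after$value[after$cas == "64-17-5" & after$endpoint == "CMR"]
    expect_equal(v_a, "YES")
    expect_gte(rank[[v_a]], rank[[v_b]])
  }
})
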