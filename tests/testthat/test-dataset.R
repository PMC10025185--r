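make_labelled_fixture <- function() {
  reg <- registry()
  smiles <- c("CCO", "c1ccccc1", "CCCCO", "CC(=O)O", "CCN", "Oc1ccccc1")
  cas <- c("64-17-5", "71-43-2", "71-36-3", "64-19-7", "75-04-7", "108-95-2")
  for (i in seq_along(cas)) {
    reg <- register_substance(reg, cas[i], paste0("s", i), smiles[i])
  }
  report <- select_modelable(curate_registry(reg))
  labels <- data.frame(
    cas = rep(cas, each = 4),
    endpoint = rep(ENDPOINTS, 6),
    value = "NoInformation", provenance = "integrated",
    stringsAsFactors = FALSE
  )
  set_label <- function(labels, cas, ep, v) {
    labels$value[labels$cas == cas & labels$endpoint == ep] <- v
    labels
  }
  labels <- set_label(labels, "64-17-5", "CMR", "YES")
  labels <- set_label(labels, "71-43-2", "CMR", "Pending")
  labels <- set_label(labels, "71-36-3", "CMR", "NO")
  labels <- set_label(labels, "64-17-5", "PBT", "Pending")
  labels <- set_label(labels, "71-43-2", "PBT", "YES")
  labels <- set_label(labels, "64-17-5", "ED", "YES")
  list(labels = labels, report = report, cas = cas)
}

test_that("training extraction applies the endpoint-specific Pending policy", {
  fx <- make_labelled_fixture()
  cmr <- extract_training_set(fx$labels, fx$report, "CMR")
  # Pending coded positive for CMR
  expect_equal(cmr$training$y[cmr$training$cas == "71-43-2"], 1L)
  expect_equal(cmr$training$y[cmr$training$cas == "64-17-5"], 1L)
  expect_equal(cmr$training$y[cmr$training$cas == "71-36-3"], 0L)
  # NoInformation substances only ever appear in the prediction set
  expect_false(any(cmr$prediction$cas %in% cmr$training$cas))
  expect_true("64-19-7" %in% cmr$prediction$cas)
  # Pending excluded from both sets for PBT
  pbt <- extract_training_set(fx$labels, fx$report, "PBT")
  expect_false("64-17-5" %in% pbt$training$cas)
  expect_false("64-17-5" %in% pbt$prediction$cas)
})

test_that("an endpoint with an empty class is flagged unmodelable toward read-across", {
  fx <- make_labelled_fixture()
  ed <- extract_training_set(fx$labels, fx$report, "ED")
  expect_false(ed$modelable)
  expect_match(ed$reason, "read-across")
})

test_that("oversampling doubles the minority class exactly once", {
  df <- data.frame(cas = as.character(1:25), smiles = "CCO",
                   y = rep(c(1L, 0L), c(5L, 20L)))
  out <- oversample(df)
  expect_equal(sum(out$y == 1L), 10L)
  expect_equal(sum(out$y == 0L), 20L)
  # additions are copies of existing minority records
  added <- out[26:30, ]
  expect_true(all(added$cas %in% df$cas[df$y == 1L]))
  expect_equal(sort(table(out$cas[out$y == 1L])), sort(rep(2L, 5L)),
               ignore_attr = TRUE)
  # balanced input returned unchanged
  bal <- data.frame(cas = as.character(1:10), smiles = "CCO",
                    y = rep(c(0L, 1L), 5))
  expect_message(out2 <- oversample(bal), "balanced")
  expect_equal(out2, bal)
  expect_error(oversample(data.frame(cas = "1", smiles = "CCO", y = 1L)),
               "non-empty")
})

test_that("ensemble partition: all negatives everywhere, balanced, positives covered", {
  base <- function(n_pos, n_neg) data.frame(
    cas = as.character(seq_len(n_pos + n_neg)), smiles = "CCO",
    y = rep(c(1L, 0L), c(n_pos, n_neg))
  )
  # 9 pos / 3 neg in 3 subsets: exact chunking
  p <- partition_ensemble(base(9, 3), seed = 4)
  expect_length(p$subsets, 3L)
  pos_union <- character(0)
  for (s in p$subsets) {
    expect_equal(sum(s$y == 0L), 3L)
    expect_equal(sum(s$y == 1L), 3L)
    expect_setequal(s$cas[s$y == 0L], as.character(10:12))
    expect_false(any(duplicated(s$cas)))
    pos_union <- union(pos_union, s$cas[s$y == 1L])
  }
  expect_setequal(pos_union, as.character(1:9))
  # 6 pos / 3 neg: still 3 balanced subsets, union covers all with overlap
  p2 <- partition_ensemble(base(6, 3), seed = 4)
  expect_setequal(unique(unlist(lapply(p2$subsets, function(s)
    s$cas[s$y == 1L]))), as.character(1:6))
  # positives <= negatives: partitioning is unnecessary
  expect_error(partition_ensemble(base(3, 5)), "unnecessary")
})

test_that("ensemble partition is deterministic in (dataset, seed)", {
  df <- data.frame(cas = as.character(1:40), smiles = "CCO",
                   y = rep(c(1L, 0L), c(30L, 10L)))
  p1 <- partition_ensemble(df, seed = 9)
  p2 <- partition_ensemble(df, seed = 9)
  expect_identical(p1, p2)
  p3 <- partition_ensemble(df, seed = 10)
  expect_false(identical(p1$subsets, p3$subsets))
})

test_that("partition invariants hold over randomized imbalanced datasets", {
  set.seed(123)
  for (case in 1:100) {
    n_neg <- sample(2:8, 1)
    n_pos <- n_neg + sample(1:20, 1)
    df <- data.frame(cas = as.character(seq_len(n_pos + n_neg)),
                     smiles = "CCO",
                     y = rep(c(1L, 0L), c(n_pos, n_neg)))
    p <- partition_ensemble(df, seed = case)
    union_pos <- character(0)
    for (s in p$subsets) {
      expect_equal(sum(s$y == 0L), n_neg)
      expect_equal(sum(s$y == 1L), n_neg)
      expect_false(any(duplicated(s$cas)))
      union_pos <- union(union_pos, s$cas[s$y == 1L])
    }
    expect_setequal(union_pos, df$cas[df$y == 1L])
  }
})
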