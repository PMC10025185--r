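# Mondrian (class-conditional) inductive conformal classification over
# random forests: per-class p-values, prediction-set label assignment,
# significance/confidence reporting, majority-vote ensembling and conformal
# quality metrics.

#' Fit a Mondrian inductive conformal random-forest classifier
#'
#' The training data are split (stratified, seed-deterministic) into a
#' proper-training part used to grow the forest and a calibration part used
#' for the conformal machinery. The nonconformity score of a record for
#' class `c` is `1 - p_hat(c | x)`, the forest's estimated probability of
#' that class subtracted from one. Calibration scores are stored per class
#' (Mondrian calibration), which yields the per-class p-values `p0`/`p1`
#' reported downstream and class-conditional validity: at significance level
#' `s`, at most `1 - s` of true labels are excluded from the prediction set,
#' per class, up to finite-sample noise.
#'
#' @param dataset a `tox_binary_dataset` or data frame with columns `cas`,
#'   `smiles`, `y` (0/1).
#' @param level default significance level used by [predict.tox_conformal_rf()]
#'   (fraction in (0,1); the regulatory default is 0.8, i.e. at most 20%
#'   errors).
#' @param num_trees random-forest size (default 500).
#' @param calib_frac fraction of records held out for calibration
#'   (default 0.3).
#' @param min_per_class minimum records per class (default 10).
#' @param mtry features per split; default `floor(sqrt(ncol))`.
#' @param seed integer seed controlling the split and the forest.
#' @return an object of class `tox_conformal_rf`: the fitted forest, sorted
#'   per-class calibration score lists, the fingerprint dialect, the seed
#'   and the default level.
#' @export
fit_conformal <- function(dataset, level = 0.8, num_trees = 500L,
                          calib_frac = 0.3, min_per_class = 10L,
                          mtry = NULL, seed = 1L) {
  df <- if (inherits(dataset, "tox_binary_dataset")) dataset$training
        else dataset
  stopifnot(all(df$y %in% c(0L, 1L)), level > 0, level < 1)
  n1 <- sum(df$y == 1L)
  n0 <- sum(df$y == 0L)
  if (n1 < min_per_class || n0 < min_per_class) {
    stop("need >= ", min_per_class, " records per class (have ",
         n0, " / ", n1, ")", call. = FALSE)
  }
  x <- fingerprint_matrix(df$smiles)
  if (length(attr(x, "failed"))) {
    stop("unfeaturizable training structures at rows: ",
         paste(attr(x, "failed"), collapse = ", "), call. = FALSE)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  calib_idx <- unlist(lapply(c(0L, 1L), function(cls) {
    idx <- which(df$y == cls)
    take <- max(1L, round(calib_frac * length(idx)))
    idx[sample.int(length(idx), take)]
  }))
  proper_idx <- setdiff(seq_len(nrow(df)), calib_idx)
  if (length(unique(df$y[calib_idx])) < 2L ||
      length(unique(df$y[proper_idx])) < 2L) {
    stop("a class is absent from the proper-training or calibration split",
         call. = FALSE)
  }

  colnames(x) <- paste0("b", seq_len(ncol(x)))
  fit_df <- data.frame(y = factor(df$y[proper_idx], levels = c("0", "1")),
                       x[proper_idx, , drop = FALSE])
  forest <- ranger::ranger(
    y ~ ., data = fit_df, probability = TRUE, num.trees = num_trees,
    mtry = if (is.null(mtry)) floor(sqrt(ncol(x))) else mtry,
    seed = seed, num.threads = 1L
  )
  calib_prob <- stats::predict(
    forest, data.frame(x[calib_idx, , drop = FALSE]),
    num.threads = 1L)$predictions
  # nonconformity of each calibration record for its own class
  y_cal <- df$y[calib_idx]
  alpha <- 1 - calib_prob[cbind(seq_along(calib_idx),
                                match(as.character(y_cal),
                                      colnames(calib_prob)))]
  structure(list(
    forest = forest,
    calibration = list(
      "0" = sort(alpha[y_cal == 0L]),
      "1" = sort(alpha[y_cal == 1L])
    ),
    feature_dialect = attr(x, "dialect"),
    nbits = ncol(x),
    level = level,
    seed = seed,
    n_proper = length(proper_idx),
    n_calibration = length(calib_idx)
  ), class = "tox_conformal_rf")
}

#' @export
print.tox_conformal_rf <- function(x, ...) {
  cat("<tox_conformal_rf> ", x$forest$num.trees, " trees; calibration ",
      length(x$calibration[["0"]]), " neg / ",
      length(x$calibration[["1"]]), " pos; default level ", x$level,
      "\n", sep = "")
  invisible(x)
}

#' Conformal p-values for query structures
#'
#' For a query with class-`c` nonconformity score `a`, the Mondrian p-value
#' is `(#\{calibration scores of class c >= a\} + 1) / (n_c + 1)`, ties
#' counting as greater-or-equal. `p0` and `p1` are the raw per-class
#' p-values (they do not sum to 1).
#'
#' @param bundle a fitted `tox_conformal_rf`.
#' @param smiles character vector of query SMILES.
#' @return data frame with columns `p0`, `p1`.
#' @export
conformal_p_values <- function(bundle, smiles) {
  x <- fingerprint_matrix(smiles, bundle$nbits)
  if (length(attr(x, "failed"))) {
    stop("unfeaturizable query structures at rows: ",
         paste(attr(x, "failed"), collapse = ", "), call. = FALSE)
  }
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  prob <- stats::predict(bundle$forest, data.frame(x),
                         num.threads = 1L)$predictions
  p0 <- p_value_from_scores(1 - prob[, "0"], bundle$calibration[["0"]])
  p1 <- p_value_from_scores(1 - prob[, "1"], bundle$calibration[["1"]])
  data.frame(p0 = p0, p1 = p1)
}

# rank-counting p-value against a sorted calibration list
p_value_from_scores <- function(scores, calibration) {
  n <- length(calibration)
  vapply(scores, function(a)
    (sum(calibration >= a - 1e-12) + 1) / (n + 1), numeric(1))
}

#' Assign a conformal prediction label
#'
#' Class `c` enters the prediction set iff `p_c > 1 - level` (strict
#' inequality). A singleton set gives a definite `positive` or `negative`;
#' both classes in the set ("both") or neither ("empty") give `uncertain`.
#'
#' @param p0,p1 per-class p-values (vectorised).
#' @param level significance level in (0,1), default 0.8.
#' @return character vector in `positive` / `negative` / `uncertain`.
#' @export
assign_label <- function(p0, p1, level = 0.8) {
  stopifnot(level > 0, level < 1)
  # strict inequality at the boundary; the epsilon absorbs the binary
  # representation error of 1 - level (e.g. 1 - 0.8 > 0.2 in doubles)
  eps <- 1e-9
  in0 <- p0 > (1 - level) + eps
  in1 <- p1 > (1 - level) + eps
  ifelse(in1 & !in0, "positive",
         ifelse(in0 & !in1, "negative", "uncertain"))
}

#' Significance and confidence of a conformal prediction
#'
#' Per-prediction reliability summaries: significance is one minus the
#' smaller of the two p-values (how firmly the unlikely class is rejected);
#' confidence is the other (larger) p-value expressed as a percentage.
#'
#' @param p0,p1 per-class p-values (vectorised).
#' @return data frame with columns `significance`, `confidence_pct`.
#' @export
significance_confidence <- function(p0, p1) {
  data.frame(
    significance = 1 - pmin(p0, p1),
    confidence_pct = 100 * pmax(p0, p1)
  )
}

#' Predict with a conformal random forest
#'
#' @param object a `tox_conformal_rf`.
#' @param newdata data frame with columns `cas` and `smiles` (or a character
#'   vector of SMILES).
#' @param level significance level; defaults to the bundle's.
#' @param ... unused.
#' @return data frame `cas`, `p0`, `p1`, `label`, `significance`,
#'   `confidence_pct`.
#' @export
predict.tox_conformal_rf <- function(object, newdata, level = NULL, ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(cas = as.character(seq_along(newdata)),
                          smiles = newdata)
  }
  if (is.null(level)) level <- object$level
  pv <- conformal_p_values(object, newdata$smiles)
  sc <- significance_confidence(pv$p0, pv$p1)
  data.frame(
    cas = newdata$cas, p0 = pv$p0, p1 = pv$p1,
    label = assign_label(pv$p0, pv$p1, level),
    significance = sc$significance, confidence_pct = sc$confidence_pct,
    stringsAsFactors = FALSE
  )
}

#' Fit one conformal forest per balanced ensemble subset
#'
#' @param partition a `tox_ensemble_partition` from [partition_ensemble()].
#' @param ... passed to [fit_conformal()]; each member gets `seed + k - 1`.
#' @param seed base seed.
#' @return an object of class `tox_conformal_ensemble` (list of
#'   `tox_conformal_rf` members).
#' @export
fit_conformal_ensemble <- function(partition, seed = 1L, ...) {
  stopifnot(inherits(partition, "tox_ensemble_partition"))
  members <- lapply(seq_along(partition$subsets), function(k) {
    fit_conformal(partition$subsets[[k]], seed = seed + k - 1L, ...)
  })
  structure(list(members = members, seed = seed),
            class = "tox_conformal_ensemble")
}

#' Majority vote over conformal prediction sets
#'
#' Each model contributes +1 to the count of every class contained in its
#' prediction set: a definite prediction increments one class, a
#' "both-classes" uncertain increments both, an empty set increments
#' neither. Strictly more class-1 votes give `positive`, strictly more
#' class-0 votes give `negative`, equal counts give `uncertain`. The result
#' is invariant to the order of the models.
#'
#' Convenience: `votes` may also be a character vector of labels, in which
#' case `uncertain` is counted as both classes (the set information is no
#' longer available; use prediction sets when you have them).
#'
#' @param votes list of prediction sets (character subsets of
#'   `c("0", "1")`) or a character label vector.
#' @return `"positive"`, `"negative"` or `"uncertain"`.
#' @export
ensemble_vote <- function(votes) {
  if (is.character(votes)) {
    votes <- lapply(votes, function(lbl) switch(lbl,
      positive = "1", negative = "0", uncertain = c("0", "1"),
      stop("unknown label: ", lbl, call. = FALSE)))
  }
  c1 <- sum(vapply(votes, function(v) "1" %in% v, logical(1)))
  c0 <- sum(vapply(votes, function(v) "0" %in% v, logical(1)))
  if (c1 > c0) "positive" else if (c0 > c1) "negative" else "uncertain"
}

#' Predict with a conformal ensemble (majority voting)
#'
#' Members predict independently; their prediction sets are combined with
#' [ensemble_vote()]. The reported `p0`/`p1` (and hence significance and
#' confidence) are the member medians, a summary used only for ranking —
#' the label comes from the vote.
#'
#' @param object a `tox_conformal_ensemble`.
#' @param newdata data frame with `cas`, `smiles` (or character vector).
#' @param level significance level; defaults to the first member's.
#' @param ... unused.
#' @return data frame as [predict.tox_conformal_rf()].
#' @export
predict.tox_conformal_ensemble <- function(object, newdata, level = NULL,
                                           ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(cas = as.character(seq_along(newdata)),
                          smiles = newdata)
  }
  if (is.null(level)) level <- object$members[[1]]$level
  pvs <- lapply(object$members, function(m)
    conformal_p_values(m, newdata$smiles))
  labels <- vapply(seq_len(nrow(newdata)), function(i) {
    sets <- lapply(pvs, function(pv) {
      s <- character(0)
      if (pv$p0[i] > 1 - level) s <- c(s, "0")
      if (pv$p1[i] > 1 - level) s <- c(s, "1")
      s
    })
    ensemble_vote(sets)
  }, character(1))
  p0 <- apply(vapply(pvs, function(pv) pv$p0, numeric(nrow(newdata))), 1,
              stats::median)
  p1 <- apply(vapply(pvs, function(pv) pv$p1, numeric(nrow(newdata))), 1,
              stats::median)
  sc <- significance_confidence(p0, p1)
  data.frame(
    cas = newdata$cas, p0 = p0, p1 = p1, label = labels,
    significance = sc$significance, confidence_pct = sc$confidence_pct,
    stringsAsFactors = FALSE
  )
}

#' @export
print.tox_conformal_ensemble <- function(x, ...) {
  cat("<tox_conformal_ensemble> ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Evaluate a conformal model on a labelled test set
#'
#' Coverage is the fraction of definite (non-uncertain) predictions; the
#' remaining metrics — accuracy, sensitivity, specificity and the Matthews
#' correlation coefficient — are computed over the definite predictions
#' only. With zero definite predictions, coverage is 0 and the other
#' metrics are `NA` (undefined).
#'
#' @param model a `tox_conformal_rf` or `tox_conformal_ensemble`.
#' @param test data frame with columns `cas`, `smiles`, `y`.
#' @param level significance level; defaults to the model's.
#' @return a list of class `tox_model_metrics`: `sensitivity`,
#'   `specificity`, `mcc`, `conformal_coverage`, `conformal_accuracy`,
#'   plus the confusion counts `tp`, `tn`, `fp`, `fn` and `n`.
#' @export
evaluate_conformal <- function(model, test, level = NULL) {
  pred <- stats::predict(model, test[, c("cas", "smiles")], level = level)
  metrics_from_predictions(pred$label, test$y)
}

# shared metric arithmetic, exposed for oracle testing
metrics_from_predictions <- function(label, y) {
  stopifnot(length(label) == length(y))
  definite <- label != "uncertain"
  n <- length(y)
  coverage <- if (n == 0L) NA_real_ else sum(definite) / n
  if (!any(definite)) {
    return(structure(list(
      sensitivity = NA_real_, specificity = NA_real_, mcc = NA_real_,
      conformal_coverage = coverage, conformal_accuracy = NA_real_,
      tp = 0L, tn = 0L, fp = 0L, fn = 0L, n = n
    ), class = "tox_model_metrics"))
  }
  lab <- label[definite]
  yy <- y[definite]
  tp <- sum(lab == "positive" & yy == 1L)
  tn <- sum(lab == "negative" & yy == 0L)
  fp <- sum(lab == "positive" & yy == 0L)
  fn <- sum(lab == "negative" & yy == 1L)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  structure(list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_,
    conformal_coverage = coverage,
    conformal_accuracy = (tp + tn) / (tp + tn + fp + fn),
    tp = tp, tn = tn, fp = fp, fn = fn, n = n
  ), class = "tox_model_metrics")
}

#' @export
print.tox_model_metrics <- function(x, ...) {
  cat(sprintf(
    "<tox_model_metrics> sens %.3f | spec %.3f | MCC %.3f | coverage %.3f | accuracy %.3f (n = %d)\n",
    x$sensitivity, x$specificity, x$mcc, x$conformal_coverage,
    x$conformal_accuracy, x$n))
  invisible(x)
}
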