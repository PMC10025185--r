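# Gap-filling bookkeeping: apply models to uninformed substances, merge
# predicted labels without touching integrated ones, and account for the
# before/after label distribution with and without a confidence cutoff.

#' Predict the uninformed substances of one endpoint
#'
#' Only substances whose integrated label is `NoInformation` are predicted;
#' experimental (integrated) labels are never re-predicted or overwritten.
#' Substances that cannot be predicted are collected in a `failures` table
#' with a reason (`no_structure`, `discarded_category`, `featurize_fail`),
#' never silently dropped.
#'
#' @param labels integrated labels from [integrate_all()].
#' @param curation the raw curation table from [curate_registry()].
#' @param curation_report the [select_modelable()] report.
#' @param model a `tox_conformal_rf` or `tox_conformal_ensemble`.
#' @param endpoint endpoint name.
#' @param level significance level (defaults to the model's).
#' @return list with `predictions` (the [predict.tox_conformal_rf()] table,
#'   provenance `"predicted"`) and `failures` (data frame `cas`, `reason`).
#' @export
predict_uninformed <- function(labels, curation, curation_report, model,
                               endpoint, level = NULL) {
  stopifnot(endpoint %in% ENDPOINTS)
  uninformed <- labels$cas[labels$endpoint == endpoint &
                             labels$value == "NoInformation"]
  kept <- curation_report$kept
  failures <- list()
  for (cas in setdiff(uninformed, kept$cas)) {
    status <- curation$status[curation$cas == cas]
    reason <- if (length(status) && status == "missing") "no_structure"
              else if (length(status) && status == "parse_fail") "featurize_fail"
              else "discarded_category"
    failures[[length(failures) + 1L]] <- data.frame(cas = cas,
                                                    reason = reason)
  }
  todo <- kept[kept$cas %in% uninformed, , drop = FALSE]
  preds <- NULL
  if (nrow(todo)) {
    fps_ok <- vapply(todo$model_smiles, function(s)
      !inherits(tryCatch(fingerprint(s), error = function(e) e), "error"),
      logical(1))
    for (cas in todo$cas[!fps_ok]) {
      failures[[length(failures) + 1L]] <-
        data.frame(cas = cas, reason = "featurize_fail")
    }
    todo <- todo[fps_ok, , drop = FALSE]
    if (nrow(todo)) {
      preds <- stats::predict(
        model, data.frame(cas = todo$cas, smiles = todo$model_smiles),
        level = level)
      preds$provenance <- "predicted"
    }
  }
  if (is.null(preds)) {
    preds <- data.frame(cas = character(), p0 = numeric(), p1 = numeric(),
                        label = character(), significance = numeric(),
                        confidence_pct = numeric(), provenance = character())
  }
  list(
    predictions = preds,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(cas = character(), reason = character())
  )
}

#' Merge predicted labels into an integrated label table
#'
#' Definite predictions fill `NoInformation` slots only; integrated `YES`,
#' `NO` and `Pending` labels are untouchable (provenance separation).
#' Uncertain predictions fill nothing.
#'
#' @param labels integrated label table.
#' @param predictions prediction table with `cas`, `label`, optionally
#'   `confidence_pct`.
#' @param endpoint endpoint the predictions belong to.
#' @param min_confidence optional confidence cutoff (percent); only
#'   predictions at or above it are merged.
#' @return the label table with filled rows set to the predicted value and
#'   provenance `"predicted"` (or `"rax"` if the prediction row carries that
#'   provenance).
#' @export
merge_predictions <- function(labels, predictions, endpoint,
                              min_confidence = NULL) {
  def <- predictions[predictions$label %in% c("positive", "negative"), ,
                     drop = FALSE]
  if (!is.null(min_confidence) && nrow(def)) {
    def <- def[def$confidence_pct >= min_confidence, , drop = FALSE]
  }
  for (r in seq_len(nrow(def))) {
    i <- which(labels$cas == def$cas[r] & labels$endpoint == endpoint)
    if (length(i) != 1L) next
    if (labels$value[i] != "NoInformation") next  # never overwrite
    labels$value[i] <- if (def$label[r] == "positive") "YES" else "NO"
    labels$provenance[i] <- if (!is.null(def$provenance) &&
                                 def$provenance[r] == "rax") "rax"
                            else "predicted"
  }
  labels
}

#' Before/after accounting of gap filling for one endpoint
#'
#' All derived percentages are recomputable from the stored integer counts
#' (the integers are the source of truth; percentages are reported rounded
#' half-up to 2 decimals):
#' * `coverage_pct` — definite predictions / all predictions;
#' * `filled_pct` — definite predictions of previously uninformed substances
#'   / `NoInformation` count before;
#' * `filled_highconf_pct` — same, counting only predictions with
#'   `confidence_pct >= threshold` (inclusive, per the high-confidence
#'   rule);
#' * `positive_share_pct` — positives among the definite new labels.
#'
#' @param before named integer vector of label counts before gap filling
#'   (`YES`, `NO`, `Pending`, `NoInformation`), or an integrated label table
#'   (then tallied for `endpoint`).
#' @param predictions prediction table (`label`, `confidence_pct`, and
#'   logical column `new` marking predictions for previously uninformed
#'   substances; if absent all rows count as new).
#' @param endpoint endpoint name (used when `before` is a label table).
#' @param threshold_pct high-confidence threshold, default 80 (inclusive).
#' @return a list of class `tox_accounting` holding the integer counts and
#'   the derived percentages.
#' @export
account <- function(before, predictions, endpoint = NULL,
                    threshold_pct = 80) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  if (is.data.frame(before)) {
    stopifnot(!is.null(endpoint))
    sel <- before$endpoint == endpoint
    before <- vapply(LABEL_VALUES, function(v)
      sum(before$value[sel] == v), integer(1))
  }
  before <- before[LABEL_VALUES]
  stopifnot(!anyNA(before))
  if (is.null(predictions$new)) predictions$new <- TRUE
  if (is.null(predictions$confidence_pct)) {
    predictions$confidence_pct <- NA_real_
  }

  n_pred <- nrow(predictions)
  definite <- predictions$label %in% c("positive", "negative")
  highconf <- definite & !is.na(predictions$confidence_pct) &
    predictions$confidence_pct >= threshold_pct
  counts <- list(
    before = as.list(before),
    predicted = n_pred,
    predicted_positive = sum(predictions$label == "positive"),
    predicted_negative = sum(predictions$label == "negative"),
    predicted_uncertain = sum(predictions$label == "uncertain"),
    new_definite = sum(definite & predictions$new),
    new_positive = sum(definite & predictions$new &
                         predictions$label == "positive"),
    new_negative = sum(definite & predictions$new &
                         predictions$label == "negative"),
    new_highconf = sum(highconf & predictions$new),
    new_highconf_positive = sum(highconf & predictions$new &
                                  predictions$label == "positive"),
    new_highconf_negative = sum(highconf & predictions$new &
                                  predictions$label == "negative")
  )
  no_info <- before[["NoInformation"]]
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2) else 0
  structure(c(counts, list(
    threshold_pct = threshold_pct,
    coverage_pct = pct(counts$predicted_positive +
                         counts$predicted_negative, n_pred),
    filled_pct = pct(counts$new_definite, no_info),
    filled_highconf_pct = pct(counts$new_highconf, no_info),
    positive_share_pct = pct(counts$new_positive, counts$new_definite)
  )), class = "tox_accounting")
}

#' Reconstruct a row-level prediction table from aggregate tallies
#'
#' Accounting audits often start from published aggregate counts rather than
#' per-substance predictions. This helper expands such tallies into a
#' minimal row-level table consumable by [account()]: rows carry only the
#' fields the accounting uses (`label`, `confidence_pct`, `new`), with
#' high-confidence rows placed at the threshold and the rest safely below
#' it. [account()] run on the expansion reproduces every percentage the
#' tallies determine.
#'
#' @param total total number of predictions.
#' @param positive,negative definite prediction counts (uncertain is the
#'   remainder).
#' @param new_positive,new_negative definite predictions for previously
#'   uninformed substances.
#' @param highconf_new_positive,highconf_new_negative the subset of new
#'   definite predictions at or above the confidence threshold.
#' @param threshold_pct the high-confidence threshold (default 80).
#' @return data frame `label`, `confidence_pct`, `new`.
#' @export
predictions_from_tally <- function(total, positive, negative,
                                   new_positive, new_negative,
                                   highconf_new_positive,
                                   highconf_new_negative,
                                   threshold_pct = 80) {
  uncertain <- total - positive - negative
  stopifnot(uncertain >= 0,
            new_positive <= positive, new_negative <= negative,
            highconf_new_positive <= new_positive,
            highconf_new_negative <= new_negative)
  low <- threshold_pct / 2
  block <- function(label, n_old, n_new_low, n_new_high) {
    data.frame(
      label = rep(label, n_old + n_new_low + n_new_high),
      confidence_pct = c(rep(low, n_old + n_new_low),
                         rep(threshold_pct, n_new_high)),
      new = c(rep(FALSE, n_old), rep(TRUE, n_new_low + n_new_high))
    )
  }
  out <- rbind(
    block("positive", positive - new_positive,
          new_positive - highconf_new_positive, highconf_new_positive),
    block("negative", negative - new_negative,
          new_negative - highconf_new_negative, highconf_new_negative),
    block("uncertain", uncertain, 0L, 0L)
  )
  rownames(out) <- NULL
  out
}

#' Share of possible endpoint annotations that are informative
#'
#' Each substance has one annotation slot per endpoint, so the universe is
#' `4 * n_compounds` slots; the share is the percentage of those slots
#' carrying anything other than `NoInformation`.
#'
#' @param n_annotated number of informative annotations.
#' @param n_compounds number of substances in the registry.
#' @return list with `total_possible` and `annotated_share_pct` (rounded
#'   half-up to 2 decimals).
#' @export
annotated_share <- function(n_annotated, n_compounds) {
  total <- 4L * as.integer(n_compounds)
  list(total_possible = total,
       annotated_share_pct = round(100 * n_annotated / total, 2))
}

#' @export
print.tox_accounting <- function(x, ...) {
  cat("<tox_accounting> before: YES ", x$before$YES, " | NO ", x$before$NO,
      " | Pending ", x$before$Pending, " | NoInformation ",
      x$before$NoInformation, "\n", sep = "")
  cat(sprintf(
    "  predictions %d (pos %d / neg %d / uncertain %d), coverage %.2f%%\n",
    x$predicted, x$predicted_positive, x$predicted_negative,
    x$predicted_uncertain, x$coverage_pct))
  cat(sprintf(
    "  filled %.2f%% of uninformed (%.2f%% at >= %g%% confidence); positive share %.2f%%\n",
    x$filled_pct, x$filled_highconf_pct, x$threshold_pct,
    x$positive_share_pct))
  invisible(x)
}
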