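# Prospective-validation candidate selection and prediction/experiment
# comparison.

#' Rank predictions of one class by reliability
#'
#' Sorted descending by significance, then confidence, with ties broken by
#' CAS ascending, so the ranking is a reproducible total order. Significance
#' is the primary key because it is derived from the smaller p-value (the
#' dominant reliability term); the order is configurable via `by`.
#'
#' @param predictions prediction table with `cas`, `label`, `significance`,
#'   `confidence_pct`.
#' @param predicted_class `"positive"` or `"negative"`.
#' @param by ranking keys, default `c("significance", "confidence_pct")`.
#' @return the filtered, ranked prediction table.
#' @export
rank_candidates <- function(predictions,
                            predicted_class = c("positive", "negative"),
                            by = c("significance", "confidence_pct")) {
  predicted_class <- match.arg(predicted_class)
  df <- predictions[predictions$label == predicted_class, , drop = FALSE]
  if (!nrow(df)) return(df)
  keys <- c(lapply(by, function(k) -df[[k]]), list(df$cas))
  df <- df[do.call(order, keys), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select a prospective validation set
#'
#' Takes the `n` most reliable and the `n` least reliable candidates from
#' each ranked class — the top stratum probes the model where it claims
#' certainty, the bottom stratum stress-tests it where it does not. When a
#' class has `<= 2n` entries the strata overlap and are deduplicated (an
#' entry keeps its `top` stratum).
#'
#' @param ranked_positives,ranked_negatives outputs of [rank_candidates()].
#' @param n candidates per stratum per class (default 10, i.e. up to 20
#'   positives and 20 negatives in total).
#' @return data frame of candidates with an added `stratum` column
#'   (`"top"` / `"bottom"`).
#' @export
select_validation_set <- function(ranked_positives, ranked_negatives,
                                  n = 10L) {
  stopifnot(n >= 0L)
  take <- function(df) {
    m <- nrow(df)
    if (!m || n == 0L) {
      out <- df[0, , drop = FALSE]
      out$stratum <- character(0)
      return(out)
    }
    top_idx <- seq_len(min(n, m))
    bottom_idx <- setdiff(seq(max(1L, m - n + 1L), m), top_idx)
    out <- rbind(
      cbind(df[top_idx, , drop = FALSE], stratum = "top"),
      if (length(bottom_idx))
        cbind(df[bottom_idx, , drop = FALSE], stratum = "bottom")
    )
    rownames(out) <- NULL
    out
  }
  out <- rbind(take(ranked_positives), take(ranked_negatives))
  rownames(out) <- NULL
  out
}

#' Combine experimental assay outcomes into one endpoint conclusion
#'
#' CMR batteries (carcinogenicity, micronucleus, reprotoxicity) combine with
#' a logical OR: any positive assay makes the substance positive. PBT
#' combines persistence, bioaccumulation and toxicity with a logical AND:
#' all three must be positive. Missing outcomes (`NA`) make the conclusion
#' `incomplete` whenever they could still change it: under OR a missing
#' assay matters only if no positive was seen yet; under AND it always
#' matters unless some completed assay is already negative.
#'
#' @param endpoint `"CMR"` or `"PBT"`.
#' @param outcomes named logical vector of assay outcomes (`NA` = not done),
#'   e.g. `c(carcinogenicity = TRUE, micronucleus = FALSE,
#'   reprotoxicity = NA)`.
#' @return `"positive"`, `"negative"` or `"incomplete"`.
#' @export
combine_assays <- function(endpoint, outcomes) {
  endpoint <- match.arg(endpoint, c("CMR", "PBT"))
  stopifnot(is.logical(outcomes), length(outcomes) >= 1L)
  if (endpoint == "CMR") {
    if (any(outcomes %in% TRUE)) return("positive")
    if (anyNA(outcomes)) return("incomplete")
    return("negative")
  }
  # PBT: AND over the three components
  if (any(outcomes %in% FALSE)) return("negative")
  if (anyNA(outcomes)) return("incomplete")
  "positive"
}

#' Compare predictions against experimental conclusions
#'
#' Joined on CAS; an experimental `incomplete` is counted as `incomplete`,
#' not as a disagreement (the prediction can be neither confirmed nor
#' refuted). Predictions are stratified into confidence strata (`high` at or
#' above the threshold, `low` below). CAS present on one side only are
#' reported in `unmatched`, never dropped.
#'
#' @param experimental data frame with `cas`, `outcome`
#'   (`positive`/`negative`/`incomplete`).
#' @param predictions prediction table (`cas`, `label`, `confidence_pct`).
#' @param threshold_pct confidence threshold separating the strata
#'   (default 80, inclusive).
#' @return list with `table` (per-CAS comparison: `cas`, `stratum`,
#'   `predicted`, `experimental`, `result`), `summary` (per-stratum counts
#'   of agreements / disagreements / incompletes) and `unmatched`.
#' @export
compare_predictions <- function(experimental, predictions,
                                threshold_pct = 80) {
  common <- intersect(experimental$cas, predictions$cas)
  unmatched <- c(setdiff(experimental$cas, common),
                 setdiff(predictions$cas, common))
  rows <- lapply(common, function(k) {
    p <- predictions[predictions$cas == k, , drop = FALSE][1, ]
    e <- experimental$outcome[experimental$cas == k][1]
    result <- if (e == "incomplete") "incomplete"
              else if (p$label == "uncertain") "not_predicted"
              else if (p$label == e) "agreement"
              else "disagreement"
    data.frame(
      cas = k,
      stratum = if (!is.na(p$confidence_pct) &&
                    p$confidence_pct >= threshold_pct) "high" else "low",
      predicted = p$label, experimental = e, result = result,
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cas = character(), stratum = character(),
               predicted = character(), experimental = character(),
               result = character())
  summary <- do.call(rbind, lapply(c("high", "low"), function(s) {
    sel <- tab$stratum == s
    data.frame(
      stratum = s, n = sum(sel),
      agreements = sum(tab$result[sel] == "agreement"),
      disagreements = sum(tab$result[sel] == "disagreement"),
      incompletes = sum(tab$result[sel] == "incomplete"),
      stringsAsFactors = FALSE
    )
  }))
  list(table = tab, summary = summary, unmatched = unmatched)
}
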