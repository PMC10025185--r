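# Analogue read-across: nearest annotated positive by Tanimoto similarity.

#' Read-across inference from positive analogues
#'
#' For every query structure the maximum Tanimoto similarity to any
#' positively annotated structure is computed on 2048-bit path fingerprints.
#' Queries whose best analogue exceeds the cutoff (strictly) inherit a
#' positive inference; everything else is reported as `none` — the absence
#' of a sufficiently similar analogue is NOT a negative label, it only means
#' read-across cannot assess the compound. Only positive inference is made,
#' because the annotated set against which similarity is computed is a
#' positive set.
#'
#' @param queries data frame with columns `cas`, `smiles`.
#' @param positives data frame with columns `cas`, `smiles` of positively
#'   annotated substances; must be non-empty (with no positives read-across
#'   is impossible — the degenerate case of an endpoint with almost no
#'   annotations of one polarity).
#' @param cutoff similarity cutoff, default 0.8; inference requires
#'   `similarity > cutoff`.
#' @return data frame `query_cas`, `nearest_positive_cas`, `similarity`,
#'   `inferred` (`"positive"` / `"none"`), sorted by similarity descending
#'   (ties by query CAS ascending). Nearest-neighbour ties break on the
#'   lexicographically smaller positive CAS. Unfeaturizable queries are
#'   returned with `NA` similarity and `inferred = "none"`.
#' @export
rax_infer <- function(queries, positives, cutoff = 0.8) {
  if (is.null(positives) || nrow(positives) == 0L) {
    stop("read-across impossible: the positive annotated set is empty",
         call. = FALSE)
  }
  pos_fp <- lapply(positives$smiles, function(s)
    tryCatch(fingerprint(s), error = function(e) NULL))
  keep <- !vapply(pos_fp, is.null, logical(1))
  if (!any(keep)) {
    stop("read-across impossible: no positive structure could be featurized",
         call. = FALSE)
  }
  pos_fp <- pos_fp[keep]
  pos_cas <- positives$cas[keep]
  ord <- order(pos_cas)  # CAS-lexicographic tie-break
  pos_fp <- pos_fp[ord]
  pos_cas <- pos_cas[ord]

  out <- data.frame(
    query_cas = queries$cas,
    nearest_positive_cas = NA_character_,
    similarity = NA_real_,
    inferred = "none",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(queries))) {
    qfp <- tryCatch(fingerprint(queries$smiles[i]), error = function(e) NULL)
    if (is.null(qfp)) next
    sims <- vapply(pos_fp, function(fp)
      suppressWarnings(tanimoto(qfp, fp)), numeric(1))
    best <- which.max(sims)  # first max = smallest CAS on ties
    out$nearest_positive_cas[i] <- pos_cas[best]
    out$similarity[i] <- sims[best]
    if (sims[best] > cutoff) out$inferred[i] <- "positive"
  }
  ord_out <- order(-ifelse(is.na(out$similarity), -Inf, out$similarity),
                   out$query_cas)
  out <- out[ord_out, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "dialect") <- FP_DIALECT
  out
}

#' Read-across labels for uninformed substances of one endpoint
#'
#' Convenience wrapper that takes integrated labels plus a curation report,
#' builds the positive set (`YES`, optionally `Pending`) and the query set
#' (`NoInformation`), and runs [rax_infer()]. Inferred labels carry
#' provenance `"rax"` and never overwrite integrated labels.
#'
#' @param labels integrated labels from [integrate_all()].
#' @param curation_report a `tox_curation_report`.
#' @param endpoint endpoint name.
#' @param cutoff similarity cutoff.
#' @param include_pending treat `Pending` as positive analogues too
#'   (default FALSE).
#' @return list with `results` (the [rax_infer()] table) and `labels`
#'   (data frame `cas`, `endpoint`, `value = "YES"`, `provenance = "rax"`
#'   for inferred positives).
#' @export
rax_endpoint <- function(labels, curation_report, endpoint, cutoff = 0.8,
                         include_pending = FALSE) {
  stopifnot(endpoint %in% ENDPOINTS)
  kept <- curation_report$kept
  lab <- labels[labels$endpoint == endpoint & labels$cas %in% kept$cas, ]
  smiles_of <- stats::setNames(kept$model_smiles, kept$cas)
  pos_values <- if (include_pending) c("YES", "Pending") else "YES"
  positives <- data.frame(cas = lab$cas[lab$value %in% pos_values],
                          stringsAsFactors = FALSE)
  positives$smiles <- unname(smiles_of[positives$cas])
  queries <- data.frame(cas = lab$cas[lab$value == "NoInformation"],
                        stringsAsFactors = FALSE)
  queries$smiles <- unname(smiles_of[queries$cas])
  res <- rax_infer(queries, positives, cutoff)
  hit <- res$query_cas[res$inferred == "positive"]
  list(
    results = res,
    labels = data.frame(
      cas = hit,
      endpoint = if (length(hit)) endpoint else character(0),
      value = if (length(hit)) "YES" else character(0),
      provenance = if (length(hit)) "rax" else character(0),
      stringsAsFactors = FALSE
    )
  )
}
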