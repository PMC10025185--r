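# Binary training-set construction and class-imbalance correction.

#' Extract a binary training set for one endpoint
#'
#' Only integrated `YES` (coded 1) and `NO` (coded 0) labels enter the
#' training set. For CMR the default policy additionally codes `Pending` as
#' positive (if a substance might be CMR it is treated as CMR — the
#' conservative reading); for the other endpoints `Pending` is excluded from
#' both sets. `NoInformation` substances are never trained on: they form the
#' prediction set. Both sets are restricted to modelable (curated, desalted)
#' structures.
#'
#' @param labels integrated label table from [integrate_all()].
#' @param curation_report a `tox_curation_report` from [select_modelable()].
#' @param endpoint one of `"CMR"`, `"ED"`, `"PBT"`, `"vPvB"`.
#' @param pending_policy `"as_positive"` or `"exclude"`; defaults to
#'   `"as_positive"` for CMR and `"exclude"` otherwise.
#' @return a list of class `tox_binary_dataset` with `training` (data frame
#'   `cas`, `smiles`, `y`), `prediction` (data frame `cas`, `smiles`),
#'   `endpoint` and `pending_policy`. If either class is empty the object
#'   has `modelable = FALSE` and a `reason` recommending read-across — the
#'   endocrine-disruption situation, where negatives are nearly absent.
#' @export
extract_training_set <- function(labels, curation_report, endpoint,
                                 pending_policy = NULL) {
  stopifnot(endpoint %in% ENDPOINTS)
  if (is.null(pending_policy)) {
    pending_policy <- if (endpoint == "CMR") "as_positive" else "exclude"
  }
  pending_policy <- match.arg(pending_policy, c("as_positive", "exclude"))
  lab <- labels[labels$endpoint == endpoint, , drop = FALSE]
  kept <- curation_report$kept
  lab <- lab[lab$cas %in% kept$cas, , drop = FALSE]
  smiles_of <- stats::setNames(kept$model_smiles, kept$cas)

  y <- rep(NA_integer_, nrow(lab))
  y[lab$value == "YES"] <- 1L
  y[lab$value == "NO"] <- 0L
  if (pending_policy == "as_positive") y[lab$value == "Pending"] <- 1L

  train <- data.frame(
    cas = lab$cas[!is.na(y)],
    smiles = unname(smiles_of[lab$cas[!is.na(y)]]),
    y = y[!is.na(y)],
    stringsAsFactors = FALSE
  )
  pred_cas <- lab$cas[lab$value == "NoInformation"]
  prediction <- data.frame(
    cas = pred_cas, smiles = unname(smiles_of[pred_cas]),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(train$smiles) | duplicated(train$smiles, fromLast = TRUE)
  out <- structure(list(
    training = train, prediction = prediction, endpoint = endpoint,
    pending_policy = pending_policy,
    duplicate_structures = unique(train$smiles[dup]),
    modelable = sum(train$y == 1L) > 0L && sum(train$y == 0L) > 0L
  ), class = "tox_binary_dataset")
  if (!out$modelable) {
    out$reason <- paste0(
      "endpoint ", endpoint, " has an empty class (",
      sum(train$y == 1L), " positives / ", sum(train$y == 0L),
      " negatives): unmodelable, use read-across (rax_infer)")
  }
  out
}

#' @export
print.tox_binary_dataset <- function(x, ...) {
  cat("<tox_binary_dataset> ", x$endpoint, ": ",
      sum(x$training$y == 1L), " pos / ", sum(x$training$y == 0L),
      " neg; prediction set ", nrow(x$prediction), "\n", sep = "")
  if (!x$modelable) cat("  NOT modelable: ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Simple oversampling (doubling the minority class)
#'
#' Each minority-class record is duplicated exactly once, so the minority
#' count doubles and the majority class is untouched. No new structures are
#' invented: added records are copies of existing ones. Deterministic; the
#' `seed` argument is accepted for interface uniformity but unused. A
#' dataset that is already balanced is returned unchanged with a message.
#'
#' @param dataset a `tox_binary_dataset` (or plain data frame with column
#'   `y`).
#' @param seed ignored (the operation is deterministic).
#' @return the dataset with the minority class doubled.
#' @export
oversample <- function(dataset, seed = NULL) {
  df <- if (inherits(dataset, "tox_binary_dataset")) dataset$training
        else dataset
  n1 <- sum(df$y == 1L)
  n0 <- sum(df$y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty",
                                 call. = FALSE)
  if (n1 == n0) {
    message("classes already balanced; dataset returned unchanged")
    out <- df
  } else {
    minority <- if (n1 < n0) 1L else 0L
    out <- rbind(df, df[df$y == minority, , drop = FALSE])
    rownames(out) <- NULL
  }
  if (inherits(dataset, "tox_binary_dataset")) {
    dataset$training <- out
    dataset$balance <- "oversample"
    dataset
  } else {
    out
  }
}

#' Partition a positive-heavy dataset into balanced ensemble subsets
#'
#' When positives far outnumber negatives, oversampling the negatives is not
#' enough; instead several balanced datasets are built, each containing
#' every negative compound plus an equal-sized random sample of positives,
#' such that every positive appears in at least one subset. Construction:
#' positives are shuffled (seed-deterministic) and chunked into `n_subsets`
#' blocks of `n_neg`; a short final chunk is topped up by resampling
#' positives already used in other chunks (never duplicating within the
#' chunk), so each subset is exactly balanced.
#'
#' @param dataset a `tox_binary_dataset` or data frame with columns `cas`,
#'   `smiles`, `y`, with more positives than negatives.
#' @param n_subsets number of subsets; default
#'   `max(3, ceiling(n_pos / n_neg))`.
#' @param seed RNG seed for the shuffle.
#' @return a list of class `tox_ensemble_partition`: `subsets` (list of data
#'   frames, each with all negatives and `n_neg` positives), `seed`,
#'   `n_subsets`.
#' @export
partition_ensemble <- function(dataset, n_subsets = NULL, seed = 1L) {
  df <- if (inherits(dataset, "tox_binary_dataset")) dataset$training
        else dataset
  pos <- df[df$y == 1L, , drop = FALSE]
  neg <- df[df$y == 0L, , drop = FALSE]
  n_pos <- nrow(pos)
  n_neg <- nrow(neg)
  if (n_pos <= n_neg) {
    stop("positives (", n_pos, ") do not outnumber negatives (", n_neg,
         "): partitioning unnecessary, use oversample()", call. = FALSE)
  }
  min_subsets <- ceiling(n_pos / n_neg)
  if (is.null(n_subsets)) n_subsets <- max(3L, min_subsets)
  if (n_subsets < min_subsets) {
    stop("n_subsets must be >= ceiling(n_pos / n_neg) = ", min_subsets,
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  order_pos <- sample.int(n_pos)
  chunks <- split(order_pos, ceiling(seq_along(order_pos) / n_neg))
  # fewer chunks than subsets: start extra chunks empty
  while (length(chunks) < n_subsets) chunks[[length(chunks) + 1L]] <- integer(0)
  chunks <- lapply(chunks, function(ch) {
    short <- n_neg - length(ch)
    if (short > 0L) {
      pool <- setdiff(order_pos, ch)
      ch <- c(ch, pool[sample.int(length(pool), short)])
    }
    ch
  })
  subsets <- lapply(chunks, function(ch) {
    out <- rbind(neg, pos[ch, , drop = FALSE])
    rownames(out) <- NULL
    out
  })
  structure(list(subsets = subsets, seed = seed, n_subsets = n_subsets),
            class = "tox_ensemble_partition")
}

#' @export
print.tox_ensemble_partition <- function(x, ...) {
  cat("<tox_ensemble_partition> ", length(x$subsets), " balanced subsets of ",
      nrow(x$subsets[[1]]), " records (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# save/restore the global RNG state so seeded operations do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
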