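#' Create an empty substance registry
#'
#' A registry is the in-memory analogue of the chemical-inventory database:
#' one row per substance, keyed on CAS-RN, with a synonym set, an optional
#' SMILES structure and an optional EC number. All downstream stages
#' (curation, endpoint integration, modelling) consume a registry.
#'
#' @return an object of class `tox_registry`.
#' @seealso [register_substance()], [read_substances_csv()],
#'   [summarize_registry()]
#' @export
registry <- function() {
  structure(
    list(
      substances = data.frame(
        cas = character(), smiles = character(), ec_number = character(),
        structure_status = character(), stringsAsFactors = FALSE
      ),
      synonyms = list()
    ),
    class = "tox_registry"
  )
}

#' Register (or merge) a substance
#'
#' New CAS numbers create an entry; re-registering an existing CAS merges the
#' name into the synonym set (case-insensitively, whitespace-normalised) and
#' fills in the SMILES only if it was previously absent. Registration is
#' idempotent. A record whose SMILES conflicts with an already-stored,
#' non-identical structure raises a condition of class
#' `toxtriage_smiles_conflict` carrying both structures; structures are never
#' silently overwritten. Substances without a structure are retained (they
#' are routed to non-QSAR methods later), never dropped.
#'
#' @param reg a `tox_registry`.
#' @param cas CAS-RN (must pass [validate_cas()] unless `lenient = TRUE`).
#' @param name substance name (added to the synonym set).
#' @param smiles optional SMILES string (`NA` for none).
#' @param ec_number optional EC number.
#' @param lenient if `TRUE`, accept CAS identifiers that fail validation
#'   (they are still usable as opaque keys); the default is strict.
#' @return the updated registry.
#' @export
register_substance <- function(reg, cas, name, smiles = NA_character_,
                               ec_number = NA_character_, lenient = FALSE) {
  stopifnot(inherits(reg, "tox_registry"), length(cas) == 1L)
  cas <- trimws(as.character(cas))
  if (!lenient) {
    verdict <- validate_cas(cas)
    if (verdict != "valid") {
      stop("CAS '", cas, "' is ", verdict,
           "; use lenient = TRUE to register anyway", call. = FALSE)
    }
  }
  smiles <- if (length(smiles) == 0 || is.na(smiles) || !nzchar(trimws(smiles)))
    NA_character_ else trimws(smiles)
  name <- norm_name(name)
  i <- match(cas, reg$substances$cas)
  if (is.na(i)) {
    reg$substances <- rbind(reg$substances, data.frame(
      cas = cas, smiles = smiles, ec_number = as.character(ec_number),
      structure_status = if (is.na(smiles)) "missing" else "unparsed",
      stringsAsFactors = FALSE
    ))
    reg$synonyms[[cas]] <- name
  } else {
    old <- reg$substances$smiles[i]
    if (!is.na(smiles) && !is.na(old) && !identical_structure(old, smiles)) {
      cond <- structure(
        class = c("toxtriage_smiles_conflict", "error", "condition"),
        list(message = sprintf(
          "conflicting structures for CAS %s: '%s' vs '%s'", cas, old, smiles),
          call = sys.call(-1), cas = cas, existing = old, incoming = smiles)
      )
      stop(cond)
    }
    if (is.na(old) && !is.na(smiles)) {
      reg$substances$smiles[i] <- smiles
      reg$substances$structure_status[i] <- "unparsed"
    }
    if (is.na(reg$substances$ec_number[i]) && !is.na(ec_number)) {
      reg$substances$ec_number[i] <- as.character(ec_number)
    }
    syn <- reg$synonyms[[cas]]
    if (!tolower(name) %in% tolower(syn)) {
      reg$synonyms[[cas]] <- c(syn, name)
    }
  }
  reg
}

norm_name <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))

# two SMILES denote the same structure if equal verbatim or after
# canonicalisation (canonicalisation failures fall back to string identity)
identical_structure <- function(a, b) {
  if (identical(a, b)) return(TRUE)
  ca <- tryCatch(canonical_smiles(a), error = function(e) NA_character_)
  cb <- tryCatch(canonical_smiles(b), error = function(e) NA_character_)
  !is.na(ca) && !is.na(cb) && identical(ca, cb)
}

#' Read a substances CSV into a registry
#'
#' Expects a UTF-8 CSV with a header and columns `cas,name,smiles,ec_number`
#' (the last two may be empty). Rows are registered in file order via
#' [register_substance()], so duplicate CAS rows merge into synonyms.
#'
#' @param path CSV file path.
#' @param lenient passed to [register_substance()].
#' @return a `tox_registry`.
#' @export
read_substances_csv <- function(path, lenient = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cas", "name")
  if (!all(need %in% names(df))) {
    stop("substances CSV must have at least columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  if (!"ec_number" %in% names(df)) df$ec_number <- NA_character_
  df$smiles[!nzchar(trimws(ifelse(is.na(df$smiles), "", df$smiles)))] <- NA
  reg <- registry()
  for (r in seq_len(nrow(df))) {
    reg <- register_substance(reg, df$cas[r], df$name[r], df$smiles[r],
                              df$ec_number[r], lenient = lenient)
  }
  reg
}

#' Write a registry to a substances CSV
#'
#' @param reg a `tox_registry`.
#' @param path output path. Synonyms are joined with `"; "` into the `name`
#'   column.
#' @return `path`, invisibly.
#' @export
write_substances_csv <- function(reg, path) {
  df <- reg$substances
  df$name <- vapply(df$cas, function(k)
    paste(reg$synonyms[[k]], collapse = "; "), character(1))
  utils::write.csv(df[, c("cas", "name", "smiles", "ec_number")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Summarise a registry
#'
#' Tallies the registry the way an inventory report does: number of
#' substances, how many carry a structure, annotation counts per source (if
#' annotations are supplied), and the label distribution over the four
#' endpoints. Every (substance, endpoint) pair missing from `labels` counts
#' as `NoInformation`, so the label tally always sums to
#' `4 * n_compounds` (conservation).
#'
#' @param reg a `tox_registry`.
#' @param labels optional integrated label table from [integrate_all()].
#' @param annotations optional annotation table (columns `cas`, `source`).
#' @return a list of class `tox_registry_summary`.
#' @export
summarize_registry <- function(reg, labels = NULL, annotations = NULL) {
  n <- nrow(reg$substances)
  tally <- c(YES = 0L, NO = 0L, Pending = 0L, NoInformation = 4L * n)
  if (!is.null(labels) && nrow(labels) > 0) {
    lab <- labels[labels$cas %in% reg$substances$cas, , drop = FALSE]
    lab <- lab[!duplicated(lab[, c("cas", "endpoint")]), , drop = FALSE]
    tb <- table(factor(lab$value,
                       levels = c("YES", "NO", "Pending", "NoInformation")))
    tally <- tally + c(tb) - c(0L, 0L, 0L, sum(tb))
  }
  n_by_source <- if (is.null(annotations)) integer(0) else
    table(annotations$source[annotations$cas %in% reg$substances$cas])
  structure(list(
    n_compounds = n,
    n_with_structure = sum(!is.na(reg$substances$smiles)),
    n_annotations_by_source = n_by_source,
    label_tally = tally,
    total_possible = 4L * n
  ), class = "tox_registry_summary")
}

#' @export
print.tox_registry_summary <- function(x, ...) {
  cat("Substance registry summary\n")
  cat("  compounds:        ", x$n_compounds, "\n")
  cat("  with structure:   ", x$n_with_structure, "\n")
  cat("  possible labels:  ", x$total_possible, " (4 endpoints)\n")
  cat("  label tally:       YES ", x$label_tally[["YES"]],
      " | NO ", x$label_tally[["NO"]],
      " | Pending ", x$label_tally[["Pending"]],
      " | NoInformation ", x$label_tally[["NoInformation"]], "\n", sep = "")
  if (length(x$n_annotations_by_source)) {
    cat("  annotations by source:\n")
    for (s in names(x$n_annotations_by_source)) {
      cat("    ", s, ": ", x$n_annotations_by_source[[s]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
print.tox_registry <- function(x, ...) {
  cat("<tox_registry> ", nrow(x$substances), " substances (",
      sum(!is.na(x$substances$smiles)), " with structure)\n", sep = "")
  invisible(x)
}
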