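# Structure categorisation and the modelable-subset selection.

CURATION_CATEGORIES <- c(
  "organic", "organic_salt", "organometallic", "peptide",
  "inorganic", "inorganic_salt", "inorganic_metal",
  "nosanitizable_organic", "nosanitizable_inorganic",
  "nosanitizable_organometallic"
)

MODELABLE_CATEGORIES <- c("organic", "organic_salt", "peptide")

# --- individually testable predicates -------------------------------------

# any bond between a carbon and a metal atom?
has_carbon_metal_bond <- function(g) {
  if (nrow(g$bonds) == 0L) return(FALSE)
  s1 <- g$symbols[g$bonds$a1]
  s2 <- g$symbols[g$bonds$a2]
  any((s1 == "C" & is_metal(s2)) | (s2 == "C" & is_metal(s1)))
}

# does a fragment contain an "organic" carbon, i.e. a carbon bonded to H
# (implicit or explicit) or to another carbon?
fragment_has_organic_carbon <- function(g, atoms) {
  cs <- atoms[g$symbols[atoms] == "C"]
  if (!length(cs)) return(FALSE)
  bo <- atom_bond_order_sum(g)
  for (i in cs) {
    nb <- neighbours_of(g, i)
    if (any(g$symbols[nb] %in% c("C", "H"))) return(TRUE)
    # implicit hydrogens: free valence left after explicit bonds and charge
    maxv <- 4 - abs(g$charge[i])
    if (bo[i] < maxv - 1e-9) return(TRUE)
  }
  FALSE
}

neighbours_of <- function(g, i) {
  c(g$bonds$a2[g$bonds$a1 == i], g$bonds$a1[g$bonds$a2 == i])
}

# a peptide shows >= 2 backbone residue units N-C(alpha)-C(=O)
PEPTIDE_SMARTS <- "[NX3][CX4][CX3]=O"

is_peptide <- function(smiles) {
  hits <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "q")))
    ChemmineR::smartsSearchOB(sdf, PEPTIDE_SMARTS, uniqueMatches = TRUE)
  }, error = function(e) 0L)
  isTRUE(hits[[1]] >= 2L)
}

# --- classification --------------------------------------------------------

#' Classify a parsed structure into a curation category
#'
#' Applies a deterministic rule ladder to the output of
#' [parse_and_sanitize()]:
#' 1. a sanitisation failure maps to the `nosanitizable_*` subcategory chosen
#'    by rules 2-4 applied to the raw parse;
#' 2. any carbon-metal bond makes the structure `organometallic`;
#' 3. multi-fragment inputs are salts: `organic_salt` when any fragment
#'    carries a carbon bonded to H or to another carbon, else
#'    `inorganic_salt`;
#' 4. single fragments are `organic` when carbon-bearing, `inorganic_metal`
#'    when a lone metal atom/ion, otherwise `inorganic`;
#' 5. an organic single fragment with at least two peptide-backbone repeats
#'    (`r PEPTIDE_SMARTS`) is a `peptide`.
#'
#' Classification operates on the canonical form, so it is invariant to
#' atom-order permutations of the same molecule.
#'
#' @param parsed result of [parse_and_sanitize()].
#' @return a single category string (see `CURATION_CATEGORIES`).
#' @export
classify_structure <- function(parsed) {
  if (parsed$status == "parse_fail") {
    stop("cannot classify a structure that failed to parse", call. = FALSE)
  }
  g <- parsed$graph
  frags <- parsed$fragments
  base <- classify_graph(g, frags, parsed$canonical)
  if (parsed$status == "sanitize_fail") {
    key <- switch(base,
      organometallic = "organometallic",
      organic = , organic_salt = , peptide = "organic",
      "inorganic"
    )
    return(paste0("nosanitizable_", key))
  }
  base
}

classify_graph <- function(g, frags, canonical) {
  if (has_carbon_metal_bond(g)) return("organometallic")
  n_frag <- max(frags)
  if (n_frag > 1L) {
    organic <- any(vapply(seq_len(n_frag), function(f)
      fragment_has_organic_carbon(g, which(frags == f)), logical(1)))
    return(if (organic) "organic_salt" else "inorganic_salt")
  }
  if (any(g$symbols == "C")) {
    if (!is.na(canonical) && is_peptide(canonical)) return("peptide")
    return("organic")
  }
  if (g$n_atoms == 1L && is_metal(g$symbols[1])) return("inorganic_metal")
  "inorganic"
}

#' Curate every structured substance in a registry
#'
#' Runs [parse_and_sanitize()] and [classify_structure()] on each substance
#' carrying a SMILES; substances without one get category `NA` and status
#' `missing`.
#'
#' @param reg a `tox_registry`.
#' @return a data frame with columns `cas`, `status`, `category`,
#'   `canonical_smiles`.
#' @export
curate_registry <- function(reg) {
  subs <- reg$substances
  out <- data.frame(
    cas = subs$cas,
    status = "missing",
    category = NA_character_,
    canonical_smiles = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(subs))) {
    if (is.na(subs$smiles[i])) next
    p <- parse_and_sanitize(subs$smiles[i])
    out$status[i] <- p$status
    out$canonical_smiles[i] <- p$canonical
    if (p$status != "parse_fail") {
      out$category[i] <- classify_structure(p)
    }
  }
  out
}

#' Select the modelable subset of a curated registry
#'
#' Keeps substances whose category is `organic`, `organic_salt` or `peptide`;
#' organometallic, inorganic, inorganic salt, inorganic metal and all
#' no-sanitizable categories are discarded (they break descriptor
#' calculation), as are substances with no or unparseable structure. Organic
#' salts are desalted to their largest organic fragment for modelling; the
#' desalted structure is returned in `model_smiles`.
#'
#' @param curation output of [curate_registry()].
#' @return a list of class `tox_curation_report` with elements `kept` (data
#'   frame `cas`, `category`, `model_smiles`) and `excluded` (data frame
#'   `cas`, `reason` in `discarded_category` / `missing_structure` /
#'   `parse_fail`). `nrow(kept) + nrow(excluded)` equals the input size.
#' @export
select_modelable <- function(curation) {
  kept <- list()
  excluded <- list()
  for (i in seq_len(nrow(curation))) {
    row <- curation[i, ]
    if (row$status == "missing") {
      excluded[[length(excluded) + 1L]] <-
        data.frame(cas = row$cas, reason = "missing_structure")
    } else if (row$status == "parse_fail") {
      excluded[[length(excluded) + 1L]] <-
        data.frame(cas = row$cas, reason = "parse_fail")
    } else if (!row$category %in% MODELABLE_CATEGORIES) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(cas = row$cas, reason = "discarded_category")
    } else {
      ms <- if (row$category == "organic_salt") {
        largest_organic_fragment(row$canonical_smiles)
      } else {
        row$canonical_smiles
      }
      kept[[length(kept) + 1L]] <-
        data.frame(cas = row$cas, category = row$category, model_smiles = ms)
    }
  }
  structure(list(
    kept = if (length(kept)) do.call(rbind, kept) else
      data.frame(cas = character(), category = character(),
                 model_smiles = character()),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(cas = character(), reason = character())
  ), class = "tox_curation_report")
}

#' Largest organic fragment of a (salt) SMILES
#'
#' Fragments are the dot-separated components; "organic" means carrying a
#' carbon bonded to H or C. Among organic fragments the one with most atoms
#' wins; ties break on the lexicographically smaller canonical SMILES for
#' reproducibility.
#'
#' @param smiles SMILES, possibly multi-fragment.
#' @return canonical SMILES of the largest organic fragment.
#' @export
largest_organic_fragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  best <- NULL
  best_key <- list(-Inf, "")
  for (p in parts) {
    g <- mol_graph(p)
    if (is.null(g)) next
    if (!fragment_has_organic_carbon(g, seq_len(g$n_atoms))) next
    canon <- tryCatch(canonical_smiles(p), error = function(e) NA_character_)
    if (is.na(canon)) next
    if (g$n_atoms > best_key[[1]] ||
        (g$n_atoms == best_key[[1]] && canon < best_key[[2]])) {
      best <- canon
      best_key <- list(g$n_atoms, canon)
    }
  }
  if (is.null(best)) stop("no organic fragment in: ", smiles, call. = FALSE)
  best
}

#' @export
print.tox_curation_report <- function(x, ...) {
  cat("<tox_curation_report> kept ", nrow(x$kept), ", excluded ",
      nrow(x$excluded), "\n", sep = "")
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}
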