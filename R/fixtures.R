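# Deterministic synthetic-data generators. They emulate the statistical
# shape of a real industrial-chemicals inventory — sparse annotations
# (~84% of endpoint slots uninformed), strong class imbalance that differs
# by endpoint, multi-source annotation conflicts, and a structure mix
# spanning every curation category — without any download. All generators
# are pure functions of their arguments and seed.

# template structures per curation category (used by generate_registry)
FIXTURE_TEMPLATES <- list(
  organic = c(
    "CCO", "Cc1ccccc1", "Oc1ccccc1", "CC(=O)Nc1ccc(O)cc1",
    "COC(=O)C=Cc1ccccc1", "O=[N+]([O-])c1ccccc1", "CCCCCCCCO",
    "Clc1ccccc1Cl", "CC(C)Cc1ccccc1", "OCC(O)CO"
  ),
  organic_salt = c(
    "CC(=O)[O-].[Na+]", "[Na+].[O-]C(=O)c1ccccc1",
    "C[N+](C)(C)CCO.[Cl-]", "CC(=O)[O-].[NH4+]"
  ),
  organometallic = c(
    "CC[Sn](CC)CC", "CC[Pb](CC)(CC)CC", "C[Mg]Br", "C[Hg]Cl"
  ),
  peptide = c(
    "CC(N)C(=O)NC(C)C(=O)O", "NCC(=O)NCC(=O)NCC(=O)O",
    "CC(N)C(=O)NC(C)C(=O)NC(C)C(=O)O"
  ),
  inorganic = c("O=S(=O)(O)O", "OP(=O)(O)O", "O", "N"),
  inorganic_salt = c("[Na+].[Cl-]", "[K+].[Br-]", "[NH4+].[Cl-]",
                     "[Mg+2].[Cl-].[Cl-]"),
  inorganic_metal = c("[Na+]", "[Fe]", "[Cu+2]", "[Zn+2]"),
  nosanitizable_organic = c("N(C)(C)(C)(C)C", "CC(C)(C)(C)(C)C"),
  nosanitizable_inorganic = c("F(F)F"),
  nosanitizable_organometallic = c("C[Sn](C)CN(C)(C)(C)C")
)

# default structure mix: mostly modelable organics, with every category
# represented so each curation branch is exercised
FIXTURE_DEFAULT_MIX <- c(
  organic = 0.69, organic_salt = 0.08, peptide = 0.02,
  organometallic = 0.05, inorganic = 0.05, inorganic_salt = 0.05,
  inorganic_metal = 0.02, nosanitizable_organic = 0.015,
  nosanitizable_inorganic = 0.015, nosanitizable_organometallic = 0.01
)

# endpoint prevalence regimes, P(YES | annotated): CMR-like (positives
# dominate, triggering balanced-subset ensembles), PBT/vPvB-like (rare
# positives, triggering oversampling), ED-like (negatives nearly absent,
# triggering the read-across fallback)
FIXTURE_DEFAULT_PREVALENCE <- c(CMR = 0.75, ED = 0.985, PBT = 0.10,
                                vPvB = 0.12)

# substituted-benzene generator: a ring with 0-5 substituent slots filled
# from a small vocabulary; used for organic variety and for the binary
# structure datasets
SUBSTITUENTS <- c("", "C", "CC", "CCC", "O", "N", "OC", "C(C)C", "C=C", "F")

random_benzene <- function(subs) {
  slots <- vapply(subs, function(s)
    if (nzchar(s)) paste0("(", s, ")") else "", character(1))
  paste0("c1c", slots[1], "c", slots[2], "c", slots[3], "c", slots[4],
         "c1", if (nzchar(subs[5])) subs[5] else "")
}

random_organic_smiles <- function(k) {
  vapply(seq_len(k), function(i) {
    if (stats::runif(1) < 0.3) {
      sample(FIXTURE_TEMPLATES$organic, 1)
    } else {
      random_benzene(sample(SUBSTITUENTS, 5, replace = TRUE))
    }
  }, character(1))
}

#' Generate a synthetic substance registry
#'
#' CAS-like identifiers all carry correct check digits; structures are drawn
#' from a template library spanning all ten curation categories at the
#' configured mix, with a fraction of substances carrying no structure at
#' all (real inventories include mixtures and proprietary substances with no
#' resolvable structure).
#'
#' @param n number of substances.
#' @param structure_mix named proportions over curation categories (must sum
#'   to 1).
#' @param p_missing probability of a missing structure (default 0.1).
#' @param seed RNG seed.
#' @return data frame `cas`, `name`, `smiles`, `ec_number`, plus attribute
#'   `category` (the intended category per row, `NA` for missing).
#' @export
generate_registry <- function(n, structure_mix = FIXTURE_DEFAULT_MIX,
                              p_missing = 0.1, seed = 1L) {
  stopifnot(abs(sum(structure_mix) - 1) < 1e-8,
            all(names(structure_mix) %in% names(FIXTURE_TEMPLATES)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cas <- unique(random_cas(2L * n))[seq_len(n)]
  missing <- stats::runif(n) < p_missing
  category <- ifelse(missing, NA_character_,
                     sample(names(structure_mix), n, replace = TRUE,
                            prob = structure_mix))
  smiles <- rep(NA_character_, n)
  for (i in which(!missing)) {
    smiles[i] <- if (category[i] == "organic" && stats::runif(1) < 0.7) {
      random_organic_smiles(1)
    } else {
      sample(FIXTURE_TEMPLATES[[category[i]]], 1)
    }
  }
  out <- data.frame(
    cas = cas,
    name = paste0("substance-", seq_len(n)),
    smiles = smiles,
    ec_number = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(out, "category") <- category
  out
}

#' Generate synthetic multi-source hazard annotations with ground truth
#'
#' Per (substance, endpoint) slot: with probability `1 - sparsity` the slot
#' is annotated. An annotated slot gets a ground-truth label (`YES` with the
#' endpoint's prevalence, else `NO`) and 1-3 annotations from sources
#' consistent with that truth — positives from the ECHA core and Pharos,
#' negatives from the reference database and Pharos, so that with
#' `conflict_rate = 0` integration reproduces the truth exactly. With
#' probability `conflict_rate` one extra annotation of opposite polarity is
#' added (multi-source disagreement; integration resolves it conservatively
#' toward YES).
#'
#' @param registry data frame with a `cas` column (e.g.
#'   [generate_registry()] output).
#' @param prevalence named per-endpoint P(YES | annotated).
#' @param sparsity P(slot not annotated), default 0.84.
#' @param conflict_rate P(an annotated slot carries conflicting polarities).
#' @param seed RNG seed.
#' @return list with `annotations` (data frame `cas`, `source`,
#'   `hazard_code`, `polarity`) and `truth` (data frame `cas`, `endpoint`,
#'   `value` in `YES`/`NO`/`NoInformation`).
#' @export
generate_source_annotations <- function(registry,
                                        prevalence = FIXTURE_DEFAULT_PREVALENCE,
                                        sparsity = 0.84,
                                        conflict_rate = 0.02,
                                        seed = 1L) {
  stopifnot(all(ENDPOINTS %in% names(prevalence)),
            sparsity >= 0, sparsity <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos_sources <- c("ECHA_CLP", "ECHA_REACH", "ECHA_SVHC", "PHAROS")
  neg_sources <- c("REFERENCE_DB", "PHAROS")
  code_for <- function(endpoint, source) {
    if (endpoint == "CMR" && startsWith(source, "ECHA")) {
      sample(c("H340", "H350", "H351", "H360", "H361"), 1)
    } else if (endpoint == "PBT" && startsWith(source, "ECHA")) {
      "PBT_Annex_XIII"
    } else if (endpoint == "vPvB" && startsWith(source, "ECHA")) {
      "vPvB_Annex_XIII"
    } else if (endpoint == "ED" && startsWith(source, "ECHA")) {
      "ED_assessment_list"
    } else {
      endpoint  # plain endpoint tag (Pharos / reference database)
    }
  }
  ann <- list()
  truth <- list()
  for (cas in registry$cas) {
    for (ep in ENDPOINTS) {
      if (stats::runif(1) < sparsity) {
        truth[[length(truth) + 1L]] <-
          data.frame(cas = cas, endpoint = ep, value = "NoInformation")
        next
      }
      is_yes <- stats::runif(1) < prevalence[[ep]]
      truth[[length(truth) + 1L]] <-
        data.frame(cas = cas, endpoint = ep,
                   value = if (is_yes) "YES" else "NO")
      k <- sample(1:3, 1)
      srcs <- sample(if (is_yes) pos_sources else neg_sources, k,
                     replace = TRUE)
      for (s in srcs) {
        ann[[length(ann) + 1L]] <- data.frame(
          cas = cas, source = s, hazard_code = code_for(ep, s),
          polarity = if (is_yes) "positive" else "negative")
      }
      if (stats::runif(1) < conflict_rate) {
        s <- sample(if (is_yes) neg_sources else pos_sources, 1)
        ann[[length(ann) + 1L]] <- data.frame(
          cas = cas, source = s, hazard_code = code_for(ep, s),
          polarity = if (is_yes) "negative" else "positive")
      }
    }
  }
  list(
    annotations = if (length(ann)) do.call(rbind, ann) else
      data.frame(cas = character(), source = character(),
                 hazard_code = character(), polarity = character()),
    truth = do.call(rbind, truth)
  )
}

#' Generate a binary-labelled structure dataset
#'
#' The class signal is a structural motif: positives are polychlorinated
#' benzenes (3-5 ring chlorines), negatives carry at most one chlorine and
#' otherwise alkyl/ether/amine decorations. Labels are then flipped with
#' probability `noise`, producing exchangeable noisy data for conformal
#' validity checks: at `noise = 0` a forest separates the classes almost
#' perfectly, at `noise = 0.5` the label carries no structural information.
#'
#' @param n_pos,n_neg class sizes (by motif, before label flipping).
#' @param noise label-flip probability in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return data frame `cas`, `smiles`, `y` (observed label); attribute
#'   `y_motif` holds the unflipped motif class.
#' @export
generate_binary_structure_dataset <- function(n_pos, n_neg, noise = 0,
                                              seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, noise >= 0, noise <= 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_pos + n_neg
  make_pos <- function() {
    n_cl <- sample(3:5, 1)
    subs <- c(rep("Cl", n_cl),
              sample(SUBSTITUENTS, 5 - n_cl, replace = TRUE))
    random_benzene(sample(subs))
  }
  make_neg <- function() {
    n_cl <- sample(0:1, 1, prob = c(0.7, 0.3))
    subs <- c(rep("Cl", n_cl),
              sample(setdiff(SUBSTITUENTS, "Cl"), 5 - n_cl, replace = TRUE))
    random_benzene(sample(subs))
  }
  smiles <- c(vapply(seq_len(n_pos), function(i) make_pos(), character(1)),
              vapply(seq_len(n_neg), function(i) make_neg(), character(1)))
  y_motif <- c(rep(1L, n_pos), rep(0L, n_neg))
  flip <- stats::runif(n) < noise
  y <- ifelse(flip, 1L - y_motif, y_motif)
  perm <- sample.int(n)
  out <- data.frame(
    cas = random_cas(n)[perm],
    smiles = smiles[perm],
    y = y[perm],
    stringsAsFactors = FALSE
  )
  attr(out, "y_motif") <- y_motif[perm]
  out
}
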