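# 2048-bit hashed topological path fingerprint and Tanimoto similarity.
#
# One structure representation serves the whole pipeline: the same
# fingerprint feeds both the read-across similarity search and the QSAR
# feature matrix. Dialect: all linear atom paths of 1..7 bonds (plus the
# bare atoms, so single-atom fragments are not empty), encoded as the
# canonical-direction sequence of element symbols and bond orders, each path
# hashed twice into 2048 bits.

FP_NBITS <- 2048L
FP_MAX_BONDS <- 7L
FP_DIALECT <- "toxtriage-path/v1 (linear paths 1-7 bonds, 2048 bits, 2 bits/path)"

# deterministic polynomial string hash; modulus < 2^26 keeps all arithmetic
# exact in doubles
str_hash <- function(s, mod = 67108859, mult = 131) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * mult + b) %% mod
  h
}

path_bits <- function(key, nbits = FP_NBITS) {
  h <- str_hash(key)
  c(h %% nbits, (h * 7919 + 13) %% 67108859 %% nbits) + 1L
}

# enumerate all simple linear paths with 0..max_bonds bonds; each undirected
# path is emitted once (canonical direction = lexicographically smaller key)
enumerate_path_keys <- function(g, max_bonds = FP_MAX_BONDS) {
  n <- g$n_atoms
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[r]; b <- g$bonds$a2[r]; o <- g$bonds$order[r]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  keys <- character(0)
  emit <- function(atoms, orders) {
    fwd <- paste(g$symbols[atoms], collapse = "~")
    if (length(orders)) {
      fwd <- paste(paste(g$symbols[atoms[-length(atoms)]],
                         orders, sep = "|"), collapse = "~")
      fwd <- paste0(fwd, "~", g$symbols[atoms[length(atoms)]])
      rev_key <- paste(paste(g$symbols[rev(atoms)[-length(atoms)]],
                             rev(orders), sep = "|"), collapse = "~")
      rev_key <- paste0(rev_key, "~", g$symbols[atoms[1]])
      if (rev_key < fwd) fwd <- rev_key
    }
    keys[[length(keys) + 1L]] <<- fwd
  }
  dfs <- function(atoms, orders) {
    emit(atoms, orders)
    if (length(orders) >= max_bonds) return()
    last <- atoms[length(atoms)]
    nb <- adj[[last]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% atoms) next
      # dedupe reverse traversals of the same path: only extend when the
      # endpoint pair is visited once (start <= new end breaks symmetry for
      # paths of >= 1 bond)
      dfs(c(atoms, nxt), c(orders, nb[r, 2]))
    }
  }
  for (s in seq_len(n)) dfs(s, integer(0))
  keys
}

#' Compute the 2048-bit path fingerprint of a structure
#'
#' Deterministic: identical molecules (same canonical SMILES) yield identical
#' fingerprints. The dialect string is attached as attribute `dialect` so
#' that model manifests and read-across outputs can record it.
#'
#' @param smiles a single SMILES string.
#' @param nbits fingerprint length in bits (default 2048).
#' @return an integer 0/1 vector of length `nbits`.
#' @export
fingerprint <- function(smiles, nbits = FP_NBITS) {
  p <- parse_and_sanitize(smiles)
  if (p$status == "parse_fail") {
    stop("cannot fingerprint unparseable SMILES: ", smiles, call. = FALSE)
  }
  # fingerprint the canonical form so atom numbering in the input is moot
  g <- mol_graph(p$canonical)
  if (is.null(g)) g <- p$graph
  bits <- integer(nbits)
  for (key in enumerate_path_keys(g)) {
    bits[path_bits(key, nbits)] <- 1L
  }
  attr(bits, "dialect") <- FP_DIALECT
  bits
}

#' @rdname fingerprint
#' @export
featurize <- fingerprint

#' Fingerprint matrix for a set of structures
#'
#' @param smiles character vector of SMILES.
#' @return integer matrix, one row per structure, `nbits` columns. Rows that
#'   fail to parse are filled with `NA` and flagged in attribute `failed`
#'   (their indices).
#' @export
fingerprint_matrix <- function(smiles, nbits = FP_NBITS) {
  m <- matrix(NA_integer_, nrow = length(smiles), ncol = nbits)
  failed <- integer(0)
  for (i in seq_along(smiles)) {
    fp <- tryCatch(fingerprint(smiles[i], nbits), error = function(e) NULL)
    if (is.null(fp)) failed <- c(failed, i) else m[i, ] <- fp
  }
  attr(m, "failed") <- failed
  attr(m, "dialect") <- FP_DIALECT
  m
}

#' Tanimoto similarity between two bit vectors
#'
#' `|a AND b| / |a OR b|`; symmetric, in `[0, 1]`. Two all-zero fingerprints
#' have undefined similarity; by convention 0 is returned with a warning.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints differ in length", call. = FALSE)
  }
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto undefined, returning 0")
    return(0)
  }
  sum(a & b) / u
}
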