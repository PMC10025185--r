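# Chemistry layer: SMILES parsing via OpenBabel (ChemmineOB), plus the
# valence (sanitisation) check and the structure-category rule ladder.

# Elements NOT treated as metals for the organometallic / inorganic rules.
NONMETALS <- c(
  "H", "C", "N", "O", "P", "S", "Se", "B", "Si",
  "F", "Cl", "Br", "I", "At",
  "He", "Ne", "Ar", "Kr", "Xe", "Rn"
)

is_metal <- function(symbol) !(symbol %in% NONMETALS)

# Maximum allowed total valence (explicit bond-order sum + implicit H) per
# element. Hypervalent-capable main-group elements get their highest common
# valence; elements absent from the table are not checked.
MAX_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1,
  Si = 6, P = 5, S = 6, Cl = 7, Se = 6, Br = 7, I = 7, As = 5
)

# Lexical SMILES validity. The underlying toolkit silently repairs some
# malformed inputs (e.g. dangling branch opens), so token balance is checked
# before parsing: parentheses, brackets, and ring-bond closures must pair up.
smiles_lex_ok <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(FALSE)
  if (grepl("[[:space:]]", smiles)) return(FALSE)
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  in_bracket <- FALSE
  rings <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "[") return(FALSE)
      if (ch == "]") in_bracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") {
      in_bracket <- TRUE
    } else if (ch == "]") {
      return(FALSE)
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$",
                               paste0(chars[i + 1L], chars[i + 2L]))) {
        return(FALSE)
      }
      rings <- toggle_ring(rings, paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      rings <- toggle_ring(rings, ch)
    } else if (!grepl("[]A-Za-z@+=#$:/.*\\\\-]", ch, perl = TRUE)) {
      return(FALSE)
    }
    i <- i + 1L
  }
  !in_bracket && depth == 0L && length(rings) == 0L
}

toggle_ring <- function(open, id) {
  if (id %in% open) setdiff(open, id) else c(open, id)
}

# Parse one SMILES into an atom/bond graph via OpenBabel's molfile output.
# The V2000 fields are fixed-position; charges come from the atom-line charge
# code and any M CHG property lines (which override). Returns NULL on failure.
mol_graph <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles),
    error = function(e) NULL
  )
  if (is.null(txt) || !nzchar(txt)) return(NULL)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds) || n_atoms < 1L) return(NULL)
  atom_lines <- lines[5:(4 + n_atoms)]
  symbols <- trimws(substr(atom_lines, 32, 34))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  # old-style codes: 0 none, 1..3 = +3..+1, 4 radical, 5..7 = -1..-3
  charge <- ifelse(chg_code %in% 1:3, 4L - chg_code,
                   ifelse(chg_code %in% 5:7, -(chg_code - 4L), 0L))
  bonds <- if (n_bonds > 0L) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                "[[:space:]]+")[[1]])
    k <- toks[1]
    for (j in seq_len(k)) {
      charge[toks[2 * j]] <- toks[2 * j + 1]
    }
  }
  list(symbols = symbols, charge = charge, bonds = bonds,
       n_atoms = n_atoms)
}

# connected components of the molecular graph (fragments)
graph_fragments <- function(g) {
  comp <- integer(g$n_atoms)
  cur <- 0L
  adj <- vector("list", g$n_atoms)
  for (r in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[r]; b <- g$bonds$a2[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (s in seq_len(g$n_atoms)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# total explicit bond order per atom (aromatic molfile bonds arrive kekulised)
atom_bond_order_sum <- function(g) {
  s <- numeric(g$n_atoms)
  for (r in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[r]
    if (o == 4L) o <- 1.5 # aromatic, defensive; OpenBabel normally kekulises
    s[g$bonds$a1[r]] <- s[g$bonds$a1[r]] + o
    s[g$bonds$a2[r]] <- s[g$bonds$a2[r]] + o
  }
  s
}

# valence sanity: an atom fails if its explicit bond-order sum exceeds the
# maximum allowed valence for its element (charge-adjusted for B/C/N/O).
valence_ok <- function(g) {
  bo <- atom_bond_order_sum(g)
  for (i in seq_len(g$n_atoms)) {
    sym <- g$symbols[i]
    if (!sym %in% names(MAX_VALENCE)) next
    maxv <- MAX_VALENCE[[sym]]
    q <- g$charge[i]
    if (sym %in% c("N", "O", "B")) maxv <- maxv + q
    if (sym == "C") maxv <- maxv - abs(q)
    if (bo[i] > maxv + 1e-9) return(FALSE)
  }
  TRUE
}

#' Canonicalise a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES; errors if the input cannot be parsed.
#' @export
canonical_smiles <- function(smiles) {
  if (!smiles_lex_ok(smiles)) stop("unparseable SMILES: ", smiles,
                                   call. = FALSE)
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  out <- trimws(strsplit(out, "[\t\n]")[[1]][1])
  if (is.na(out) || !nzchar(out)) stop("unparseable SMILES: ", smiles,
                                       call. = FALSE)
  out
}

#' Parse and sanitise a SMILES structure
#'
#' Parsing turns the SMILES into an explicit atom/bond graph with fragment
#' decomposition; sanitisation then checks every atom against a standard
#' valence table (e.g. a pentavalent neutral nitrogen fails). Failures are
#' reported as statuses, never as exceptions, because inventory files
#' routinely contain unparseable entries: a `sanitize_fail` keeps the raw
#' parse so the structure can still be categorised as no-sanitizable.
#'
#' @param smiles a single SMILES string (`NA` allowed).
#' @return a list with elements `status` (`"ok"`, `"parse_fail"` or
#'   `"sanitize_fail"`), `graph` (atom/bond graph or `NULL`), `fragments`
#'   (integer component index per atom or `NULL`), and `canonical` (canonical
#'   SMILES, `NA` when parsing failed).
#' @export
parse_and_sanitize <- function(smiles) {
  fail <- list(status = "parse_fail", graph = NULL, fragments = NULL,
               canonical = NA_character_)
  if (length(smiles) != 1L || is.na(smiles) || !smiles_lex_ok(smiles)) {
    return(fail)
  }
  g <- mol_graph(smiles)
  if (is.null(g)) return(fail)
  canon <- tryCatch(canonical_smiles(smiles), error = function(e) NA_character_)
  status <- if (valence_ok(g)) "ok" else "sanitize_fail"
  list(status = status, graph = g, fragments = graph_fragments(g),
       canonical = canon)
}
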