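# Integration of source-level hazard annotations into one label per
# (substance, endpoint).

ENDPOINTS <- c("CMR", "ED", "PBT", "vPvB")
LABEL_VALUES <- c("YES", "NO", "Pending", "NoInformation")
ANNOTATION_SOURCES <- c("ECHA_CLP", "ECHA_REACH", "ECHA_SVHC",
                        "ECHA_REGDOSSIER", "ECHA_OTHER",
                        "REFERENCE_DB", "PHAROS")

# precedence tiers of the decision workflow: a positive in the ECHA core
# (CLP / REACH / SVHC) is a firm YES; the remaining ECHA sources
# (registration dossiers etc.) only support Pending; then the reference
# database, then Pharos.
TIER_ECHA_CORE <- c("ECHA_CLP", "ECHA_REACH", "ECHA_SVHC")
TIER_ECHA_SOFT <- c("ECHA_REGDOSSIER", "ECHA_OTHER")

#' Default hazard-code to endpoint mapping
#'
#' The shipped mapping covers the CLP health-hazard codes that define CMR
#' (H340/H341 mutagenicity, H350/H351 carcinogenicity, H360/H361/H362
#' reproductive toxicity), the REACH Annex XIII PBT/vPvB flags, the ED
#' assessment-list flag, and plain endpoint tags (`CMR`, `ED`, `PBT`,
#' `vPvB`) as used by Pharos and reference-database exports. It is an
#' editable configuration table (see [read_hazard_mapping()]), not a fixed
#' rule: `source = "*"` matches any source.
#'
#' @return data frame with columns `source`, `hazard_code`, `endpoint`.
#' @export
default_hazard_mapping <- function() {
  path <- system.file("extdata", "hazard_endpoint_map.csv",
                      package = "toxtriage")
  read_hazard_mapping(path)
}

#' Read a hazard-code mapping table
#'
#' @param path CSV with columns `source` (`"*"` for any), `hazard_code`,
#'   `endpoint`.
#' @return the mapping data frame, validated.
#' @export
read_hazard_mapping <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  stopifnot(all(c("source", "hazard_code", "endpoint") %in% names(m)))
  bad <- setdiff(unique(m$endpoint), ENDPOINTS)
  if (length(bad)) stop("unknown endpoints in mapping: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  m
}

#' Map one hazard annotation to endpoints
#'
#' Deterministic lookup: unknown codes map to no endpoint at all (they are
#' simply not informative for the four tracked endpoints).
#'
#' @param source annotation source (one of `ANNOTATION_SOURCES`).
#' @param hazard_code the source's hazard code or tag.
#' @param mapping a mapping table ([default_hazard_mapping()] by default).
#' @return character vector of endpoints (possibly empty).
#' @export
map_hazard_to_endpoint <- function(source, hazard_code,
                                   mapping = default_hazard_mapping()) {
  hit <- mapping$hazard_code == hazard_code &
    (mapping$source == "*" | mapping$source == source)
  unique(mapping$endpoint[hit])
}

#' Integrate the annotations of one (substance, endpoint) pair
#'
#' Precedence, applied to annotations already mapped to the endpoint:
#' 1. any positive from the ECHA core (CLP, REACH, SVHC) gives `YES`;
#' 2. else any positive from the remaining ECHA sources (registration
#'    dossier, other) gives `Pending`;
#' 3. else a reference-database annotation passes through (positive `YES`,
#'    negative `NO`);
#' 4. else Pharos: positive `YES`, negative `NO`;
#' 5. no annotation at all gives `NoInformation`.
#' Within every tier a positive beats a negative (conservative rule:
#' conflicting evidence is resolved toward hazard).
#'
#' @param annotations data frame with columns `source`, `polarity`
#'   (`"positive"`/`"negative"`) for a single substance and endpoint; zero
#'   rows allowed.
#' @return one of `"YES"`, `"NO"`, `"Pending"`, `"NoInformation"`.
#' @export
integrate_endpoint_label <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) return("NoInformation")
  stopifnot(all(annotations$polarity %in% c("positive", "negative")))
  pos <- annotations$source[annotations$polarity == "positive"]
  neg <- annotations$source[annotations$polarity == "negative"]
  if (any(pos %in% TIER_ECHA_CORE)) return("YES")
  if (any(pos %in% TIER_ECHA_SOFT)) return("Pending")
  if (any(pos == "REFERENCE_DB")) return("YES")
  if (any(neg == "REFERENCE_DB")) return("NO")
  if (any(pos == "PHAROS")) return("YES")
  if (any(neg == "PHAROS")) return("NO")
  # ECHA tiers contribute positives only (classification listings); negative
  # evidence there is not a firm NO
  "NoInformation"
}

#' Integrate all annotations of a registry
#'
#' Produces exactly one integrated label per (substance, endpoint) pair —
#' `4 * n` labels. The result is independent of annotation row order and
#' idempotent. Annotations whose CAS is absent from the registry are
#' collected in the `rejects` attribute, never silently dropped.
#'
#' @param reg a `tox_registry`.
#' @param annotations data frame with columns `cas`, `source`,
#'   `hazard_code`, `polarity`.
#' @param mapping hazard-code mapping, see [default_hazard_mapping()].
#' @return data frame `cas`, `endpoint`, `value`, `provenance`
#'   (`"integrated"`), with attribute `rejects` (data frame of unknown-CAS
#'   annotations).
#' @export
integrate_all <- function(reg, annotations,
                          mapping = default_hazard_mapping()) {
  cas_all <- reg$substances$cas
  if (is.null(annotations)) {
    annotations <- data.frame(cas = character(), source = character(),
                              hazard_code = character(),
                              polarity = character())
  }
  bad_src <- setdiff(unique(annotations$source), ANNOTATION_SOURCES)
  if (length(bad_src)) {
    stop("unknown annotation sources: ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  known <- annotations$cas %in% cas_all
  rejects <- annotations[!known, , drop = FALSE]
  ann <- annotations[known, , drop = FALSE]

  # expand each annotation to its endpoint(s)
  if (nrow(ann)) {
    eps <- lapply(seq_len(nrow(ann)), function(r)
      map_hazard_to_endpoint(ann$source[r], ann$hazard_code[r], mapping))
    reps <- lengths(eps)
    mapped <- data.frame(
      cas = rep(ann$cas, reps),
      source = rep(ann$source, reps),
      polarity = rep(ann$polarity, reps),
      endpoint = unlist(eps),
      stringsAsFactors = FALSE
    )
  } else {
    mapped <- data.frame(cas = character(), source = character(),
                         polarity = character(), endpoint = character())
  }

  out <- expand.grid(cas = cas_all, endpoint = ENDPOINTS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$cas, cas_all), match(out$endpoint, ENDPOINTS)), ]
  groups <- split(mapped[, c("source", "polarity")],
                  paste(mapped$cas, mapped$endpoint, sep = "\r"))
  out_key <- paste(out$cas, out$endpoint, sep = "\r")
  out$value <- vapply(out_key, function(k) {
    integrate_endpoint_label(groups[[k]])
  }, character(1), USE.NAMES = FALSE)
  out$provenance <- "integrated"
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Read an annotations CSV
#'
#' @param path CSV with columns `cas`, `source`, `hazard_code`, `polarity`.
#' @return data frame.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cas", "source", "hazard_code", "polarity")
  if (!all(need %in% names(df))) {
    stop("annotations CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
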