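#' Molecular consequence classes
#'
#' The closed set of molecular classes inferred from transcript-level HGVS
#' descriptions by [classify_molecular_class()].
#'
#' @return Character vector of valid class names.
#' @export
molecular_classes <- function() {
  c("missense", "nonsense", "frameshift_insertion", "frameshift_deletion",
    "canonical_splice", "intronic_near_splice", "synonymous", "other")
}

#' Normalise an HGVS string
#'
#' Printed variant tables are typographically noisy: en/em dashes for the
#' intron-offset minus sign, minus signs from PDF extraction, spaces around
#' `>` and `_`, and hyphens where `_` is meant in insertion ranges. All
#' spellings of the same description must key identically.
#'
#' @param x character vector of HGVS `c.` or `p.` strings.
#' @return Character vector with whitespace stripped and dash variants mapped
#'   to ASCII hyphen; `NA` and empty/`"-"`/em-dash placeholders become `NA`.
#' @export
#' @examples
#' normalize_hgvs("c.611–2A > T")  # "c.611-2A>T"
normalize_hgvs <- function(x) {
  if (is.null(x)) return(NA_character_)
  x <- gsub("[–—−]", "-", as.character(x))
  x <- gsub("\\s+", "", x)
  # printed insertion ranges sometimes use '-' where HGVS requires '_'
  x <- sub("^(c\\.\\d+)-(\\d+(ins|del|dup))", "\\1_\\2", x)
  x[!nzchar(x) | x %in% c("-", "—", "NA")] <- NA_character_
  x
}

# Parse the cDNA subset used by this pipeline. Returns a list describing the
# event, or stops with the offending token. Supported: substitutions
# (c.988G>T, c.511+8C>A), dup/ins/del (c.805dupC, c.1716_1717insT,
# c.5888delG), with optional intron offsets.
parse_cdna <- function(cdna) {
  x <- normalize_hgvs(cdna)
  if (is.na(x)) stop("cDNA HGVS is missing", call. = FALSE)
  if (!startsWith(x, "c.")) {
    stop(sprintf("unparsable HGVS token: '%s' (expected 'c.' prefix)", x),
         call. = FALSE)
  }
  body <- substring(x, 3L)

  sub_re <- "^(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$"
  if (grepl(sub_re, body)) {
    m <- regmatches(body, regexec(sub_re, body))[[1]]
    off <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    return(list(kind = "substitution", pos = as.integer(m[2]), offset = off,
                ref = m[4], alt = m[5]))
  }

  indel_re <- "^(\\d+)([+-]\\d+)?(_(\\d+)([+-]\\d+)?)?(dup|ins|del|delins)([ACGT]*)$"
  if (grepl(indel_re, body)) {
    m <- regmatches(body, regexec(indel_re, body))[[1]]
    off <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    kind <- m[7]
    if (kind == "delins") return(list(kind = "delins", pos = as.integer(m[2]), offset = off))
    return(list(kind = kind, pos = as.integer(m[2]), offset = off, seq = m[8]))
  }

  stop(sprintf("unparsable HGVS token: '%s'", x), call. = FALSE)
}

# Parse the protein subset used here: p.Xxx123Yyy, p.Trp1389Ter / p.W1416*,
# p.Leu269ProfsTer2, p.Leu100=. Returns NULL for absent input.
parse_protein <- function(protein) {
  x <- normalize_hgvs(protein)
  if (is.na(x)) return(NULL)
  x <- sub("^p\\.\\(?", "", sub("\\)$", "", x))
  if (grepl("fs", x)) return(list(kind = "frameshift"))
  aa <- "([A-Z][a-z]{2}|[A-Z])"
  stop_re <- paste0("^", aa, "(\\d+)(Ter|\\*)$")
  if (grepl(stop_re, x)) return(list(kind = "stop_gained"))
  syn_re <- paste0("^", aa, "(\\d+)=$")
  if (grepl(syn_re, x)) return(list(kind = "synonymous"))
  sub_re <- paste0("^", aa, "(\\d+)", aa, "$")
  if (grepl(sub_re, x)) {
    m <- regmatches(x, regexec(sub_re, x))[[1]]
    kind <- if (identical(m[2], m[4])) "synonymous" else "substitution"
    return(list(kind = kind, ref = m[2], alt = m[4]))
  }
  stop(sprintf("unparsable protein HGVS token: '%s'", protein), call. = FALSE)
}

#' Infer the molecular class of a variant from its HGVS descriptions
#'
#' Deterministic rule-based inference over the HGVS dialect that appears in
#' clinical deafness-gene variant tables: a frameshift marker in the protein
#' description wins (split into insertion/deletion by the cDNA event), then a
#' stop gain, then intron offsets (canonical splice site at |offset| <= 2,
#' near-splice intronic beyond), then single-residue substitutions
#' (missense/synonymous). Anything outside the dialect (e.g. `delins`) is
#' returned as `"other"` with a warning, never silently guessed.
#'
#' @param cdna HGVS `c.` description (single allele).
#' @param protein HGVS `p.` description, or `NA`/`NULL` when the variant has
#'   no annotated protein consequence (intronic changes).
#' @return One of [molecular_classes()].
#' @export
#' @examples
#' classify_molecular_class("c.805dupC", "p.Leu269ProfsTer2")  # frameshift_insertion
#' classify_molecular_class("c.611-2A>T", NA)                  # canonical_splice
#' classify_molecular_class("c.988G>T", "p.Gly330Trp")         # missense
classify_molecular_class <- function(cdna, protein = NULL) {
  cd <- parse_cdna(cdna)
  pr <- parse_protein(protein)

  if (!is.null(pr) && pr$kind == "frameshift") {
    if (cd$kind %in% c("dup", "ins")) return("frameshift_insertion")
    if (cd$kind == "del") return("frameshift_deletion")
    warning(sprintf("frameshift protein consequence with cDNA event '%s'; class 'other'",
                    cd$kind))
    return("other")
  }
  if (!is.null(pr) && pr$kind == "stop_gained") return("nonsense")

  if (cd$kind == "substitution" && cd$offset != 0L && is.null(pr)) {
    return(if (abs(cd$offset) <= 2L) "canonical_splice" else "intronic_near_splice")
  }
  if (cd$kind == "substitution") {
    if (!is.null(pr) && pr$kind == "synonymous") return("synonymous")
    if (!is.null(pr) && pr$kind == "substitution") return("missense")
    if (identical(cd$ref, cd$alt)) return("synonymous")
    warning(sprintf("exonic substitution '%s' without protein consequence; class 'other'",
                    cdna))
    return("other")
  }
  warning(sprintf("cDNA event '%s' outside the supported dialect; class 'other'", cd$kind))
  "other"
}

#' Is a molecular class truncating?
#'
#' Truncating convention used for patient genotype grouping: stop gains,
#' frameshifts and all splice-region variants (canonical sites and near-splice
#' intronic) count as truncating; missense and synonymous do not. Splice-region
#' assignment is the unique simple convention under which the case-study
#' cohort's printed patient-level 7/12/2 truncating split is reproduced (see
#' the methods vignette). Individual variants can be overridden via
#' `override`.
#'
#' @param molecular_class one of [molecular_classes()] (vectorised).
#' @param override optional logical vector (or single value); non-`NA` entries
#'   replace the rule's verdict.
#' @return Logical vector.
#' @export
is_truncating <- function(molecular_class, override = NA) {
  truncating <- c("nonsense", "frameshift_insertion", "frameshift_deletion",
                  "canonical_splice", "intronic_near_splice")
  non_truncating <- c("missense", "synonymous")
  override <- rep_len(override, length(molecular_class))
  out <- logical(length(molecular_class))
  for (i in seq_along(molecular_class)) {
    if (!is.na(override[i])) { out[i] <- override[i]; next }
    cl <- molecular_class[i]
    if (cl %in% truncating) out[i] <- TRUE
    else if (cl %in% non_truncating) out[i] <- FALSE
    else stop(sprintf("class '%s' has no default truncating status; supply an explicit override", cl),
              call. = FALSE)
  }
  out
}
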