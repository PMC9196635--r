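#' @name acmg
#' @title ACMG/AMP evidence-code combining
#'
#' @description
#' Evidence codes (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7) are parsed
#' from `+`-delimited strings and combined into the five-tier classification
#' (Pathogenic, Likely Pathogenic, Uncertain Significance, Likely Benign,
#' Benign). Code *assignment* is upstream curation and is never computed here;
#' the engine only combines.
NULL

.acmg_ranges <- list(PVS = 1L, PS = 4L, PM = 6L, PP = 5L, BA = 1L, BS = 4L, BP = 7L)

.acmg_labels <- c("Pathogenic", "Likely Pathogenic", "Uncertain Significance",
                  "Likely Benign", "Benign")

#' Parse an ACMG/AMP evidence-code string
#'
#' @param code_string a string such as `"PVS1+PM2+PP3"`; tokens are
#'   case-insensitive and order-free. An empty string or `NA` yields an empty
#'   code set (classified Uncertain Significance).
#' @return A character vector of canonical codes with class
#'   `"acmg_codes"`.
#' @details Unknown tokens (`"PX9"`), out-of-range indices (`"PVS2"`) and
#'   duplicated identical codes are errors. PP5/BP6 (reputable-source codes)
#'   are accepted at ordinary supporting strength because published variant
#'   tables use them.
#' @export
#' @examples
#' parse_codes("PVS1+PM2+PP3")
parse_codes <- function(code_string) {
  if (length(code_string) != 1L) stop("parse_codes() takes a single string")
  if (is.na(code_string) || !nzchar(trimws(code_string))) {
    return(structure(character(0), class = "acmg_codes"))
  }
  tokens <- toupper(trimws(strsplit(code_string, "+", fixed = TRUE)[[1]]))
  tokens <- tokens[nzchar(tokens)]
  re <- "^(PVS|PS|PM|PP|BA|BS|BP)([0-9]+)$"
  bad <- tokens[!grepl(re, tokens)]
  if (length(bad)) {
    stop(sprintf("unknown ACMG evidence code token(s): %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  cat_ <- sub(re, "\\1", tokens)
  idx <- as.integer(sub(re, "\\2", tokens))
  out_of_range <- idx < 1L | idx > unlist(.acmg_ranges)[cat_]
  if (any(out_of_range)) {
    stop(sprintf("ACMG code index out of published range: %s",
                 paste(sQuote(tokens[out_of_range]), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(tokens)) {
    stop(sprintf("duplicated evidence code(s): %s",
                 paste(sQuote(unique(tokens[duplicated(tokens)])), collapse = ", ")),
         call. = FALSE)
  }
  structure(sort(tokens), class = "acmg_codes")
}

# category counts for a parsed code set
.acmg_counts <- function(codes) {
  cat_ <- sub("^(PVS|PS|PM|PP|BA|BS|BP).*$", "\\1", unclass(codes))
  counts <- table(factor(cat_, levels = names(.acmg_ranges)))
  as.list(as.integer(counts)) |> stats::setNames(names(.acmg_ranges))
}

# Combining table on category counts. Exposed (unexported) so the oracle in
# the test suite can cross-check a structurally different implementation.
combine_counts <- function(nPVS, nPS, nPM, nPP, nBA, nBS, nBP) {
  pathogenic <-
    (nPVS >= 1 && (nPS >= 1 || nPM >= 2 || (nPM >= 1 && nPP >= 1) || nPP >= 2)) ||
    nPS >= 2 ||
    (nPS == 1 && (nPM >= 3 || (nPM == 2 && nPP >= 2) || (nPM == 1 && nPP >= 4)))
  likely_pathogenic <- !pathogenic && (
    (nPVS >= 1 && nPM >= 1) ||
    (nPS == 1 && nPM >= 1) ||
    (nPS == 1 && nPP >= 2) ||
    nPM >= 3 ||
    (nPM == 2 && nPP >= 2) ||
    (nPM == 1 && nPP >= 4))
  path_label <- if (pathogenic) "Pathogenic" else if (likely_pathogenic)
    "Likely Pathogenic" else "Uncertain Significance"

  benign <- nBA >= 1 || nBS >= 2
  likely_benign <- !benign && ((nBS == 1 && nBP >= 1) || nBP >= 2)
  benign_label <- if (benign) "Benign" else if (likely_benign)
    "Likely Benign" else "Uncertain Significance"

  any_path_codes <- (nPVS + nPS + nPM + nPP) > 0
  any_benign_codes <- (nBA + nBS + nBP) > 0

  # Conflict resolution: two decisive sides always conflict to VUS. A side at
  # full strength (Pathogenic / Benign) stands even when weak opposite-side
  # codes are present; a "Likely" call is demoted to VUS by any opposite-side
  # evidence. Reproduces e.g. PM2+BP4+BP6 -> VUS while PP2+BS1+BS2+BP4 -> Benign.
  if (path_label != "Uncertain Significance" && benign_label != "Uncertain Significance")
    return("Uncertain Significance")
  if (path_label == "Pathogenic") return("Pathogenic")
  if (path_label == "Likely Pathogenic")
    return(if (any_benign_codes) "Uncertain Significance" else "Likely Pathogenic")
  if (benign_label == "Benign") return("Benign")
  if (benign_label == "Likely Benign")
    return(if (any_path_codes) "Uncertain Significance" else "Likely Benign")
  "Uncertain Significance"
}

#' Combine a parsed evidence-code set into a five-tier classification
#'
#' Pathogenic-side and benign-side rules are evaluated independently on
#' category counts; conflicts between the sides resolve to Uncertain
#' Significance (see Details). The function is total: any valid code set,
#' including the empty set, yields exactly one label.
#'
#' @details Pathogenic iff PVS1 with (>=1 PS | >=2 PM | 1 PM + 1 PP | >=2 PP),
#' or >=2 PS, or 1 PS with (>=3 PM | 2 PM + >=2 PP | 1 PM + >=4 PP). Likely
#' Pathogenic iff (not Pathogenic and) PVS1 + >=1 PM, 1 PS + >=1 PM,
#' 1 PS + >=2 PP, >=3 PM, 2 PM + >=2 PP, or 1 PM + >=4 PP. Benign iff BA1 or
#' >=2 BS; Likely Benign iff 1 BS + 1 BP or >=2 BP. When both sides are
#' decisive the result is Uncertain Significance; a "Likely" verdict on one
#' side is additionally demoted to Uncertain Significance whenever any
#' opposite-side codes are present, while a full-strength verdict stands.
#'
#' @param codes an `"acmg_codes"` object from [parse_codes()], or a string.
#' @return One of `"Pathogenic"`, `"Likely Pathogenic"`,
#'   `"Uncertain Significance"`, `"Likely Benign"`, `"Benign"`.
#' @export
#' @examples
#' combine_codes(parse_codes("PVS1+PM2+PP3"))  # "Pathogenic"
#' combine_codes("PM2+BP4+BP6")                # "Uncertain Significance"
combine_codes <- function(codes) {
  if (is.character(codes) && !inherits(codes, "acmg_codes")) codes <- parse_codes(codes)
  n <- .acmg_counts(codes)
  combine_counts(n$PVS, n$PS, n$PM, n$PP, n$BA, n$BS, n$BP)
}

#' Classify a variant table by its evidence-code strings
#'
#' @param variants data frame with columns `variant_id` and `codes`
#'   (`+`-delimited evidence-code strings).
#' @return The input with a `classification` column added; the tally over any
#'   subset is available via `table()`.
#' @export
classify_variants <- function(variants) {
  stopifnot(is.data.frame(variants), all(c("variant_id", "codes") %in% names(variants)))
  variants$classification <- vapply(seq_len(nrow(variants)), function(i) {
    tryCatch(combine_codes(variants$codes[i]), error = function(e) {
      stop(sprintf("variant '%s': %s", variants$variant_id[i], conditionMessage(e)),
           call. = FALSE)
    })
  }, character(1))
  variants
}

#' Tally classification labels
#'
#' @param classification character vector of five-tier labels.
#' @return Named integer vector over the five labels (zeros kept).
#' @export
classification_tally <- function(classification) {
  tab <- table(factor(classification, levels = .acmg_labels))
  stats::setNames(as.integer(tab), names(tab))
}
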