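#' Build a trio call table
#'
#' One row per variant observed in a proband, with parental carriage from
#' Sanger validation or a trio VCF. `in_mother`/`in_father` are `NA` when that
#' parent's sample was unavailable.
#'
#' @param variant_id variant keys.
#' @param gene gene symbol per variant.
#' @param child_zygosity `"het"` or `"hom"`.
#' @param in_mother,in_father logical or `NA` (parent not genotyped).
#' @param trio_id optional trio/proband identifier.
#' @return data frame of class `"trio_calls"`.
#' @export
trio_calls <- function(variant_id, gene, child_zygosity, in_mother, in_father,
                       trio_id = "trio1") {
  stopifnot(all(child_zygosity %in% c("het", "hom")))
  if (!length(variant_id)) trio_id <- character(0)
  df <- data.frame(trio_id = trio_id, variant_id = variant_id, gene = gene,
                   child_zygosity = child_zygosity,
                   in_mother = as.logical(in_mother),
                   in_father = as.logical(in_father),
                   stringsAsFactors = FALSE)
  class(df) <- c("trio_calls", "data.frame")
  df
}

#' Phase a pair of heterozygous variants from parental carriage
#'
#' With both variants heterozygous in the child: if each is carried by a
#' different single parent the pair is in trans; if both are carried by the
#' same single parent (and absent from the other) the child's single
#' transmitted haplotype from that parent must carry both, so the pair is in
#' cis; any ambiguity (a variant present in both parents, or a missing
#' parent) leaves the phase unknown. A variant absent from both genotyped
#' parents is flagged apparent de novo (attribute `de_novo`), phase unknown.
#'
#' @param callA,callB single rows of a [trio_calls()] table (het in child).
#' @return `"trans"`, `"cis"` or `"unknown"`.
#' @export
phase_pair <- function(callA, callB) {
  stopifnot(callA$child_zygosity == "het", callB$child_zygosity == "het")
  origin <- function(call) {
    m <- call$in_mother; f <- call$in_father
    if (!is.na(m) && !is.na(f) && !m && !f) return("de_novo")
    if (isTRUE(m) && identical(f, FALSE)) return("mother")
    if (isTRUE(f) && identical(m, FALSE)) return("father")
    "ambiguous"  # present in both, or a parent missing
  }
  oa <- origin(callA); ob <- origin(callB)
  if (oa == "de_novo" || ob == "de_novo")
    return(structure("unknown", de_novo = TRUE))
  if (oa %in% c("mother", "father") && ob %in% c("mother", "father")) {
    return(if (oa == ob) "cis" else "trans")
  }
  "unknown"
}

#' Select candidate genotypes from trio calls
#'
#' Candidate disease genotypes for a sporadic proband under the autosomal
#' recessive and de-novo dominant models:
#' \itemize{
#'   \item `AR_hom`: child homozygous, every genotyped parent a carrier;
#'   \item `AR_comphet`: two heterozygous variants in one gene, in trans when
#'     both parents are genotyped, or phase-unresolved with a missing parent;
#'   \item `AD_denovo`: child heterozygous, variant absent from both
#'     genotyped parents.
#' }
#' `segregation_status` is `"confirmed"` with both parents genotyped,
#' `"partial"` with one missing, `"unconfirmed"` with both missing. Variants
#' fitting no model are dropped; a homozygous child with a genotyped
#' non-carrier parent is reported in the `inconsistencies` attribute (possible
#' genotyping error or uniparental event), never silently dropped.
#'
#' @param calls a [trio_calls()] table for one proband.
#' @return data frame of candidate genotypes, one row per genotype, with
#'   columns `gene`, `allele1`, `allele2`, `model`, `phase`,
#'   `segregation_status`; attribute `inconsistencies` lists Mendelian
#'   conflicts.
#' @export
select_candidates <- function(calls) {
  stopifnot(is.data.frame(calls))
  out <- list(); inconsistent <- character(0)
  status_of <- function(m, f) {
    miss <- is.na(m) + is.na(f)
    c("confirmed", "partial", "unconfirmed")[miss + 1L]
  }
  for (g in unique(calls$gene)) {
    gc <- calls[calls$gene == g, , drop = FALSE]
    homs <- gc[gc$child_zygosity == "hom", , drop = FALSE]
    hets <- gc[gc$child_zygosity == "het", , drop = FALSE]

    for (i in seq_len(nrow(homs))) {
      h <- homs[i, ]
      if (identical(h$in_mother, FALSE) || identical(h$in_father, FALSE)) {
        inconsistent <- c(inconsistent, h$variant_id)  # de novo hom or error
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        trio_id = h$trio_id, gene = g, allele1 = h$variant_id, allele2 = h$variant_id,
        model = "AR_hom", phase = "hom",
        segregation_status = status_of(h$in_mother, h$in_father),
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(nrow(hets))) {
      h <- hets[i, ]
      if (identical(h$in_mother, FALSE) && identical(h$in_father, FALSE)) {
        out[[length(out) + 1L]] <- data.frame(
          trio_id = h$trio_id, gene = g, allele1 = h$variant_id, allele2 = NA_character_,
          model = "AD_denovo", phase = NA_character_,
          segregation_status = "confirmed", stringsAsFactors = FALSE)
      }
    }

    if (nrow(hets) >= 2) {
      idx <- utils::combn(nrow(hets), 2)
      for (k in seq_len(ncol(idx))) {
        a <- hets[idx[1, k], ]; b <- hets[idx[2, k], ]
        ph <- phase_pair(a, b)
        if (ph == "cis") next
        if (ph == "unknown" && isTRUE(attr(ph, "de_novo"))) ph <- "unknown"
        out[[length(out) + 1L]] <- data.frame(
          trio_id = a$trio_id, gene = g, allele1 = a$variant_id, allele2 = b$variant_id,
          model = "AR_comphet", phase = as.character(ph),
          segregation_status = min_status(status_of(a$in_mother, a$in_father),
                                          status_of(b$in_mother, b$in_father)),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trio_id = character(0), gene = character(0), allele1 = character(0),
               allele2 = character(0), model = character(0), phase = character(0),
               segregation_status = character(0), stringsAsFactors = FALSE)
  attr(res, "inconsistencies") <- inconsistent
  res
}

# worst of two segregation statuses
min_status <- function(a, b) {
  lv <- c(confirmed = 1L, partial = 2L, unconfirmed = 3L)
  names(lv)[max(lv[a], lv[b])]
}

#' Exclude cis passenger alleles from a resolved genotype
#'
#' After a causative pair is resolved, remaining heterozygous alleles in the
#' same gene are passengers if they travel on a haplotype already occupied by
#' a causative allele: an extra allele carried exclusively by one genotyped
#' unaffected parent who also transmits a causative allele is in cis with it
#' (or, for a homozygous causative genotype, redundant to it) and is moved to
#' `excluded_cis`. Extras in trans with both causative alleles, or of unknown
#' phase, are retained with a warning -- they may be independently relevant.
#'
#' @param genotype one-row candidate genotype (from [select_candidates()]).
#' @param extra_calls [trio_calls()] rows for the extra heterozygous alleles.
#' @param causative_calls [trio_calls()] rows for the causative pair.
#' @return `genotype` with list-columns `excluded_cis` and `retained_extra`.
#' @export
exclude_cis_passenger <- function(genotype, extra_calls, causative_calls) {
  excluded <- character(0); retained <- character(0)
  for (i in seq_len(nrow(extra_calls))) {
    e <- extra_calls[i, ]
    is_cis <- FALSE
    if (genotype$model == "AR_hom") {
      # both parental haplotypes already carry the causative allele; an extra
      # inherited from a single genotyped parent is necessarily cis to one copy
      single_parent <- (isTRUE(e$in_mother) && identical(e$in_father, FALSE)) ||
                       (isTRUE(e$in_father) && identical(e$in_mother, FALSE))
      is_cis <- single_parent
    } else {
      for (j in seq_len(nrow(causative_calls))) {
        if (causative_calls$child_zygosity[j] != "het") next
        if (identical(phase_pair(e, causative_calls[j, ]), "cis")) is_cis <- TRUE
      }
    }
    if (is_cis) excluded <- c(excluded, e$variant_id)
    else {
      retained <- c(retained, e$variant_id)
      warning(sprintf("extra allele '%s' is not phased cis to the causative genotype; retained",
                      e$variant_id))
    }
  }
  genotype$excluded_cis <- I(list(excluded))
  genotype$retained_extra <- I(list(retained))
  genotype
}

#' Rank candidate genotypes across genes by allele classification strength
#'
#' Classification strengths Pathogenic 5 > Likely Pathogenic 4 > Uncertain
#' Significance 3 > Likely Benign 2 > Benign 1; each genotype scores as its
#' sorted (descending) pair of allele strengths and genotypes are compared
#' lexicographically, so any genotype with a Pathogenic/Likely Pathogenic
#' allele outranks an all-VUS genotype. Exact ties are reported as unresolved
#' (`tie` column), never broken arbitrarily.
#'
#' @param candidates candidate genotype data frame ([select_candidates()]).
#' @param classifications named character vector mapping `variant_id` to a
#'   five-tier label.
#' @return `candidates` ordered best-first with `score1`, `score2`, `rank` and
#'   `tie` columns; empty input yields empty output.
#' @export
adjudicate_causative_gene <- function(candidates, classifications) {
  if (!nrow(candidates)) {
    candidates$score1 <- numeric(0); candidates$score2 <- numeric(0)
    candidates$rank <- integer(0); candidates$tie <- logical(0)
    return(candidates)
  }
  strength <- c("Pathogenic" = 5, "Likely Pathogenic" = 4,
                "Uncertain Significance" = 3, "Likely Benign" = 2, "Benign" = 1)
  score <- function(a1, a2) {
    s <- strength[classifications[c(a1, a2)]]
    if (anyNA(s))
      stop(sprintf("missing classification for allele(s) of genotype %s/%s", a1, a2),
           call. = FALSE)
    sort(unname(s), decreasing = TRUE)
  }
  sc <- t(vapply(seq_len(nrow(candidates)), function(i) {
    a2 <- candidates$allele2[i]
    if (is.na(a2)) a2 <- candidates$allele1[i]  # de novo: single allele counted once
    score(candidates$allele1[i], a2)
  }, numeric(2)))
  candidates$score1 <- sc[, 1]; candidates$score2 <- sc[, 2]
  ord <- order(-candidates$score1, -candidates$score2)
  candidates <- candidates[ord, , drop = FALSE]
  key <- paste(candidates$score1, candidates$score2)
  candidates$rank <- match(key, unique(key))
  candidates$tie <- duplicated(key) | duplicated(key, fromLast = TRUE)
  rownames(candidates) <- NULL
  candidates
}

#' Segregate every trio of a cohort
#'
#' Applies [select_candidates()] per trio and stacks the results.
#'
#' @param calls a [trio_calls()] table with a `trio_id` column covering many
#'   probands.
#' @return Candidate genotype data frame over all trios; attribute
#'   `inconsistencies` is the union of per-trio Mendelian conflicts.
#' @export
segregate_cohort <- function(calls) {
  pieces <- lapply(split(calls, calls$trio_id), select_candidates)
  if (!length(pieces)) pieces <- list(select_candidates(calls))
  res <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  attr(res, "inconsistencies") <-
    unlist(lapply(pieces, attr, "inconsistencies"), use.names = FALSE)
  res
}
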