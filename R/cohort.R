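#' Half-up rounding at a fixed number of decimals
#'
#' Published cohort percentages use conventional half-up rounding (0.5 rounds
#' away from zero), not the round-half-even of [base::round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

#' Cohort prevalence of solved cases
#'
#' @param n_solved patients with a resolved causative genotype.
#' @param n_cohort patients screened.
#' @param digits decimals of the reported percent (default 2).
#' @return Percent, half-up rounded.
#' @export
#' @examples
#' prevalence(21, 2901)  # 0.72
prevalence <- function(n_solved, n_cohort, digits = 2) {
  stopifnot(n_cohort > 0, n_solved >= 0, n_solved <= n_cohort)
  round_half_up(100 * n_solved / n_cohort, digits)
}

#' Cohort allele frequency of a variant
#'
#' Causative allele count over twice the number of screened patients (alleles
#' per diploid genome): a heterozygote contributes one allele, a homozygote
#' two, and cis-excluded passenger alleles contribute zero (they are not part
#' of any causative genotype; the report flags this convention).
#'
#' @param patients patient data frame with `allele1`/`allele2` columns.
#' @param variant_id variant key.
#' @param n_cohort patients screened (denominator is `2 * n_cohort`).
#' @param digits decimals of the percent (default 4).
#' @return List with `count`, `denominator`, `percent`.
#' @export
#' @examples
#' cohort_allele_frequency(loxhd1_patients(), "c.5888delG", 2901)  # 5 / 5802
cohort_allele_frequency <- function(patients, variant_id, n_cohort, digits = 4) {
  count <- sum(patients$allele1 == variant_id) + sum(patients$allele2 == variant_id)
  denom <- 2L * n_cohort
  list(count = as.integer(count), denominator = denom,
       percent = round_half_up(100 * count / denom, digits))
}

#' Recurrent variants of a cohort
#'
#' Variants whose causative alleles are observed in at least `min_patients`
#' unrelated patients. Homozygosity within a single patient does not by
#' itself make a variant recurrent.
#'
#' @param patients patient data frame with `allele1`/`allele2`.
#' @param min_patients minimum number of distinct carriers (default 2).
#' @return Sorted character vector of variant ids.
#' @export
recurrent_variants <- function(patients, min_patients = 2) {
  carriers <- rbind(data.frame(patient_id = patients$patient_id, v = patients$allele1),
                    data.frame(patient_id = patients$patient_id, v = patients$allele2))
  carriers <- unique(carriers)
  tab <- table(carriers$v)
  sort(names(tab)[tab >= min_patients])
}

#' Onset-age distribution
#'
#' Count and proportion of patients with onset at or below the
#' congenital/prelingual cutoff (default 3 years).
#'
#' @param patients patient data frame with `onset_age`.
#' @param congenital_cutoff years (default 3).
#' @param digits decimals of the percent (default 1).
#' @return List with `count`, `n`, `percent`.
#' @export
#' @examples
#' onset_distribution(loxhd1_patients())  # 19 of 21, 90.5%
onset_distribution <- function(patients, congenital_cutoff = 3, digits = 1) {
  stopifnot(!anyNA(patients$onset_age))
  count <- sum(patients$onset_age <= congenital_cutoff)
  n <- nrow(patients)
  list(count = as.integer(count), n = n,
       percent = round_half_up(100 * count / n, digits))
}

# domain label -> "P" (inside a PLAT repeat) or "I" (inter-repeat interval)
domain_side <- function(label) {
  if (any(is.na(label) | !nzchar(label)))
    stop("missing domain label", call. = FALSE)
  ifelse(grepl("^PLAT([1-9]|1[0-5])$", label), "P",
         ifelse(grepl("^Interval", label), "I", NA_character_))
}

#' Patient genotype grouping by PLAT-domain location
#'
#' Groups each solved patient by whether the two causative alleles fall inside
#' PLAT repeats (`PP`), one inside and one in an inter-repeat interval (`PI`),
#' or both in intervals (`II`). Homozygotes contribute the same label twice;
#' cis-excluded alleles are ignored.
#'
#' @param patients patient data frame with `allele1`/`allele2`.
#' @param variants variant table with `variant_id` and `domain`.
#' @return Named integer vector `c(PP=, PI=, II=)`.
#' @export
domain_groups <- function(patients, variants) {
  side <- stats::setNames(domain_side(variants$domain), variants$variant_id)
  lookup <- function(id) {
    s <- side[id]
    if (anyNA(s)) stop(sprintf("variant '%s' lacks a PLAT/interval domain label",
                               paste(id[is.na(s)], collapse = ", ")), call. = FALSE)
    s
  }
  g <- vapply(seq_len(nrow(patients)), function(i) {
    s <- sort(lookup(c(patients$allele1[i], patients$allele2[i])))
    paste(s, collapse = "")  # "PP", "IP" or "II"
  }, character(1))
  c(PP = sum(g == "PP"), PI = sum(g == "IP"), II = sum(g == "II"))
}

#' Patient genotype grouping by truncating status
#'
#' Groups each solved patient by the truncating status of the two causative
#' alleles: both truncating (`TT`), mixed (`NT_T`), both non-truncating
#' (`NT_NT`), under the [is_truncating()] convention.
#'
#' @param patients patient data frame with `allele1`/`allele2`.
#' @param variants variant table with `variant_id` and `molecular_class`.
#' @return Named integer vector `c(TT=, NT_T=, NT_NT=)`.
#' @export
truncation_groups <- function(patients, variants) {
  trunc <- stats::setNames(is_truncating(variants$molecular_class), variants$variant_id)
  g <- vapply(seq_len(nrow(patients)), function(i) {
    tr <- trunc[c(patients$allele1[i], patients$allele2[i])]
    if (anyNA(tr)) stop(sprintf("patient %s carries an allele without a resolved class",
                                patients$patient_id[i]), call. = FALSE)
    sum(tr)
  }, numeric(1))
  c(TT = sum(g == 2), NT_T = sum(g == 1), NT_NT = sum(g == 0))
}

#' Variant-type spectrum
#'
#' Counts of molecular classes over a subset of the variant table, optionally
#' collapsing the two splice-region classes into a single `splicing` category
#' (the usual presentation of variant spectra).
#'
#' @param variants variant table with `variant_id` and `molecular_class`.
#' @param subset optional vector of variant ids (default: all).
#' @param collapse_splicing merge `canonical_splice` and
#'   `intronic_near_splice` into `splicing`.
#' @return Named integer vector of counts (zero classes dropped).
#' @export
type_spectrum <- function(variants, subset = NULL, collapse_splicing = TRUE) {
  cls <- variants$molecular_class
  if (!is.null(subset)) cls <- cls[variants$variant_id %in% subset]
  if (collapse_splicing)
    cls[cls %in% c("canonical_splice", "intronic_near_splice")] <- "splicing"
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' Full cohort summary
#'
#' Assembles every cohort-level statistic: prevalence, per-variant cohort
#' allele frequencies, recurrent variants, onset distribution, domain and
#' truncation genotype groupings, and the variant-type spectrum.
#'
#' @param patients solved patient records (e.g. [loxhd1_patients()]).
#' @param variants variant table with `domain`, `molecular_class`, `codes`
#'   (e.g. [loxhd1_variants()]).
#' @param n_cohort number of patients screened.
#' @param congenital_cutoff onset cutoff in years for the congenital band.
#' @param audiograms optional long audiogram table; when given, audiogram
#'   configuration counts (per-patient symmetry x shape) are included.
#' @return A list of class `"cohort_summary"`.
#' @export
cohort_summary <- function(patients, variants, n_cohort,
                           congenital_cutoff = 3, audiograms = NULL) {
  used <- sort(unique(c(patients$allele1, patients$allele2)))
  af <- do.call(rbind, lapply(used, function(v) {
    x <- cohort_allele_frequency(patients, v, n_cohort)
    data.frame(variant_id = v, count = x$count, denominator = x$denominator,
               percent = x$percent, stringsAsFactors = FALSE)
  }))
  onset <- onset_distribution(patients, congenital_cutoff)
  out <- list(
    n_cohort = n_cohort,
    n_solved = nrow(patients),
    prevalence_pct = prevalence(nrow(patients), n_cohort),
    allele_frequencies = af,
    recurrent = recurrent_variants(patients),
    onset = onset,
    domain_group_counts = as.list(domain_groups(patients, variants)),
    truncation_group_counts = as.list(truncation_groups(patients, variants)),
    type_spectrum = type_spectrum(variants),
    type_spectrum_novel = type_spectrum(variants, variants$variant_id[variants$novel]),
    notes = "cis-excluded passenger alleles contribute 0 to allele frequencies")
  if (!is.null(audiograms)) {
    ax <- assess_audiograms(audiograms)
    shape_at_visit <- patient_shape(ax)
    merged <- merge(ax$patients, shape_at_visit, by = "patient_id")
    out$audiogram_configurations <- merged
    n_avail <- nrow(merged)
    n_sym_down <- sum(merged$symmetry == "symmetric" & merged$shape == "down_sloping")
    out$symmetric_down_sloping <- list(
      count = as.integer(n_sym_down), n = n_avail,
      percent = round_half_up(100 * n_sym_down / n_avail, 1))
  }
  class(out) <- c("cohort_summary", "list")
  out
}

# per-patient shape label: the shape shared by both ears at the latest
# two-ear visit, or "mixed" when the ears disagree
patient_shape <- function(ax) {
  a <- ax$assessments
  res <- lapply(split(a, a$patient_id), function(g) {
    at <- g[g$visit_age == max(g$visit_age), ]
    sh <- unique(at$shape)
    data.frame(patient_id = g$patient_id[1],
               shape = if (length(sh) == 1) sh else "mixed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d/%d solved (prevalence %.2f%%)\n",
              x$n_solved, x$n_cohort, x$prevalence_pct))
  cat(sprintf("  onset <= cutoff: %d/%d (%.1f%%)\n",
              x$onset$count, x$onset$n, x$onset$percent))
  cat(sprintf("  recurrent variants: %s\n", paste(x$recurrent, collapse = ", ")))
  cat("  domain groups: ", paste(names(x$domain_group_counts),
                                 unlist(x$domain_group_counts), sep = "=", collapse = " "), "\n")
  cat("  truncation groups: ", paste(names(x$truncation_group_counts),
                                     unlist(x$truncation_group_counts), sep = "=", collapse = " "), "\n")
  if (!is.null(x$symmetric_down_sloping))
    cat(sprintf("  symmetric down-sloping: %d/%d (%.1f%%)\n",
                x$symmetric_down_sloping$count, x$symmetric_down_sloping$n,
                x$symmetric_down_sloping$percent))
  invisible(x)
}
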