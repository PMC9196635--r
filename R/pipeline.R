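#' Run the cohort analysis pipeline end to end
#'
#' Stages: variant classification (evidence-code combining + molecular-class
#' inference) -> per-trio segregation (candidate selection, phasing,
#' causative-gene adjudication, cis-passenger exclusion) -> audiogram
#' phenotyping -> cohort statistics. Inputs may come from
#' [simulate_cohort()], [fixture_cohort()], or files read with the `read_*`
#' functions and assembled into the same list shape.
#'
#' @param cohort list with `variants`, `calls`, optional `audiograms`,
#'   optional `secondary` (extra-gene variant codes), optional `truth`.
#' @param n_cohort denominator for prevalence and allele frequencies (number
#'   of patients screened); defaults to the number of trios in `calls`.
#' @param patient_meta optional data frame (`trio_id`, `onset_age`,
#'   `visit_age`) merged into resolved patients; required for onset
#'   statistics.
#' @param target_gene restrict solved status to genotypes in this gene
#'   (default `"LOXHD1"`); `NULL` accepts any gene.
#' @param congenital_cutoff onset cutoff (years) for the congenital band.
#' @param out_dir if non-`NULL`, the JSON report and TSV summaries are
#'   written there.
#' @return List with `patients` (resolved genotypes), `candidates` (all
#'   ranked candidate genotypes), `variants` (classified table), `summary`
#'   (a [cohort_summary()]), and `inconsistencies`.
#' @export
run_pipeline <- function(cohort, n_cohort = NULL, patient_meta = NULL,
                         target_gene = "LOXHD1", congenital_cutoff = 3,
                         out_dir = NULL) {
  variants <- classify_variants(cohort$variants)
  if (!"molecular_class" %in% names(variants) || anyNA(variants$molecular_class)) {
    variants$molecular_class <- vapply(seq_len(nrow(variants)), function(i)
      classify_molecular_class(variants$cdna[i], variants$protein[i]), character(1))
  }
  classifications <- stats::setNames(variants$classification, variants$variant_id)
  if (!is.null(cohort$secondary)) {
    sec <- classify_variants(cohort$secondary)
    classifications <- c(classifications,
                         stats::setNames(sec$classification, sec$variant_id))
  }

  calls <- cohort$calls
  if (is.null(n_cohort)) n_cohort <- length(unique(calls$trio_id))

  cands <- segregate_cohort(calls)
  resolved <- list(); ranked <- list()
  for (tid in unique(cands$trio_id)) {
    tc <- adjudicate_causative_gene(cands[cands$trio_id == tid, , drop = FALSE],
                                    classifications)
    ranked[[tid]] <- tc
    if (!nrow(tc)) next
    top <- tc[1, , drop = FALSE]
    if (!is.na(target_gene) && !is.null(target_gene) && top$gene != target_gene) next
    if (!top$model %in% c("AR_hom", "AR_comphet")) next

    trio_calls_here <- calls[calls$trio_id == tid & calls$gene == top$gene, , drop = FALSE]
    pair_ids <- unique(c(top$allele1, top$allele2))
    extras <- trio_calls_here[!trio_calls_here$variant_id %in% pair_ids &
                                trio_calls_here$child_zygosity == "het", , drop = FALSE]
    if (nrow(extras)) {
      top <- suppressWarnings(
        exclude_cis_passenger(top, extras,
                              trio_calls_here[trio_calls_here$variant_id %in% pair_ids, ,
                                              drop = FALSE]))
    } else {
      top$excluded_cis <- I(list(character(0)))
      top$retained_extra <- I(list(character(0)))
    }
    resolved[[length(resolved) + 1L]] <- top
  }
  patients <- if (length(resolved)) do.call(rbind, resolved) else NULL

  summary <- NULL
  if (!is.null(patients)) {
    patients$patient_id <- patients$trio_id
    if (!is.null(patient_meta)) {
      patients <- merge(patients, patient_meta, by = "trio_id", all.x = TRUE,
                        sort = FALSE)
    } else if (!is.null(cohort$truth)) {
      patients <- merge(patients,
                        cohort$truth[, intersect(c("trio_id", "onset_age"),
                                                 names(cohort$truth)), drop = FALSE],
                        by = "trio_id", all.x = TRUE, sort = FALSE)
    }
    has_onset <- "onset_age" %in% names(patients) && !anyNA(patients$onset_age)
    summary <- cohort_summary(
      patients,
      variants,
      n_cohort = n_cohort,
      congenital_cutoff = congenital_cutoff,
      audiograms = cohort$audiograms)
    if (!has_onset) summary$onset <- NULL
  } else {
    summary <- list(n_cohort = n_cohort, n_solved = 0L,
                    prevalence_pct = prevalence(0, n_cohort))
    class(summary) <- c("cohort_summary", "list")
  }

  out <- list(patients = patients, candidates = do.call(rbind, c(ranked, list(make.row.names = FALSE))),
              variants = variants, summary = summary,
              inconsistencies = attr(cands, "inconsistencies"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(strip_frames(summary), file.path(out_dir, "cohort_report.json"))
    if (!is.null(patients)) {
      flat <- patients
      flat$excluded_cis <- vapply(flat$excluded_cis, paste, "", collapse = ",")
      flat$retained_extra <- vapply(flat$retained_extra, paste, "", collapse = ",")
      utils::write.table(flat, file.path(out_dir, "patients.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
    }
    write_variant_table(variants, file.path(out_dir, "variants_classified.tsv"))
  }
  out
}

# data frames inside the summary are serialised row-wise for JSON
strip_frames <- function(summary) {
  s <- unclass(summary)
  s$allele_frequencies <- if (!is.null(s$allele_frequencies))
    lapply(seq_len(nrow(s$allele_frequencies)),
           function(i) as.list(s$allele_frequencies[i, ]))
  if (!is.null(s$audiogram_configurations))
    s$audiogram_configurations <- lapply(seq_len(nrow(s$audiogram_configurations)),
                                         function(i) as.list(s$audiogram_configurations[i, ]))
  s$type_spectrum <- as.list(s$type_spectrum)
  if (!is.null(s$type_spectrum_novel)) s$type_spectrum_novel <- as.list(s$type_spectrum_novel)
  s
}

#' Run the pipeline on the packaged case-study cohort
#'
#' Convenience entry point: the fixture cohort (files of record: 33 variants,
#' 21 trios, 15 patients' audiograms) through the full pipeline with the
#' study's screening denominator.
#'
#' @param n_cohort patients screened (default 2901).
#' @param out_dir optional output directory for the report.
#' @return As [run_pipeline()].
#' @export
run_fixture_pipeline <- function(n_cohort = 2901, out_dir = NULL) {
  fc <- fixture_cohort()
  fc$secondary <- loxhd1_secondary_variants()
  pts <- loxhd1_patients()
  meta <- data.frame(trio_id = paste0("P", pts$patient_id),
                     onset_age = pts$onset_age, visit_age = pts$visit_age,
                     stringsAsFactors = FALSE)
  run_pipeline(fc, n_cohort = n_cohort, patient_meta = meta, out_dir = out_dir)
}
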