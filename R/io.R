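#' Read and write the pipeline's tabular formats
#'
#' @description
#' Flat-file interfaces: a tab-separated variant table, a long-format
#' audiogram CSV, a 6-column PED file, a trio-calls TSV, and (optionally) a
#' minimal trio VCF. Readers validate mandatory columns and report row-level
#' errors with line numbers; writers round-trip (write then read yields equal
#' records) and unknown columns are preserved.
#'
#' @param path file path.
#' @name io
NULL

.variant_cols <- c("variant_id", "transcript", "cdna", "protein", "chrom", "pos",
                   "exon_intron", "domain", "codes", "classification_printed",
                   "novel", "origin")

#' @describeIn io Read a tab-separated variant table (columns `variant_id`,
#'   `transcript`, `cdna`, `protein`, `chrom`, `pos`, `exon_intron`, `domain`,
#'   `codes`, `classification_printed`, `novel`, `origin`; extra columns kept).
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  missing <- setdiff(.variant_cols, names(df))
  if (length(missing))
    stop(sprintf("variant table '%s' lacks mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  bad_pos <- which(!is.finite(df$pos) | df$pos <= 0)
  if (length(bad_pos))
    stop(sprintf("variant table '%s': non-positive or malformed pos at data line(s) %s",
                 path, paste(bad_pos, collapse = ", ")), call. = FALSE)
  df$novel <- as.logical(df$novel)
  df
}

#' @describeIn io Write a variant table as TSV.
#' @param variants,df,x object to write.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.audiogram_cols <- c("patient_id", "visit_age", "ear", "freq_hz", "threshold_db",
                     "no_response")

#' @describeIn io Read a long-format audiogram CSV (columns `patient_id`,
#'   `visit_age`, `ear`, `freq_hz`, `threshold_db`, `no_response`).
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.audiogram_cols, names(df))
  if (length(missing))
    stop(sprintf("audiogram table '%s' lacks mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df$no_response <- as.logical(df$no_response)
  bad <- which((!df$no_response & !is.finite(df$threshold_db)) |
                 (!df$no_response & (df$threshold_db < -10 | df$threshold_db > 130)) |
                 !(df$freq_hz %in% audiometric_frequencies()))
  if (length(bad))
    stop(sprintf("audiogram table '%s': malformed threshold or frequency at data line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  df
}

#' @describeIn io Write a long-format audiogram CSV.
#' @export
write_audiograms <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn io Read a standard 6-column PED file (family, individual,
#'   father, mother, sex, phenotype); `0` denotes a missing parent.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family_id", "individual_id", "father_id",
                                        "mother_id", "sex", "phenotype"))
  df
}

#' @describeIn io Write a PED file.
#' @param ped PED data frame.
#' @export
write_ped <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.calls_cols <- c("trio_id", "variant_id", "gene", "child_zygosity", "in_mother",
                 "in_father")

#' @describeIn io Read a trio-calls TSV (columns `trio_id`, `variant_id`,
#'   `gene`, `child_zygosity`, `in_mother`, `in_father`; parental carriage
#'   `TRUE`/`FALSE`/`NA`).
#' @export
read_trio_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  missing <- setdiff(.calls_cols, names(df))
  if (length(missing))
    stop(sprintf("trio calls '%s' lack mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df$in_mother <- as.logical(df$in_mother)
  df$in_father <- as.logical(df$in_father)
  class(df) <- c("trio_calls", "data.frame")
  df
}

#' @describeIn io Write a trio-calls TSV.
#' @param calls trio-calls data frame.
#' @export
write_trio_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read trio calls from a minimal VCF
#'
#' Alternative calls source: a VCF with GT fields for the child and its
#' parents. Only CHROM/POS/REF/ALT/GT are consulted; variants are keyed as
#' `chrom:pos:ref:alt` unless an `ID` is present. Requires the `vcfR` package.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param child,mother,father sample names; `mother`/`father` may be `NA` if
#'   absent from the VCF.
#' @param gene gene symbol to assign to all records (single-gene panels), or a
#'   function(chrom, pos) returning symbols.
#' @return A [trio_calls()] table.
#' @export
read_trio_vcf <- function(vcf_path, child, mother = NA, father = NA,
                          gene = "LOXHD1") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_trio_vcf() requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  carries <- function(sample) {
    if (is.na(sample)) return(rep(NA, nrow(gt)))
    if (!sample %in% colnames(gt))
      stop(sprintf("sample '%s' absent from VCF", sample), call. = FALSE)
    g <- gt[, sample]
    ifelse(is.na(g), NA, grepl("1", g))
  }
  child_gt <- gt[, child]
  alleles <- strsplit(gsub("\\|", "/", child_gt), "/", fixed = FALSE)
  zyg <- vapply(alleles, function(a) {
    if (all(a == "1")) "hom" else if (any(a == "1")) "het" else "ref"
  }, character(1))
  keep <- zyg %in% c("het", "hom")
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":"),
                fix[, "ID"])
  genes <- if (is.function(gene)) gene(fix[, "CHROM"], as.integer(fix[, "POS"])) else gene
  trio_calls(variant_id = ids[keep],
             gene = if (length(genes) > 1) genes[keep] else genes,
             child_zygosity = zyg[keep],
             in_mother = carries(mother)[keep],
             in_father = carries(father)[keep],
             trio_id = child)
}

#' Write a cohort report
#'
#' Structured JSON (schema version recorded, rule-version identifiers for the
#' combining table, shape precedence and truncating convention included for
#' provenance) plus flat TSV summaries alongside.
#'
#' @param summary a cohort summary list ([cohort_summary()]).
#' @param path path of the JSON report; TSV side-files are written next to it.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path) {
  report <- c(list(schema_version = "1.0",
                   rules = list(acmg_table = "acmg_amp_2015_unmodified",
                                shape_precedence = "complete>residual>u>down>ascending>flat",
                                truncating_convention = "splice_region_truncating")),
              summary)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  stem <- sub("\\.json$", "", path)
  if (!is.null(summary$allele_frequencies))
    utils::write.table(summary$allele_frequencies, paste0(stem, "_allele_freqs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary$type_spectrum)) {
    ts <- data.frame(molecular_class = names(summary$type_spectrum),
                     n = as.integer(summary$type_spectrum))
    utils::write.table(ts, paste0(stem, "_type_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
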