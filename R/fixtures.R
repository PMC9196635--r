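#' Packaged LOXHD1 case-study cohort: variant table
#'
#' Transcription of a published screening of 2,901 sporadic Chinese
#' non-syndromic hearing-loss probands: the 33 likely causative LOXHD1
#' variants found in 21 patients, with their transcript-level HGVS
#' descriptions, genomic loci (chr18, 1-based), exon/intron and PLAT-domain
#' annotations, curated ACMG/AMP evidence-code strings and printed five-tier
#' labels. Four variants whose exon/intron context differs between LOXHD1
#' transcripts are stored under their first-printed (exonic) transcript, with
#' the NM_144612.6 representation kept in `alias_nm144612`; all other variants
#' are on NM_144612.6. A variant is `novel` when it was observed only in this
#' cohort (`single_origin`) and not in ClinVar.
#'
#' @return data frame with 33 rows; columns `variant_id`, `transcript`,
#'   `cdna`, `protein`, `chrom`, `pos`, `exon_intron`, `domain`, `codes`,
#'   `classification_printed`, `clinvar_included`, `single_origin`, `novel`,
#'   `origin`, `alias_nm144612`, `molecular_class`.
#' @export
loxhd1_variants <- function() {
  v <- function(cdna, protein, pos, exin, domain, codes, label, clinvar, single,
                origin, transcript = "NM_144612.6", alias = NA_character_) {
    data.frame(variant_id = normalize_hgvs(cdna), transcript = transcript,
               cdna = normalize_hgvs(cdna), protein = normalize_hgvs(protein),
               chrom = "chr18", pos = pos, exon_intron = exin, domain = domain,
               codes = codes, classification_printed = label,
               clinvar_included = clinvar, single_origin = single,
               origin = origin, alias_nm144612 = alias, stringsAsFactors = FALSE)
  }
  tbl <- rbind(
    v("c.511+8C>A", NA, 44219571L, "Intron4/39", "Interval(PLAT1-2)",
      "PM2+BP4+BP6", "Uncertain Significance", "Yes", TRUE, "Chinese"),
    v("c.611-2A>T", NA, 44190889L, "Intron5/39", "PLAT2",
      "PVS1+PM1+PM2+PP3", "Pathogenic", "Yes", FALSE, "Chinese"),
    v("c.805dupC", "p.Leu269ProfsTer2", 44184147L, "Exon7/40", "PLAT2",
      "PVS1+PM2+PP3", "Pathogenic", "No", TRUE, "Chinese"),
    v("c.988G>T", "p.Gly330Trp", 44181326L, "Exon8/40", "PLAT3",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.1262G>A", "p.Arg421Gln", 44174302L, "Exon9/40", "Interval(PLAT3-4)",
      "PM2+BP1+BP4", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.1270+4A>C", NA, 44174290L, "Intron9/39", "Interval(PLAT3-4)",
      "PM1+PM2+BP4", "Uncertain Significance", "No", FALSE, "Chinese/Japanese"),
    v("c.1362delG", "p.Arg455GlyfsTer7", 44173632L, "Exon10/40", "PLAT4",
      "PVS1+PM2+PP3", "Pathogenic", "No", TRUE, "Chinese"),
    v("c.1420G>T", "p.Glu474Ter", 44173574L, "Exon10/40", "PLAT4",
      "PVS1+PM2+PP3", "Pathogenic", "No", TRUE, "Chinese"),
    v("c.1654+4A>G", NA, 44171892L, "Intron12/39", "Interval(PLAT4-5)",
      "PM2", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.1809+4A>G", NA, 44159589L, "Intron13/39", "PLAT5",
      "PM2+BP4", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.2327G>A", "p.Arg776His", 44146330L, "Exon17/40", "PLAT6",
      "PM2+BP1+BP4", "Uncertain Significance", "Yes", TRUE, "Chinese"),
    v("c.2437+1G>A", NA, 44146219L, "Intron17/39", "Interval(PLAT6-7)",
      "PVS1+PM2+PP3", "Pathogenic", "No", TRUE, "Chinese"),
    v("c.2438T>A", "p.Leu813Ter", 44143188L, "Exon18/40", "Interval(PLAT6-7)",
      "PVS1+PM2", "Likely Pathogenic", "No", TRUE, "Chinese"),
    v("c.2611G>A", "p.Asp871Asn", 44140496L, "Exon19/40", "PLAT7",
      "PM2+BP1", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.2635C>T", "p.Arg879Trp", 44140472L, "Exon19/40", "PLAT7",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.2641G>A", "p.Gly881Arg", 44140466L, "Exon19/40", "PLAT7",
      "PS1+PM2", "Likely Pathogenic", "No", FALSE, "Chinese/Dutch"),
    v("c.3061+1G>A", NA, 44140045L, "Intron19/39", "PLAT7",
      "PVS1+PM1+PP5+PM2+PP3", "Pathogenic", "No", FALSE, "Chinese/Dutch"),
    v("c.3268C>T", "p.Arg1090Trp", 44137401L, "Exon21/40", "PLAT7",
      "PM1+PM2+PP3+BP1", "Uncertain Significance", "No", FALSE, "Chinese"),
    v("c.3514+1G>A", NA, 44126857L, "Intron22/39", "Interval(PLAT7-8)",
      "PVS1+PM2+PP3+PP5", "Pathogenic", "Yes", TRUE, "Chinese"),
    v("c.3839C>T", "p.Ala1280Val", 44121813L, "Exon25/40", "PLAT8",
      "PM2+BP1+BP4", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.4167G>A", "p.Trp1389Ter", 44114343L, "Exon27/40", "PLAT9",
      "PVS1+PM2+PP3", "Pathogenic", "No", TRUE, "Chinese"),
    v("c.879+5G>A", NA, 44114293L, "Intron9/23", "PLAT9",
      "PM1+PM2+PP5", "Uncertain Significance", "Yes", FALSE, "Chinese",
      transcript = "NM_001145472.2", alias = "c.4212+5G>A"),
    v("c.4247G>A", "p.Trp1416Ter", 44113253L, "Exon28/40", "PLAT9",
      "PVS1+PM1+PM2+PP3+PP5", "Pathogenic", "Yes", FALSE, "Chinese"),
    v("c.4714C>T", "p.Arg1572Ter", 44104697L, "Exon30/40", "PLAT10",
      "PVS1+PS1+PP5+PM2+PP3", "Pathogenic", "Yes", FALSE, "Chinese/Jewish"),
    v("c.1716_1717insT", "p.Ala573CysfsTer16", 44102100L, "Exon14/24", "PLAT11",
      "PVS1+PM2+PP3", "Pathogenic", "No", TRUE, "Chinese",
      transcript = "NM_001145472.2", alias = "c.5049_5050insT"),
    v("c.1765G>A", "p.Gly589Arg", 44101233L, "Exon15/24", "PLAT11",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese",
      transcript = "NM_001145472.2", alias = "c.5085+831G>A"),
    v("c.1846T>C", "p.Cys616Arg", 44101152L, "Exon15/24", "PLAT11",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese",
      transcript = "NM_001145472.2", alias = "c.5085+912T>C"),
    v("c.5287C>T", "p.Arg1763Trp", 44089705L, "Exon34/40", "PLAT12",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.5336T>C", "p.Leu1779Pro", 44087671L, "Exon35/40", "PLAT12",
      "PM2+BP1+BP4", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.5545G>A", "p.Gly1849Arg", 44085948L, "Exon36/40", "PLAT13",
      "PM1+PM2+PP3+BP1", "Uncertain Significance", "No", FALSE, "Chinese/Czech"),
    v("c.5888delG", "p.Gly1963AlafsTer136", 44065090L, "Exon38/40", "PLAT14",
      "PVS1+PS1+PM2+PP3+PP5", "Pathogenic", "No", FALSE, "Chinese"),
    v("c.6413G>A", "p.Arg2138Gln", 44057658L, "Exon40/40", "PLAT15",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese"),
    v("c.1417G>A", "p.Val473Met", 44057557L, "Exon9/9", "PLAT15",
      "PM2+PP3+BP1", "Uncertain Significance", "No", TRUE, "Chinese",
      transcript = "NM_001145473.2", alias = "c.6514G>A")
  )
  tbl$novel <- tbl$single_origin & tbl$clinvar_included == "No"
  tbl$molecular_class <- vapply(seq_len(nrow(tbl)), function(i)
    classify_molecular_class(tbl$cdna[i], tbl$protein[i]), character(1))
  tbl
}

#' Packaged LOXHD1 case-study cohort: patient records
#'
#' The 21 probands with biallelic LOXHD1 genotypes from the 2,901-patient
#' screen: causative allele pair (equal ids encode homozygosity; patient 19 is
#' homozygous for c.5888delG with an additional non-causative heterozygous
#' allele c.1262G>A found in cis in his unaffected father), onset and visit
#' ages (years), reported progression/symmetry and vestibular symptoms (none
#' reported).
#'
#' @return data frame with 21 rows; `extra_alleles` is a comma-separated list
#'   (empty for all but patient 19).
#' @export
loxhd1_patients <- function() {
  p <- function(id, a1, a2, onset, visit, prog, sym, extra = "", avail = TRUE) {
    data.frame(patient_id = id, allele1 = normalize_hgvs(a1),
               allele2 = normalize_hgvs(a2), extra_alleles = extra,
               onset_age = onset, visit_age = visit,
               progression_reported = prog, symmetry_reported = sym,
               vertigo = FALSE, audiogram_available = avail,
               stringsAsFactors = FALSE)
  }
  rbind(
    p(1,  "c.2641G>A",       "c.1420G>T",    10,  24,  "progressive", "unknown",  avail = FALSE),
    p(2,  "c.5888delG",      "c.4714C>T",     1,   4,  "stable",      "asymmetric"),
    p(3,  "c.1362delG",      "c.2641G>A",     0,   4,  "unknown",     "asymmetric"),
    p(4,  "c.3061+1G>A",     "c.5336T>C",     0,   3,  "progressive", "symmetric"),
    p(5,  "c.4247G>A",       "c.6413G>A",     1,   2.5,"unknown",     "unknown",  avail = FALSE),
    p(6,  "c.4167G>A",       "c.1809+4A>G",   0,   1.5,"unknown",     "symmetric"),
    p(7,  "c.611-2A>T",      "c.1846T>C",     1,  28,  "progressive", "symmetric"),
    p(8,  "c.2438T>A",       "c.2635C>T",     5,   7,  "stable",      "symmetric"),
    p(9,  "c.6413G>A",       "c.2611G>A",     0,   4,  "unknown",     "symmetric", avail = FALSE),
    p(10, "c.805dupC",       "c.5545G>A",     1,   4,  "unknown",     "symmetric"),
    p(11, "c.4247G>A",       "c.2437+1G>A",   2,   3,  "stable",      "asymmetric"),
    p(12, "c.1420G>T",       "c.879+5G>A",    3,   4,  "unknown",     "symmetric", avail = FALSE),
    p(13, "c.988G>T",        "c.611-2A>T",    2,   3,  "progressive", "symmetric", avail = FALSE),
    p(14, "c.5888delG",      "c.3839C>T",     0,   5,  "stable",      "symmetric"),
    p(15, "c.1765G>A",       "c.1270+4A>C",   2,   5,  "stable",      "symmetric"),
    p(16, "c.5287C>T",       "c.511+8C>A",    1,   1.5,"unknown",     "symmetric"),
    p(17, "c.5888delG",      "c.3514+1G>A",   2,  28,  "unknown",     "symmetric"),
    p(18, "c.1654+4A>G",     "c.611-2A>T",    1,   1,  "unknown",     "symmetric"),
    p(19, "c.5888delG",      "c.5888delG",    0,   0.5,"unknown",     "symmetric",
      extra = "c.1262G>A"),
    p(20, "c.1716_1717insT", "c.3268C>T",     0,   2,  "stable",      "symmetric"),
    p(21, "c.1417G>A",       "c.2327G>A",     2,   2,  "stable",      "symmetric", avail = FALSE)
  )
}

#' Packaged LOXHD1 case-study cohort: audiograms
#'
#' Long-format audiograms for the 15 probands whose audiometric profiles are
#' described in the case-study cohort (6 further patients, mostly cochlear
#' implantees, have no audiogram). Thresholds are exact where printed and
#' synthetic interpolations at unprinted frequencies, chosen to agree with the
#' described configuration of each ear; patient 4 carries two visits (ages 1
#' and 3) with the documented 15 dB left-ear progression.
#'
#' @return Long data frame (`patient_id`, `visit_age`, `ear`, `freq_hz`,
#'   `threshold_db`, `no_response`, `method`), suitable for
#'   [assess_audiograms()] and [write_audiograms()].
#' @export
loxhd1_audiograms <- function() {
  f <- audiometric_frequencies()
  row <- function(id, age, ear, th) {
    data.frame(patient_id = paste0("P", id), visit_age = age, ear = ear, freq_hz = f,
               threshold_db = th, no_response = FALSE,
               method = if (age >= 6) "pure_tone" else "assr",
               stringsAsFactors = FALSE)
  }
  both <- function(id, age, th) rbind(row(id, age, "left", th), row(id, age, "right", th))
  df <- rbind(
    row(2, 4, "left",  rep(65, 7)),
    row(2, 4, "right", c(70, 70, 75, 100, 95, 85, 80)),
    row(3, 4, "left",  c(35, 40, 50, 70, 85, 95, 100)),
    row(3, 4, "right", rep(110, 7)),
    both(4, 1, c(50, 55, 60, 70, 75, 85, 90)),
    row(4, 3, "left",  c(65, 70, 75, 85, 90, 100, 105)),
    row(4, 3, "right", c(50, 55, 60, 70, 75, 85, 90)),
    both(6, 1.5, c(30, 30, 60, 100, 100, 100, 100)),
    both(7, 28, c(60, 80, 95, 95, 100, 105, 105)),
    both(8, 7, c(45, 45, 50, 85, 85, 85, 85)),
    row(10, 4, "left",  c(65, 70, 80, 90, 95, 100, 105)),
    row(10, 4, "right", c(55, 60, 70, 80, 85, 90, 95)),
    row(11, 3, "left",  c(55, 55, 55, 60, 60, 65, 70)),
    row(11, 3, "right", c(40, 45, 55, 70, 85, 100, 105)),
    both(14, 0.5, c(40, 45, 50, 60, 65, 70, 75)),
    both(15, 5, c(20, 20, 20, 40, 60, 90, 90)),
    both(16, 1.5, rep(110, 7)),
    both(17, 28, c(80, 90, 100, 105, 105, 110, 110)),
    both(18, 1, rep(95, 7)),
    both(19, 0.5, c(25, 25, 30, 50, 70, 50, 65)),
    row(20, 2, "left",  c(45, 50, 60, 85, 85, 85, 90)),
    row(20, 2, "right", c(60, 65, 75, 100, 100, 100, 105))
  )
  rownames(df) <- NULL
  df
}

#' Packaged LOXHD1 case-study cohort: trio calls
#'
#' Parental-validation calls for the 21 probands, reconstructed from the
#' cohort's segregation narrative: compound heterozygotes inherit one allele
#' per parent (in trans); patient 19 is homozygous with both parents carriers
#' and an extra heterozygous allele confined to the father (in cis with his
#' causative copy); patient 7's father and patient 17's parents were not
#' available (carriage `NA`); patients 1 and 8 additionally carry biallelic
#' variants in a second gene (HARS1, MYO15A) that adjudication must rank
#' below the LOXHD1 genotype.
#'
#' @return A [trio_calls()] table over trios `P1`..`P21`; secondary-gene
#'   variant ids are prefixed with their gene symbol.
#' @export
loxhd1_trio_calls <- function() {
  pts <- loxhd1_patients()
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    pt <- pts[i, ]
    id <- paste0("P", pt$patient_id)
    if (pt$allele1 == pt$allele2) {
      trio_calls(pt$allele1, "LOXHD1", "hom", TRUE, TRUE, trio_id = id)
    } else if (pt$patient_id == 7) {
      trio_calls(c(pt$allele1, pt$allele2), "LOXHD1", "het",
                 in_mother = c(TRUE, FALSE), in_father = c(NA, NA), trio_id = id)
    } else if (pt$patient_id == 17) {
      trio_calls(c(pt$allele1, pt$allele2), "LOXHD1", "het",
                 in_mother = c(NA, NA), in_father = c(NA, NA), trio_id = id)
    } else {
      trio_calls(c(pt$allele1, pt$allele2), "LOXHD1", "het",
                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE), trio_id = id)
    }
  })
  extras <- rbind(
    trio_calls("c.1262G>A", "LOXHD1", "het", FALSE, TRUE, trio_id = "P19"),
    trio_calls(c("HARS1:c.1256A>T", "HARS1:c.1255A>C"), "HARS1", "het",
               in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE), trio_id = "P1"),
    trio_calls(c("MYO15A:c.3658G>A", "MYO15A:c.5557C>G"), "MYO15A", "het",
               in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE), trio_id = "P8")
  )
  out <- rbind(do.call(rbind, rows), extras)
  class(out) <- c("trio_calls", "data.frame")
  rownames(out) <- NULL
  out
}

#' Evidence codes of the secondary-gene variants in the case-study cohort
#'
#' The HARS1 (patient 1) and MYO15A (patient 8) variants that compete with the
#' LOXHD1 genotypes during causative-gene adjudication, with their curated
#' evidence-code strings.
#'
#' @return data frame with `variant_id`, `gene`, `codes`.
#' @export
loxhd1_secondary_variants <- function() {
  data.frame(
    variant_id = c("HARS1:c.1256A>T", "HARS1:c.1255A>C",
                   "MYO15A:c.3658G>A", "MYO15A:c.5557C>G"),
    gene = c("HARS1", "HARS1", "MYO15A", "MYO15A"),
    codes = c("PM2+PP3", "PM2+BP4", "PP2+BS1+BS2+BP4", "PM1+PM2+PP2+BP4"),
    stringsAsFactors = FALSE)
}

#' Case-study cohort PED file content
#'
#' Standard 6-column pedigree rows for the 21 trios (affected proband,
#' unaffected parents); parents that were unavailable for testing are still
#' listed (missing genotypes are encoded in the calls table, not the
#' pedigree).
#'
#' @return PED data frame (`family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`).
#' @export
loxhd1_ped <- function() {
  ids <- paste0("P", loxhd1_patients()$patient_id)
  rbind(
    data.frame(family_id = ids, individual_id = ids,
               father_id = paste0(ids, "_fa"), mother_id = paste0(ids, "_mo"),
               sex = 0L, phenotype = 2L, stringsAsFactors = FALSE),
    data.frame(family_id = ids, individual_id = paste0(ids, "_fa"),
               father_id = "0", mother_id = "0", sex = 1L, phenotype = 1L,
               stringsAsFactors = FALSE),
    data.frame(family_id = ids, individual_id = paste0(ids, "_mo"),
               father_id = "0", mother_id = "0", sex = 2L, phenotype = 1L,
               stringsAsFactors = FALSE)
  )
}
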