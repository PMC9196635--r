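#' Simulation configuration for synthetic trio cohorts
#'
#' Defaults encode the structure of the case-study cohort: a biallelic
#' (solved) child rate of 0.0072 (21 of 2,901 screened), 1/21 of causative
#' genotypes homozygous, 7% of parents unavailable (3 of 42), onset ages
#' resampled from the 21 printed onsets, evidence-code profiles resampled from
#' the 33 printed code strings, and audiogram shape archetypes dominated by
#' the down-sloping configuration with 5 dB measurement noise.
#'
#' @param n_trios number of child-mother-father trios.
#' @param biallelic_rate probability a child carries a causative biallelic
#'   genotype in the target gene.
#' @param hom_fraction probability a causative genotype is homozygous (vs
#'   compound heterozygous).
#' @param missing_parent_rate per-parent probability of an unavailable sample.
#' @param background_rate Poisson mean of incidental heterozygous carrier
#'   variants per child, each in its own background gene.
#' @param code_profiles character vector of evidence-code strings sampled (with
#'   replacement) for simulated variants.
#' @param shape_archetypes named list of mean threshold vectors (dB HL at
#'   125--8000 Hz) defining the audiogram shape archetypes.
#' @param shape_probs sampling weights over `names(shape_archetypes)`.
#' @param noise_sd per-frequency measurement noise, dB (truncated normal,
#'   clipped to \[-10, 130\], thresholds rounded to the 5 dB audiometric step).
#' @param onset_pool ages (years) resampled for onset of affected children.
#' @param progression_rate probability an affected child receives a second
#'   visit with a planted >= 15 dB one-ear progression.
#' @param seed integer seed fixing the full output stream.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_trios = 200,
                       biallelic_rate = 0.0072,
                       hom_fraction = 1 / 21,
                       missing_parent_rate = 0.07,
                       background_rate = 1,
                       code_profiles = loxhd1_variants()$codes,
                       shape_archetypes = default_shape_archetypes(),
                       shape_probs = c(down_sloping = 0.62, flat = 0.20,
                                       u_shaped = 0.08, ascending = 0.10),
                       noise_sd = 5,
                       onset_pool = loxhd1_patients()$onset_age,
                       progression_rate = 4 / 11,
                       seed = 1L) {
  probs <- c(biallelic_rate = biallelic_rate, hom_fraction = hom_fraction,
             missing_parent_rate = missing_parent_rate,
             progression_rate = progression_rate)
  if (any(probs < 0 | probs > 1))
    stop(sprintf("probabilities must lie in [0, 1]: %s",
                 paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")),
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!setequal(names(shape_probs), names(shape_archetypes)))
    stop("shape_probs must be named after shape_archetypes", call. = FALSE)
  structure(list(n_trios = as.integer(n_trios), biallelic_rate = biallelic_rate,
                 hom_fraction = hom_fraction,
                 missing_parent_rate = missing_parent_rate,
                 background_rate = background_rate, code_profiles = code_profiles,
                 shape_archetypes = shape_archetypes,
                 shape_probs = shape_probs / sum(shape_probs),
                 noise_sd = noise_sd, onset_pool = onset_pool,
                 progression_rate = progression_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @details Default archetype mean vectors are synthetic conventions chosen to
#'   satisfy the shape rules with wide margins: down-sloping
#'   (20,25,40,60,80,95,100), flat (constant 70), U-shaped
#'   (40,40,50,70,70,45,40), ascending (the reverse of down-sloping).
#' @export
default_shape_archetypes <- function() {
  down <- c(20, 25, 40, 60, 80, 95, 100)
  list(down_sloping = down,
       flat = rep(70, 7),
       u_shaped = c(40, 40, 50, 70, 70, 45, 40),
       ascending = rev(down))
}

#' Simulate a synthetic trio cohort
#'
#' Generates a cohort with the statistical structure the pipeline assumes:
#' biallelic children receive a homozygous (both parents heterozygous
#' carriers) or compound-heterozygous (one allele per parent, in trans)
#' genotype in the target gene; every child is additionally sprinkled with
#' incidental background carrier variants, each in its own gene; affected
#' children receive two-ear audiograms drawn from a shape archetype plus
#' independent per-frequency noise, with an optional second visit carrying a
#' planted progression offset. Truth labels record every planted property.
#'
#' @param config a [sim_config()].
#' @return List with elements `variants` (variant table), `calls`
#'   ([trio_calls()] over all trios), `audiograms` (long table), `ped`, and
#'   `truth` (per-trio planted labels).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_trios
  trio_ids <- sprintf("T%04d", seq_len(n))

  biallelic <- stats::rbinom(n, 1, config$biallelic_rate) == 1
  model <- ifelse(!biallelic, NA_character_,
                  ifelse(stats::runif(n) < config$hom_fraction, "AR_hom", "AR_comphet"))

  # causative variant pool in the target gene
  n_pool <- max(8L, ceiling(2.5 * sum(biallelic)))
  pool <- simulate_variant_pool(n_pool, "LOXHD1", config$code_profiles)

  miss_mo <- stats::runif(n) < config$missing_parent_rate
  miss_fa <- stats::runif(n) < config$missing_parent_rate
  n_bg <- stats::rpois(n, config$background_rate)
  shapes <- sample(names(config$shape_probs), n, replace = TRUE,
                   prob = config$shape_probs)
  onsets <- sample(config$onset_pool, n, replace = TRUE)
  progressive <- stats::runif(n) < config$progression_rate

  calls <- list(); audio <- list()
  a1 <- a2 <- rep(NA_character_, n)
  mo_val <- function(i, x) if (miss_mo[i]) NA else x
  fa_val <- function(i, x) if (miss_fa[i]) NA else x
  for (i in which(biallelic)) {
    id <- trio_ids[i]
    if (model[i] == "AR_hom") {
      a1[i] <- a2[i] <- sample(pool$variant_id, 1)
      calls[[length(calls) + 1L]] <-
        trio_calls(a1[i], "LOXHD1", "hom", mo_val(i, TRUE), fa_val(i, TRUE),
                   trio_id = id)
    } else {
      pair <- sample(pool$variant_id, 2)
      a1[i] <- pair[1]; a2[i] <- pair[2]
      calls[[length(calls) + 1L]] <-
        trio_calls(pair, "LOXHD1", "het",
                   in_mother = c(mo_val(i, TRUE), mo_val(i, FALSE)),
                   in_father = c(fa_val(i, FALSE), fa_val(i, TRUE)), trio_id = id)
    }
    audio[[length(audio) + 1L]] <-
      simulate_audiograms(id, shapes[i], config, onset_age = onsets[i],
                          progressive = progressive[i])
  }

  tot_bg <- sum(n_bg)
  if (tot_bg > 0) {  # incidental carrier variants, one private gene each
    bg_mo_missing <- rep(miss_mo, n_bg); bg_fa_missing <- rep(miss_fa, n_bg)
    from_mother <- stats::runif(tot_bg) < 0.5
    calls[[length(calls) + 1L]] <- trio_calls(
      sprintf("bg%05d", seq_len(tot_bg)), sprintf("BG%05d", seq_len(tot_bg)),
      "het",
      in_mother = ifelse(bg_mo_missing, NA, from_mother),
      in_father = ifelse(bg_fa_missing, NA, !from_mother),
      trio_id = rep(trio_ids, n_bg))
  }

  truth <- data.frame(
    trio_id = trio_ids, biallelic = biallelic, model = model,
    allele1 = a1, allele2 = a2,
    mother_genotyped = !miss_mo, father_genotyped = !miss_fa,
    shape = ifelse(biallelic, shapes, NA_character_),
    onset_age = ifelse(biallelic, onsets, NA_real_),
    progressive = ifelse(biallelic, progressive, NA),
    stringsAsFactors = FALSE)

  calls_df <- if (length(calls)) do.call(rbind, calls) else
    trio_calls(character(0), character(0), character(0), logical(0), logical(0))
  class(calls_df) <- c("trio_calls", "data.frame")
  audio_df <- if (length(audio)) do.call(rbind, audio) else NULL
  truth_df <- truth
  ped <- data.frame(family_id = trio_ids, individual_id = trio_ids,
                    father_id = paste0(trio_ids, "_fa"),
                    mother_id = paste0(trio_ids, "_mo"),
                    sex = 0L, phenotype = ifelse(biallelic, 2L, 1L),
                    stringsAsFactors = FALSE)
  list(variants = pool, calls = calls_df, audiograms = audio_df, ped = ped,
       truth = truth_df)
}

# synthetic variant pool: plausible HGVS per sampled molecular class
simulate_variant_pool <- function(n, gene, code_profiles) {
  classes <- sample(c("missense", "nonsense", "frameshift_insertion",
                      "frameshift_deletion", "canonical_splice",
                      "intronic_near_splice"),
                    n, replace = TRUE,
                    prob = c(0.45, 0.15, 0.1, 0.1, 0.1, 0.1))
  pos <- sample(seq(100, 6000), n)
  aa <- c("Ala", "Arg", "Asp", "Cys", "Gly", "Leu", "Ser", "Trp", "Val")
  mk <- function(i) {
    p <- pos[i]; res <- ceiling(p / 3)
    ref <- sample(aa, 1)
    switch(classes[i],
      missense = list(cdna = sprintf("c.%dG>A", p),
                      protein = sprintf("p.%s%d%s", ref, res,
                                        sample(setdiff(aa, ref), 1))),
      nonsense = list(cdna = sprintf("c.%dG>A", p),
                      protein = sprintf("p.%s%dTer", sample(aa, 1), res)),
      frameshift_insertion = list(cdna = sprintf("c.%ddupC", p),
                                  protein = sprintf("p.%s%dProfsTer%d", sample(aa, 1),
                                                    res, sample(2:40, 1))),
      frameshift_deletion = list(cdna = sprintf("c.%ddelG", p),
                                 protein = sprintf("p.%s%dGlyfsTer%d", sample(aa, 1),
                                                   res, sample(2:40, 1))),
      canonical_splice = list(cdna = sprintf("c.%d+%dG>A", p, sample(1:2, 1)),
                              protein = NA_character_),
      intronic_near_splice = list(cdna = sprintf("c.%d+%dG>A", p, sample(3:8, 1)),
                                  protein = NA_character_))
  }
  hg <- lapply(seq_len(n), mk)
  ivl <- sample(1:14, n, replace = TRUE)
  domain <- ifelse(stats::runif(n) < 0.8,
                   sprintf("PLAT%d", sample(1:15, n, replace = TRUE)),
                   sprintf("Interval(PLAT%d-%d)", ivl, ivl + 1))
  df <- data.frame(
    variant_id = vapply(hg, `[[`, "", "cdna"),
    transcript = "NM_144612.6",
    cdna = vapply(hg, `[[`, "", "cdna"),
    protein = vapply(hg, `[[`, "", "protein"),
    chrom = "chr18",
    pos = 44060000L + sample.int(160000L, n),
    exon_intron = NA_character_, domain = domain,
    codes = sample(code_profiles, n, replace = TRUE),
    classification_printed = NA_character_, novel = NA,
    origin = "synthetic", alias_nm144612 = NA_character_,
    molecular_class = classes, stringsAsFactors = FALSE)
  df[!duplicated(df$variant_id), , drop = FALSE]
}

# two-ear (optionally two-visit) noisy audiograms for one affected child
simulate_audiograms <- function(trio_id, shape, config, onset_age, progressive) {
  f <- audiometric_frequencies()
  mu <- config$shape_archetypes[[shape]]
  visit1 <- onset_age + stats::runif(1, 0, 2)
  draw <- function(age, offset = 0) {
    do.call(rbind, lapply(c("left", "right"), function(ear) {
      th <- mu + offset + stats::rnorm(length(f), 0, config$noise_sd)
      th <- pmin(pmax(round(th / 5) * 5, -10), 130)  # 5 dB audiometric step
      data.frame(patient_id = trio_id, visit_age = age, ear = ear, freq_hz = f,
                 threshold_db = th, no_response = FALSE, method = "pure_tone",
                 stringsAsFactors = FALSE)
    }))
  }
  out <- draw(visit1)
  if (progressive) {
    # second visit: a planted 20 dB left-ear deterioration on the measured
    # baseline (re-measurement noise is not re-drawn, so the planted rise is
    # always detectable by the 15 dB progression rule)
    v2 <- out
    v2$visit_age <- visit1 + 2
    v2$threshold_db <- ifelse(v2$ear == "left",
                              pmin(v2$threshold_db + 20, 130), v2$threshold_db)
    out <- rbind(out, v2)
  }
  out
}

#' Write a simulated (or fixture) cohort to a directory
#'
#' Emits the same TSV/CSV/PED formats the readers consume, plus a truth-labels
#' TSV when present, so the full file-based pipeline path is exercised.
#'
#' @param cohort list as returned by [simulate_cohort()] or
#'   [fixture_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cohort$variants, file.path(dir, "variants.tsv"))
  write_trio_calls(cohort$calls, file.path(dir, "trio_calls.tsv"))
  write_ped(cohort$ped, file.path(dir, "cohort.ped"))
  if (!is.null(cohort$audiograms))
    write_audiograms(cohort$audiograms, file.path(dir, "audiograms.csv"))
  if (!is.null(cohort$truth))
    utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' The case-study cohort re-emitted as a simulator truth set
#'
#' Deterministically packages the 33-variant / 21-patient case-study cohort in
#' the simulator's output structure (variant table, trio calls, audiograms,
#' PED, truth labels), so the complete files-to-report pipeline path can run
#' on it.
#'
#' @return The same list structure as [simulate_cohort()].
#' @export
fixture_cohort <- function() {
  pts <- loxhd1_patients()
  truth <- data.frame(
    trio_id = paste0("P", pts$patient_id),
    biallelic = TRUE,
    model = ifelse(pts$allele1 == pts$allele2, "AR_hom", "AR_comphet"),
    allele1 = pts$allele1, allele2 = pts$allele2,
    mother_genotyped = pts$patient_id != 17,
    father_genotyped = !(pts$patient_id %in% c(7, 17)),
    shape = NA_character_, onset_age = pts$onset_age, progressive = NA,
    stringsAsFactors = FALSE)
  list(variants = loxhd1_variants(), calls = loxhd1_trio_calls(),
       audiograms = loxhd1_audiograms(), ped = loxhd1_ped(), truth = truth)
}
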