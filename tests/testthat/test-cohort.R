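test_that("half-up rounding matches published conventions", {
  expect_equal(round_half_up(0.725, 2), 0.73)
  expect_equal(round_half_up(90.476, 1), 90.5)
  expect_equal(round_half_up(0.08618, 4), 0.0862)
  expect_equal(round_half_up(2.5, 0), 3)   # banker's rounding would give 2
  expect_equal(round_half_up(-2.5, 0), -3)
})

test_that("prevalence and allele frequencies follow the diploid counting rules", {
  expect_equal(prevalence(21, 2901), 0.72)
  expect_equal(prevalence(0, 2901), 0)
  expect_equal(prevalence(2901, 2901), 100)
  expect_error(prevalence(1, 0))

  toy <- data.frame(patient_id = 1:3,
                    allele1 = c("X", "X", "Y"),
                    allele2 = c("X", "Z", "Z"))
  af <- cohort_allele_frequency(toy, "X", 10)
  expect_equal(af$count, 3)  # hom counts twice, het once
  expect_equal(af$denominator, 20)
  expect_equal(af$percent, 15)
  expect_equal(cohort_allele_frequency(toy, "missing", 10)$count, 0)
})

test_that("recurrence requires distinct patients, not homozygosity", {
  toy <- data.frame(patient_id = 1:3,
                    allele1 = c("X", "Y", "Y"),
                    allele2 = c("X", "Z", "W"))
  expect_identical(recurrent_variants(toy), "Y")
  distinct <- data.frame(patient_id = 1:2, allele1 = c("A", "B"), allele2 = c("C", "D"))
  expect_length(recurrent_variants(distinct), 0)
})

test_that("cohort tallies match exhaustive enumeration on toy cohorts", {
  set.seed(77)
  vid <- c("v1", "v2", "v3", "v4")
  classes <- c("missense", "nonsense", "canonical_splice", "missense")
  domains <- c("PLAT1", "Interval(PLAT1-2)", "PLAT3", "Interval(PLAT2-3)")
  variants <- data.frame(variant_id = vid, molecular_class = classes,
                         domain = domains, stringsAsFactors = FALSE)
  for (rep_ in 1:25) {
    n <- sample(1:4, 1)
    pat <- data.frame(patient_id = seq_len(n),
                      allele1 = sample(vid, n, replace = TRUE),
                      allele2 = sample(vid, n, replace = TRUE))
    dg <- domain_groups(pat, variants)
    tg <- truncation_groups(pat, variants)
    # independent enumeration
    exp_dg <- c(PP = 0, PI = 0, II = 0); exp_tg <- c(TT = 0, NT_T = 0, NT_NT = 0)
    for (i in seq_len(n)) {
      in_plat <- grepl("^PLAT", domains[match(c(pat$allele1[i], pat$allele2[i]), vid)])
      k <- sum(in_plat)
      exp_dg[c("II", "PI", "PP")[k + 1]] <- exp_dg[c("II", "PI", "PP")[k + 1]] + 1
      tr <- classes[match(c(pat$allele1[i], pat$allele2[i]), vid)] != "missense"
      exp_tg[c("NT_NT", "NT_T", "TT")[sum(tr) + 1]] <-
        exp_tg[c("NT_NT", "NT_T", "TT")[sum(tr) + 1]] + 1
    }
    expect_equal(dg, exp_dg)
    expect_equal(tg, exp_tg)
    expect_equal(sum(dg), n)  # conservation
    expect_equal(sum(tg), n)
  }
})

test_that("onset distribution counts congenital-band patients", {
  p <- loxhd1_patients()
  od <- onset_distribution(p)
  expect_equal(od$count, 19)
  expect_equal(od$percent, 90.5)
  expect_equal(onset_distribution(p, congenital_cutoff = 0)$count, 7)
  all0 <- data.frame(patient_id = 1:4, onset_age = rep(0, 4))
  expect_equal(onset_distribution(all0)$percent, 100)
})

test_that("type spectrum conserves subset size", {
  v <- loxhd1_variants()
  full <- type_spectrum(v)
  expect_equal(sum(full), 33)
  expect_equal(sum(type_spectrum(v, character(0))), 0)
  uncollapsed <- type_spectrum(v, collapse_splicing = FALSE)
  expect_equal(sum(uncollapsed), 33)
  expect_equal(sum(uncollapsed[c("canonical_splice", "intronic_near_splice")]),
               full[["splicing"]])
})

test_that("missing domain labels are reported by variant", {
  variants <- data.frame(variant_id = "v1", molecular_class = "missense",
                         domain = NA_character_)
  pat <- data.frame(patient_id = 1, allele1 = "v1", allele2 = "v1")
  expect_error(domain_groups(pat, variants), "domain")
})
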