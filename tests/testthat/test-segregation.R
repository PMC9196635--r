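test_that("pair phasing agrees with brute-force Mendelian enumeration", {
  states <- expand.grid(m1 = c(TRUE, FALSE), f1 = c(TRUE, FALSE),
                        m2 = c(TRUE, FALSE), f2 = c(TRUE, FALSE))
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    got <- phase_pair(call1("A", m = s$m1, f = s$f1), call1("B", m = s$m2, f = s$f2))
    expect_identical(as.character(got), oracle_phase(s$m1, s$f1, s$m2, s$f2),
                     info = paste(unlist(s), collapse = "/"))
  }
  # a missing parent always leaves the phase unknown
  expect_identical(as.character(phase_pair(call1("A", m = TRUE, f = NA),
                                           call1("B", m = FALSE, f = NA))), "unknown")
  # de novo contradiction is flagged
  ph <- phase_pair(call1("A", m = FALSE, f = FALSE), call1("B", m = TRUE, f = FALSE))
  expect_identical(as.character(ph), "unknown")
  expect_true(attr(ph, "de_novo"))
})

test_that("candidate selection implements the three inheritance models", {
  # canonical trans pair
  cand <- select_candidates(trio_calls(c("A", "B"), "LOXHD1", "het",
                                       in_mother = c(TRUE, FALSE),
                                       in_father = c(FALSE, TRUE)))
  expect_equal(nrow(cand), 1)
  expect_identical(cand$model, "AR_comphet")
  expect_identical(cand$phase, "trans")
  expect_identical(cand$segregation_status, "confirmed")

  # homozygous child of two carriers
  hom <- select_candidates(trio_calls("A", "LOXHD1", "hom", TRUE, TRUE))
  expect_identical(hom$model, "AR_hom")

  # de novo dominant
  dn <- select_candidates(trio_calls("A", "GJB2", "het", FALSE, FALSE))
  expect_identical(dn$model, "AD_denovo")

  # cis pairs and unpaired inherited hets fit no model
  cis <- select_candidates(trio_calls(c("A", "B"), "LOXHD1", "het",
                                      in_mother = c(TRUE, TRUE),
                                      in_father = c(FALSE, FALSE)))
  expect_equal(nrow(cis), 0)
  single <- select_candidates(trio_calls("A", "LOXHD1", "het", TRUE, FALSE))
  expect_equal(nrow(single), 0)

  # missing parent: candidate retained with partial status, phase unresolved
  part <- select_candidates(trio_calls(c("A", "B"), "LOXHD1", "het",
                                       in_mother = c(TRUE, FALSE),
                                       in_father = c(NA, NA)))
  expect_identical(part$segregation_status, "partial")
  expect_identical(part$phase, "unknown")

  # Mendelian inconsistency flagged, not dropped silently
  bad <- select_candidates(trio_calls("A", "LOXHD1", "hom", FALSE, TRUE))
  expect_equal(nrow(bad), 0)
  expect_identical(attr(bad, "inconsistencies"), "A")
})

test_that("removing a parent changes status and phase but never the alleles", {
  full <- trio_calls(c("A", "B"), "LOXHD1", "het",
                     in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))
  no_father <- full; no_father$in_father <- NA
  c_full <- select_candidates(full); c_nf <- select_candidates(no_father)
  expect_identical(sort(c(c_full$allele1, c_full$allele2)),
                   sort(c(c_nf$allele1, c_nf$allele2)))
  expect_identical(c_full$segregation_status, "confirmed")
  expect_identical(c_nf$segregation_status, "partial")
})

test_that("cis passengers are excluded only when phased onto a causative haplotype", {
  # homozygous causative genotype with a single-parent extra allele (redundant)
  geno <- select_candidates(trio_calls("HOM", "LOXHD1", "hom", TRUE, TRUE))
  extra <- trio_calls("EXTRA", "LOXHD1", "het", FALSE, TRUE)
  res <- exclude_cis_passenger(geno, extra, trio_calls("HOM", "LOXHD1", "hom", TRUE, TRUE))
  expect_identical(res$excluded_cis[[1]], "EXTRA")
  expect_length(res$retained_extra[[1]], 0)

  # comp-het genotype: extra cis to one causative allele
  calls <- trio_calls(c("A", "B", "EXTRA"), "LOXHD1", "het",
                      in_mother = c(TRUE, FALSE, FALSE),
                      in_father = c(FALSE, TRUE, TRUE))
  geno <- select_candidates(calls)
  geno <- geno[geno$allele1 == "A" & geno$allele2 == "B", ]
  res <- exclude_cis_passenger(geno, calls[3, ], calls[1:2, ])
  expect_identical(res$excluded_cis[[1]], "EXTRA")

  # unphaseable extra is retained with a warning
  calls2 <- trio_calls(c("A", "B", "EXTRA"), "LOXHD1", "het",
                       in_mother = c(TRUE, FALSE, TRUE),
                       in_father = c(FALSE, TRUE, TRUE))
  geno2 <- select_candidates(calls2)
  geno2 <- geno2[geno2$allele1 == "A" & geno2$allele2 == "B", ]
  expect_warning(res2 <- exclude_cis_passenger(geno2, calls2[3, ], calls2[1:2, ]),
                 "retained")
  expect_identical(res2$retained_extra[[1]], "EXTRA")
})

test_that("adjudication ranks genotypes by sorted classification strength", {
  classif <- c(A = "Likely Pathogenic", B = "Pathogenic",
               C = "Uncertain Significance", D = "Uncertain Significance",
               E = "Benign")
  cands <- rbind(
    select_candidates(trio_calls(c("A", "B"), "LOXHD1", "het",
                                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))),
    select_candidates(trio_calls(c("C", "D"), "HARS1", "het",
                                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))))
  ranked <- adjudicate_causative_gene(cands, classif)
  expect_identical(ranked$gene[1], "LOXHD1")
  expect_false(any(ranked$tie))

  # {LP, VUS} beats {Benign, VUS}
  cands2 <- rbind(
    select_candidates(trio_calls(c("A", "C"), "LOXHD1", "het",
                                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))),
    select_candidates(trio_calls(c("E", "D"), "MYO15A", "het",
                                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))))
  ranked2 <- adjudicate_causative_gene(cands2, classif)
  expect_identical(ranked2$gene[1], "LOXHD1")

  # exact ties are reported unresolved
  cands3 <- rbind(
    select_candidates(trio_calls(c("C", "D"), "G1", "het",
                                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))),
    select_candidates(trio_calls(c("D", "C"), "G2", "het",
                                 in_mother = c(TRUE, FALSE), in_father = c(FALSE, TRUE))))
  ranked3 <- adjudicate_causative_gene(cands3, classif)
  expect_true(all(ranked3$tie))
  expect_identical(adjudicate_causative_gene(cands3[0, ], classif)$rank, integer(0))
})

test_that("planted genotypes are recovered with full precision and recall", {
  cfg <- sim_config(n_trios = 500, biallelic_rate = 0.05,
                    missing_parent_rate = 0, seed = 101)
  sim <- simulate_cohort(cfg)
  res <- run_pipeline(sim, n_cohort = cfg$n_trios)
  planted <- sim$truth$trio_id[sim$truth$biallelic]
  found <- res$patients$trio_id
  expect_setequal(found, planted)
  # recovered models match the planted ones
  m <- merge(res$patients, sim$truth, by = "trio_id")
  expect_identical(m$model.x, m$model.y)
})
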