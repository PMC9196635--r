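test_that("the case-study variant table has the documented structure", {
  v <- loxhd1_variants()
  expect_equal(nrow(v), 33)
  expect_equal(sum(v$novel), 20)
  expect_equal(sum(!v$novel), 13)
  expect_true(all(v$pos > 0))
  expect_true(all(grepl("\\.\\d+$", v$transcript)))  # versioned accessions
  expect_false(anyDuplicated(v$variant_id) > 0)
  # domain labels are PLAT 1..15 or interval labels
  plat <- grepl("^PLAT([1-9]|1[0-5])$", v$domain)
  ivl <- grepl("^Interval\\(PLAT\\d+-\\d+\\)$", v$domain)
  expect_true(all(plat | ivl))
  # stored molecular class is consistent with re-derivation from HGVS
  rederived <- vapply(seq_len(nrow(v)), function(i)
    classify_molecular_class(v$cdna[i], v$protein[i]), "")
  expect_identical(v$molecular_class, rederived)
})

test_that("the case-study patients carry the documented genotypes", {
  p <- loxhd1_patients()
  expect_equal(nrow(p), 21)
  expect_true(all(p$onset_age <= p$visit_age))
  expect_true(all(p$onset_age >= 0 & p$onset_age <= 10))
  p19 <- p[p$patient_id == 19, ]
  expect_identical(p19$allele1, "c.5888delG")
  expect_identical(p19$allele2, "c.5888delG")
  expect_identical(p19$extra_alleles, "c.1262G>A")
  # every causative allele resolves in the variant table
  v <- loxhd1_variants()
  expect_true(all(c(p$allele1, p$allele2) %in% v$variant_id))
  expect_equal(sum(p$audiogram_available), 15)
})

test_that("fixture audiograms classify as the printed configurations", {
  ax <- assess_audiograms(loxhd1_audiograms())
  pts <- ax$patients
  expect_equal(nrow(pts), 15)
  asym <- sort(pts$patient_id[pts$symmetry == "asymmetric"])
  expect_identical(asym, c("P11", "P2", "P3"))
  expect_identical(pts$progression[pts$patient_id == "P4"], "progressive")
  a <- ax$assessments
  expect_identical(a$shape[a$patient_id == "P2" & a$ear == "right"], "u_shaped")
  expect_identical(a$shape[a$patient_id == "P3" & a$ear == "right"], "flat")
  expect_identical(unique(a$shape[a$patient_id == "P15"]), "down_sloping")
  expect_identical(unique(a$severity[a$patient_id == "P16"]), "profound")
  # patient 8's printed left-ear profile
  expect_equal(a$pta[a$patient_id == "P8" & a$ear == "left"], 76.25)
  # patient 15's printed band means
  p15 <- a[a$patient_id == "P15" & a$ear == "left", ]
  expect_equal(p15$low_db, 20)
  expect_equal(p15$high_db, 90)
})

test_that("fixture trio calls segregate into the 21 documented genotypes", {
  cands <- segregate_cohort(loxhd1_trio_calls())
  lox <- cands[cands$gene == "LOXHD1", ]
  p <- loxhd1_patients()
  for (i in seq_len(nrow(p))) {
    tid <- paste0("P", p$patient_id[i])
    tc <- lox[lox$trio_id == tid, ]
    hit <- (tc$allele1 == p$allele1[i] & tc$allele2 == p$allele2[i]) |
           (tc$allele1 == p$allele2[i] & tc$allele2 == p$allele1[i])
    expect_true(any(hit), info = tid)
  }
  expect_identical(lox$segregation_status[lox$trio_id == "P7" &
                                            lox$allele1 == "c.611-2A>T"], "partial")
  expect_true(all(lox$segregation_status[lox$trio_id == "P17"] == "unconfirmed"))
})
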