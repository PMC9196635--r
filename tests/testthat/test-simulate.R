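test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(hom_fraction = 1.2), "hom_fraction")
  expect_error(sim_config(biallelic_rate = -0.1), "biallelic_rate")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(shape_probs = c(down_sloping = 1)), "shape_probs")
})

test_that("identical configurations and seeds give identical cohorts", {
  c1 <- simulate_cohort(sim_config(n_trios = 120, biallelic_rate = 0.1, seed = 9))
  c2 <- simulate_cohort(sim_config(n_trios = 120, biallelic_rate = 0.1, seed = 9))
  expect_identical(c1, c2)
  c3 <- simulate_cohort(sim_config(n_trios = 120, biallelic_rate = 0.1, seed = 10))
  expect_false(identical(c1$calls, c3$calls))
  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a zero biallelic rate yields an empty solved set", {
  sim <- simulate_cohort(sim_config(n_trios = 150, biallelic_rate = 0, seed = 4))
  res <- run_pipeline(sim, n_cohort = 150)
  expect_equal(res$summary$n_solved, 0)
  expect_equal(res$summary$prevalence_pct, 0)
})

test_that("planted genotype structure respects the recessive model", {
  sim <- simulate_cohort(sim_config(n_trios = 400, biallelic_rate = 0.2,
                                    hom_fraction = 0.3, missing_parent_rate = 0,
                                    seed = 21))
  tr <- sim$truth[sim$truth$biallelic, ]
  hom <- tr[tr$model == "AR_hom", ]
  expect_true(all(hom$allele1 == hom$allele2))
  ch <- tr[tr$model == "AR_comphet", ]
  expect_true(all(ch$allele1 != ch$allele2))
  # hom children have two carrier parents; comp-het alleles come one per parent
  calls <- sim$calls
  for (i in seq_len(nrow(hom))) {
    cc <- calls[calls$trio_id == hom$trio_id[i] & calls$gene == "LOXHD1", ]
    expect_true(all(cc$in_mother & cc$in_father))
  }
})

test_that("simulated audiogram shapes recover their archetypes", {
  # slope-separated archetypes recover essentially perfectly at 5 dB noise
  cfg <- sim_config(n_trios = 300, biallelic_rate = 1,
                    shape_probs = c(down_sloping = 0.5, flat = 0, u_shaped = 0,
                                    ascending = 0.5), seed = 31)
  sim <- simulate_cohort(cfg)
  ax <- assess_audiograms(sim$audiograms)
  first <- ax$assessments[!duplicated(ax$assessments$patient_id), ]
  m <- merge(first, sim$truth, by.x = "patient_id", by.y = "trio_id")
  expect_gte(mean(m$shape.x == m$shape.y), 0.99)

  # full default mixture, including the noise-fragile flat class
  cfg2 <- sim_config(n_trios = 300, biallelic_rate = 1, seed = 32)
  sim2 <- simulate_cohort(cfg2)
  ax2 <- assess_audiograms(sim2$audiograms)
  f2 <- ax2$assessments[!duplicated(ax2$assessments$patient_id), ]
  m2 <- merge(f2, sim2$truth, by.x = "patient_id", by.y = "trio_id")
  expect_gte(mean(m2$shape.x == m2$shape.y), 0.95)
})

test_that("planted progression offsets are detected across visits", {
  cfg <- sim_config(n_trios = 60, biallelic_rate = 1, progression_rate = 0.5,
                    seed = 41)
  sim <- simulate_cohort(cfg)
  ax <- assess_audiograms(sim$audiograms)
  m <- merge(ax$patients, sim$truth, by.x = "patient_id", by.y = "trio_id")
  expect_true(all(m$progression[m$progressive] == "progressive"))
  expect_true(all(m$progression[!m$progressive] == "unknown"))
})

test_that("the fixture cohort re-emits through the simulator output contract", {
  fc <- fixture_cohort()
  expect_equal(nrow(fc$variants), 33)
  expect_equal(sum(fc$truth$biallelic), 21)
  d <- withr::local_tempdir()
  write_cohort(fc, d)
  expect_equal(nrow(read_variant_table(file.path(d, "variants.tsv"))), 33)
  expect_equal(nrow(read_trio_calls(file.path(d, "trio_calls.tsv"))),
               nrow(fc$calls))
})
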