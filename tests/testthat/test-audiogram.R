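test_that("PTA is the mean of the four speech frequencies with no-response imputed", {
  expect_equal(pta(make_audio(rep(65, 7))), 65)
  expect_equal(pta(make_audio(rep(0, 7))), 0)
  # 500 Hz = 50, 1-4 kHz = 85
  expect_equal(pta(make_audio(c(45, 45, 50, 85, 85, 85, 85))), 76.25)
  nr <- audiogram("p", 3, "left", c("500" = 90, "1000" = 95, "2000" = 100),
                  no_response = 4000)
  expect_equal(pta(nr), (90 + 95 + 100 + 120) / 4)
  incomplete <- audiogram("p", 3, "left", c("500" = 90, "1000" = 95))
  expect_error(pta(incomplete), "2000, 4000")
})

test_that("severity bands partition the PTA line at the ASHA boundaries", {
  expect_identical(severity(c(25, 25.1, 40, 40.1, 55, 55.1, 70, 70.1, 90, 90.1, 110)),
                   c("normal", "mild", "mild", "moderate", "moderate",
                     "moderately_severe", "moderately_severe", "severe", "severe",
                     "profound", "profound"))
  # every PTA maps to exactly one band
  grid <- seq(-10, 130, by = 0.5)
  expect_false(anyNA(severity(grid)))
})

test_that("shape rules classify the canonical configurations", {
  expect_identical(as.character(audiogram_shape(
    make_audio(c(20, 20, 40, 60, 90, 90), freqs = c(250, 500, 1000, 2000, 4000, 8000)))),
    "down_sloping")
  expect_identical(as.character(audiogram_shape(make_audio(rep(30, 7)))), "flat")
  expect_identical(as.character(audiogram_shape(
    make_audio(c(30, 60, 100, 100, 100, 100), freqs = c(250, 500, 1000, 2000, 4000, 8000)))),
    "down_sloping")
  expect_identical(as.character(audiogram_shape(
    make_audio(c(40, 40, 60, 60, 40, 40), freqs = c(250, 500, 1000, 2000, 4000, 8000)))),
    "u_shaped")
  expect_identical(as.character(audiogram_shape(
    make_audio(c(90, 80, 60, 40, 20, 20), freqs = c(250, 500, 1000, 2000, 4000, 8000)))),
    "ascending")
  deaf <- audiogram("p", 4, "left", numeric(0), no_response = c(500, 1000, 2000, 4000))
  expect_identical(as.character(audiogram_shape(deaf)), "complete_deafness")
  residual <- audiogram("p", 4, "left", c("250" = 80, "500" = 95),
                        no_response = c(1000, 2000, 4000, 8000))
  expect_identical(as.character(audiogram_shape(residual)), "residual")
})

test_that("slope shapes and PTA are invariant under constant threshold shifts", {
  profiles <- list(
    down = c(20, 25, 40, 60, 80, 95, 100),
    flat = rep(70, 7),
    u = c(40, 40, 50, 70, 70, 45, 40),
    asc = rev(c(20, 25, 40, 60, 80, 95, 100)))
  for (nm in names(profiles)) {
    base_ag <- make_audio(profiles[[nm]])
    base_shape <- as.character(audiogram_shape(base_ag))
    for (shift in c(-15, -5, 5, 15, 25)) {
      th <- profiles[[nm]] + shift
      if (any(th < -10 | th > 130)) next
      shifted <- make_audio(th)
      expect_identical(as.character(audiogram_shape(shifted)), base_shape,
                       info = sprintf("%s %+d dB", nm, shift))
      expect_equal(pta(shifted), pta(base_ag) + shift)
    }
  }
})

test_that("progression requires a 15 dB PTA rise between consecutive visits", {
  v1 <- make_audio(rep(70, 7), age = 1)
  v2 <- make_audio(rep(85, 7), age = 3)
  expect_identical(progression(list(v1, v2)), "progressive")
  expect_identical(progression(list(v1, make_audio(rep(70, 7), age = 3))), "stable")
  expect_identical(progression(list(v1)), "unknown")
  expect_identical(progression(list(v2, v1)), "progressive")  # order-free
  expect_error(progression(list(v1, make_audio(rep(80, 7), age = 1))), "visit ages")
})

test_that("symmetry compares shape classes and the interaural PTA gap", {
  flat_l <- make_audio(rep(65, 7), ear = "left")
  expect_identical(ear_symmetry(flat_l, make_audio(rep(65, 7), ear = "right")),
                   "symmetric")
  u_r <- make_audio(c(70, 70, 75, 100, 95, 85, 80), ear = "right")
  expect_identical(ear_symmetry(flat_l, u_r), "asymmetric")
  expect_identical(ear_symmetry(flat_l, make_audio(rep(85, 7), ear = "right")),
                   "asymmetric")  # same shape, 20 dB gap
  expect_identical(ear_symmetry(flat_l, NULL), "unknown")
})

test_that("band means average the low/mid/high frequency bands", {
  bm <- band_means(make_audio(c(20, 20, 20, 40, 60, 90, 90)))
  expect_equal(unname(bm), c(20, 50, 90))
  expect_equal(unname(band_means(make_audio(rep(30, 7)))), c(30, 30, 30))
  low_only <- audiogram("p", 4, "left", c("250" = 20, "500" = 40))
  expect_equal(band_means(low_only)[["low"]], 30)
  expect_true(is.na(band_means(low_only)[["high"]]))
})
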