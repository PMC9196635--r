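#' Audiometric frequencies and constructors
#'
#' Audiograms are represented as lightweight records: thresholds in dB HL at a
#' subset of the standard octave frequencies 125--8000 Hz for one ear at one
#' visit, with per-frequency no-response flags (no response at the
#' audiometer's maximum output).
#'
#' @param patient_id patient key.
#' @param visit_age age at examination, years (fractional allowed).
#' @param ear `"left"` or `"right"`.
#' @param thresholds named numeric vector, names are frequencies in Hz from
#'   `audiometric_frequencies()`, values in dB HL within \[-10, 130\].
#' @param no_response numeric vector of frequencies with no response at
#'   maximum output; disjoint from `names(thresholds)`.
#' @param method `"pure_tone"` (behavioural) or `"assr"` (auditory
#'   steady-state response, used below ~6 years of age).
#' @return An object of class `"audiogram"`.
#' @export
audiogram <- function(patient_id, visit_age, ear, thresholds,
                      no_response = numeric(0), method = "pure_tone") {
  ear <- match.arg(ear, c("left", "right"))
  method <- match.arg(method, c("pure_tone", "assr"))
  freqs <- as.numeric(names(thresholds))
  if (length(thresholds) && (is.null(names(thresholds)) || anyNA(freqs)))
    stop("thresholds must be named by frequency in Hz")
  bad_f <- setdiff(c(freqs, no_response), audiometric_frequencies())
  if (length(bad_f))
    stop(sprintf("frequencies outside the audiometric set: %s",
                 paste(bad_f, collapse = ", ")))
  if (any(thresholds < -10 | thresholds > 130))
    stop("thresholds must lie in [-10, 130] dB HL")
  if (length(intersect(freqs, no_response)))
    stop("a frequency cannot both carry a threshold and be flagged no-response")
  structure(list(patient_id = patient_id, visit_age = as.numeric(visit_age),
                 ear = ear, thresholds = thresholds,
                 no_response = as.numeric(no_response), method = method),
            class = "audiogram")
}

#' @rdname audiogram
#' @export
audiometric_frequencies <- function() c(125, 250, 500, 1000, 2000, 4000, 8000)

# frequencies with any assessment (threshold or no-response)
tested_frequencies <- function(ag) {
  sort(c(as.numeric(names(ag$thresholds)), ag$no_response))
}

# thresholds with no-response imputed at the stated ceiling
effective_thresholds <- function(ag, no_response_db = 120) {
  th <- ag$thresholds
  if (length(ag$no_response)) {
    nr <- stats::setNames(rep(no_response_db, length(ag$no_response)), ag$no_response)
    th <- c(th, nr)
  }
  th[order(as.numeric(names(th)))]
}

#' Pure-tone average
#'
#' Arithmetic mean of the thresholds at 0.5, 1, 2 and 4 kHz, the four
#' frequencies used for severity grading. A no-response at a PTA frequency is
#' imputed at `no_response_db` (default 120 dB HL, near common equipment
#' maxima, so profiles "over 110 dB" stay profound).
#'
#' @param ag an [audiogram()].
#' @param no_response_db imputation value for no-response frequencies, dB HL.
#' @return PTA in dB HL.
#' @export
pta <- function(ag, no_response_db = 120) {
  th <- effective_thresholds(ag, no_response_db)
  need <- c(500, 1000, 2000, 4000)
  missing <- setdiff(need, as.numeric(names(th)))
  if (length(missing))
    stop(sprintf("PTA frequencies missing (no threshold, no no-response flag): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  mean(th[as.character(need)])
}

#' ASHA severity band for a pure-tone average
#'
#' Bands partition the line: normal (<= 25), mild (25.1--40), moderate
#' (40.1--55), moderately severe (55.1--70), severe (70.1--90), profound
#' (> 90, including total deafness). Band edges are closed on the right.
#'
#' @param pta_db PTA in dB HL (vectorised).
#' @return Character vector of severity bands.
#' @export
severity <- function(pta_db) {
  stopifnot(is.numeric(pta_db), all(is.finite(pta_db)))
  as.character(cut(pta_db,
                   breaks = c(-Inf, 25, 40, 55, 70, 90, Inf),
                   labels = c("normal", "mild", "moderate", "moderately_severe",
                              "severe", "profound"),
                   right = TRUE))
}

#' Audiogram shape configuration
#'
#' Rule-based shape classes, tested in precedence order:
#' complete deafness (no response at every tested frequency), residual
#' (responses at no more than `residual_max_responses` frequencies), U-shaped
#' (worst mid-frequency 1--2 kHz threshold exceeds both the worst low-side and
#' worst high-side thresholds by >= 10 dB), down-sloping (mean 4--8 kHz
#' threshold at least 15 dB above the better of the 250/500 Hz thresholds),
#' ascending (mean 250--500 Hz threshold at least 15 dB above the better
#' 4--8 kHz threshold), flat (total range over all tested 125--8000 Hz
#' thresholds <= 15 dB), else unclassified. Precedence resolves overlaps: a
#' steep slope also fails "flat", and a deep U would otherwise satisfy a slope
#' rule on one limb.
#'
#' @param ag an [audiogram()].
#' @param residual_max_responses maximum number of responsive frequencies for
#'   the residual class.
#' @param no_response_db imputation for no-response thresholds in slope rules.
#' @return One of `"down_sloping"`, `"flat"`, `"u_shaped"`, `"ascending"`,
#'   `"residual"`, `"complete_deafness"`, `"unclassified"`. When no rule has
#'   sufficient frequencies the result is `"unclassified"` with a `reason`
#'   attribute.
#' @export
audiogram_shape <- function(ag, residual_max_responses = 2, no_response_db = 120) {
  tested <- tested_frequencies(ag)
  if (!length(tested)) {
    return(structure("unclassified", reason = "no tested frequencies"))
  }
  if (length(ag$no_response) && !length(ag$thresholds)) return("complete_deafness")
  if (length(ag$thresholds) <= residual_max_responses && length(ag$no_response))
    return("residual")

  th <- effective_thresholds(ag, no_response_db)
  f <- as.numeric(names(th))
  low <- th[f <= 500]
  low_edge <- th[f %in% c(250, 500)]
  mid <- th[f %in% c(1000, 2000)]
  high <- th[f %in% c(4000, 8000)]

  if (length(mid) && length(low) && length(high) &&
      max(mid) - max(low) >= 10 && max(mid) - max(high) >= 10)
    return("u_shaped")
  if (length(low_edge) && length(high) && mean(high) - min(low_edge) >= 15)
    return("down_sloping")
  if (length(low_edge) && length(high) && mean(low_edge) - min(high) >= 15)
    return("ascending")
  if (length(th) >= 2 && max(th) - min(th) <= 15) return("flat")
  if (!length(low_edge) || !length(high) || length(th) < 2)
    return(structure("unclassified",
                     reason = "insufficient frequencies for slope and flat rules"))
  "unclassified"
}

#' Hearing-loss progression across visits
#'
#' Progressive iff any ear's PTA rises by at least `threshold_db` between
#' consecutive visits; `"unknown"` without a second visit for at least one
#' ear. With `per_frequency = TRUE` a >= `threshold_db` rise at any single
#' shared frequency also counts (the response-threshold reading of the rule).
#'
#' @param audiograms list of [audiogram()] for one patient (any order; sorted
#'   by visit age internally, per ear).
#' @param threshold_db dB rise defining progression (default 15).
#' @param per_frequency also compare per-frequency thresholds.
#' @return `"progressive"`, `"stable"` or `"unknown"`.
#' @export
progression <- function(audiograms, threshold_db = 15, per_frequency = FALSE) {
  stopifnot(length(audiograms) > 0)
  ears <- split(audiograms, vapply(audiograms, `[[`, "", "ear"))
  any_pair <- FALSE
  for (series in ears) {
    ages <- vapply(series, `[[`, 0, "visit_age")
    if (anyDuplicated(ages))
      stop("duplicate visit ages for one ear; visit ordering is ambiguous", call. = FALSE)
    series <- series[order(ages)]
    if (length(series) < 2) next
    any_pair <- TRUE
    ptas <- vapply(series, pta, 0)
    if (any(diff(ptas) >= threshold_db)) return("progressive")
    if (per_frequency) {
      for (i in seq_len(length(series) - 1)) {
        a <- effective_thresholds(series[[i]]); b <- effective_thresholds(series[[i + 1]])
        shared <- intersect(names(a), names(b))
        if (length(shared) && any(b[shared] - a[shared] >= threshold_db))
          return("progressive")
      }
    }
  }
  if (!any_pair) "unknown" else "stable"
}

#' Interaural symmetry at one visit
#'
#' Asymmetric iff the two ears' shape classes differ or the interaural PTA gap
#' is at least `pta_gap_db` (default 20 dB); else symmetric. Published cohort
#' tables label symmetry without defining it; this rule reproduces the
#' case-study cohort's printed asymmetric patients.
#'
#' @param left,right [audiogram()] objects for the same visit.
#' @param pta_gap_db interaural PTA difference defining asymmetry.
#' @return `"symmetric"`, `"asymmetric"`, or `"unknown"` if an ear is missing.
#' @export
ear_symmetry <- function(left, right, pta_gap_db = 20) {
  if (is.null(left) || is.null(right)) return("unknown")
  if (as.character(audiogram_shape(left)) != as.character(audiogram_shape(right)))
    return("asymmetric")
  if (abs(pta(left) - pta(right)) >= pta_gap_db) return("asymmetric")
  "symmetric"
}

#' Frequency-band mean thresholds
#'
#' Mean threshold within the low (125--500 Hz), mid (1--2 kHz) and high
#' (4--8 kHz) bands; a band with no tested frequency is `NA`.
#'
#' @param ag an [audiogram()].
#' @param no_response_db imputation for no-response thresholds.
#' @return Named numeric vector `c(low=, mid=, high=)` in dB HL.
#' @export
band_means <- function(ag, no_response_db = 120) {
  th <- effective_thresholds(ag, no_response_db)
  f <- as.numeric(names(th))
  m <- function(sel) if (any(sel)) mean(th[sel]) else NA_real_
  c(low = m(f <= 500), mid = m(f >= 1000 & f <= 2000), high = m(f >= 4000))
}

#' Assess a long-format audiogram table
#'
#' Convenience wrapper over the per-ear rules: takes the long CSV
#' representation (one row per patient/visit/ear/frequency; see
#' [read_audiograms()]), builds [audiogram()] records, and returns per
#' patient-visit-ear assessments plus per-patient symmetry (at the latest
#' visit with both ears) and progression across visits.
#'
#' @param df long data frame with columns `patient_id`, `visit_age`, `ear`,
#'   `freq_hz`, `threshold_db`, `no_response`.
#' @return List with elements `assessments` (per ear-visit: PTA, severity,
#'   shape, band means) and `patients` (per patient: symmetry, progression).
#' @export
assess_audiograms <- function(df) {
  ags <- audiograms_from_long(df)
  rows <- lapply(ags, function(ag) {
    bm <- band_means(ag)
    p <- pta(ag)
    data.frame(patient_id = ag$patient_id, visit_age = ag$visit_age, ear = ag$ear,
               pta = p, severity = severity(p),
               shape = as.character(audiogram_shape(ag)),
               low_db = bm[["low"]], mid_db = bm[["mid"]], high_db = bm[["high"]],
               stringsAsFactors = FALSE)
  })
  assessments <- do.call(rbind, rows)

  per_patient <- lapply(split(ags, vapply(ags, function(a) as.character(a$patient_id), "")),
                        function(pags) {
    ages <- vapply(pags, `[[`, 0, "visit_age")
    sym <- "unknown"
    for (age in sort(unique(ages), decreasing = TRUE)) {
      at <- pags[ages == age]
      ears <- vapply(at, `[[`, "", "ear")
      if (all(c("left", "right") %in% ears)) {
        sym <- ear_symmetry(at[[match("left", ears)]], at[[match("right", ears)]])
        break
      }
    }
    data.frame(patient_id = pags[[1]]$patient_id, symmetry = sym,
               progression = progression(pags), stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, per_patient)
  rownames(patients) <- NULL
  list(assessments = assessments, patients = patients)
}

# long data frame -> list of audiogram objects (one per patient/visit/ear)
audiograms_from_long <- function(df) {
  need <- c("patient_id", "visit_age", "ear", "freq_hz", "threshold_db", "no_response")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("audiogram table lacks mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  key <- interaction(df$patient_id, df$visit_age, df$ear, drop = TRUE)
  lapply(split(df, key), function(g) {
    nr <- as.logical(g$no_response)
    th <- stats::setNames(g$threshold_db[!nr], g$freq_hz[!nr])
    method <- if ("method" %in% names(g)) g$method[1] else "pure_tone"
    audiogram(g$patient_id[1], g$visit_age[1], g$ear[1], th,
              no_response = g$freq_hz[nr], method = method)
  })
}
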