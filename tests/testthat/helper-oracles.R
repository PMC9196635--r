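# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive enumerations, structurally different from the
# package code paths they validate.

# --- ACMG combining oracle: explicit rule-table walk on category counts -----

oracle_combine_counts <- function(counts) {
  meets <- function(req) all(counts[names(req)] >= req)
  p_rules <- list(c(PVS = 1, PS = 1), c(PVS = 1, PM = 2), c(PVS = 1, PM = 1, PP = 1),
                  c(PVS = 1, PP = 2), c(PS = 2), c(PS = 1, PM = 3),
                  c(PS = 1, PM = 2, PP = 2), c(PS = 1, PM = 1, PP = 4))
  lp_rules <- list(c(PVS = 1, PM = 1), c(PS = 1, PM = 1), c(PS = 1, PP = 2),
                   c(PM = 3), c(PM = 2, PP = 2), c(PM = 1, PP = 4))
  b_rules <- list(c(BA = 1), c(BS = 2))
  lb_rules <- list(c(BS = 1, BP = 1), c(BP = 2))

  path <- if (any(vapply(p_rules, meets, TRUE))) "Pathogenic"
          else if (any(vapply(lp_rules, meets, TRUE))) "Likely Pathogenic"
          else "Uncertain Significance"
  ben <- if (any(vapply(b_rules, meets, TRUE))) "Benign"
         else if (any(vapply(lb_rules, meets, TRUE))) "Likely Benign"
         else "Uncertain Significance"
  any_p <- sum(counts[c("PVS", "PS", "PM", "PP")]) > 0
  any_b <- sum(counts[c("BA", "BS", "BP")]) > 0

  if (path != "Uncertain Significance" && ben != "Uncertain Significance")
    return("Uncertain Significance")
  if (path == "Pathogenic") return("Pathogenic")
  if (path == "Likely Pathogenic")
    return(if (any_b) "Uncertain Significance" else "Likely Pathogenic")
  if (ben == "Benign") return("Benign")
  if (ben == "Likely Benign")
    return(if (any_p) "Uncertain Significance" else "Likely Benign")
  "Uncertain Significance"
}

# all category-count combinations with per-category caps
enumerate_count_grids <- function(caps = c(PVS = 1, PS = 3, PM = 3, PP = 3,
                                           BA = 1, BS = 3, BP = 3)) {
  grid <- expand.grid(lapply(caps, function(k) 0:k))
  names(grid) <- names(caps)
  grid
}

# --- phasing oracle: brute-force over Mendelian transmission ----------------

# possible phases of a child-het variant pair given full parental carriage:
# enumerate every consistent assignment of parental origin; two variants
# transmitted by the same parent must share the single transmitted haplotype
# (cis); different parents means trans. Ambiguity -> "unknown".
oracle_phase <- function(m1, f1, m2, f2) {
  carriers <- function(m, f) c("mother", "father")[c(m, f)]
  c1 <- carriers(m1, f1); c2 <- carriers(m2, f2)
  if (!length(c1) || !length(c2)) return("unknown")  # apparent de novo
  phases <- unique(unlist(lapply(c1, function(o1)
    vapply(c2, function(o2) if (o1 == o2) "cis" else "trans", ""))))
  if (length(phases) == 1) phases else "unknown"
}

# --- small constructors -----------------------------------------------------

call1 <- function(variant_id, zyg = "het", m = NA, f = NA, gene = "G1",
                  trio_id = "T1") {
  trio_calls(variant_id, gene, zyg, m, f, trio_id = trio_id)
}

make_audio <- function(th, ear = "left", id = "pt", age = 5,
                       freqs = audiometric_frequencies(), no_response = numeric(0)) {
  audiogram(id, age, ear, stats::setNames(th, freqs[seq_along(th)]),
            no_response = no_response)
}
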