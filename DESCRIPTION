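Package: hlct
Title: Trio Segregation, ACMG Classification and Audiogram Phenotyping for
    Recessive Hearing-Loss Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of autosomal-recessive
    non-syndromic hearing loss cohorts such as LOXHD1/DFNB77. Implements
    trio-based candidate variant selection (homozygous, compound-heterozygous
    and de novo models) with compound-heterozygote phasing and cis-passenger
    exclusion, an ACMG/AMP evidence-code combining engine, HGVS-based
    molecular consequence inference, rule-based audiogram phenotyping
    (pure-tone average, ASHA severity bands, shape configuration, progression,
    symmetry), and cohort-level statistics (prevalence, cohort allele
    frequencies, recurrent variants, domain and truncation genotype
    groupings). Ships a transcribed 33-variant / 21-patient LOXHD1 case-study
    cohort and a synthetic trio-cohort simulator so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
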