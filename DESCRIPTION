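Package: hapflow
Title: Local Ancestry, Haplotype Migration and Selection Scans for Admixed Populations
Version: 0.1.0
Authors@R: person("Hapflow", "Developers", email = "hapflow@example.org",
    role = c("aut", "cre"))
Description: Window-based local-ancestry inference for admixed cohorts against
    parental haplotype panels, a haplotype-migration statistic contrasting the
    observed frequency of a parental breed's most frequent window haplotype in
    the admixed cohort with the frequency expected from local ancestry alone,
    and extended-haplotype-homozygosity selection scans (iHS, Rsb) plus
    single-marker Hudson F_ST. Includes a synthetic-data generator (diverged
    parental breeds under the Balding-Nichols model, Markov ancestry tracts,
    planted haplotype-frequency shifts) for calibration and power testing, and
    phased-VCF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    yaml,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
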