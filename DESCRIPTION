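Package: trxpka
Title: Titration Analysis and Extended Active-Site Motifs for
    Thioredoxin-Fold Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of the ionization equilibria that control the
    reactivity of thioredoxin-fold thiol-disulfide oxidoreductases.
    Provides closed-form one- and two-pKa chemical-shift titration models
    and a four-microstate model for two coupled titratable sites with
    exact microscopic/macroscopic constant conversions; multi-start
    Levenberg-Marquardt fitting of NMR pH-titration series with nested
    model selection and cross-resonance aggregation; replicate
    densitometry statistics with propagated uncertainties for in vivo
    activity assays; detection of -CXXC- active-site motifs, extraction of
    the extended active-site positions, conservation tabulation, and a
    qualitative electrostatic classification of active sites; and seeded
    synthetic-data generators for titration series, replicate tables, and
    motif sequence sets with ground-truth echoes for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
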