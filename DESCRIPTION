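Package: dyadmet
Title: Shape Discovery in Paired Maternal-Cord Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential-metabolite discovery for mother-offspring dyad
    cohorts stratified by birthweight group (small-, appropriate- and
    large-for-gestational-age). Implements NIPALS partial least squares
    discriminant analysis (PLS-DA) and orthogonal PLS-DA with variable
    importance in projection (VIP) scores and cross-validated R2/Q2,
    four-way differential-metabolite intersection, fold-change based
    classification of U-shaped and line-shaped metabolites, crude and
    covariate-adjusted (partial) Spearman correlation of metabolites with
    clinical phenotypes, Fisher-Freeman-Halton exact r x c tests and
    one-way ANOVA from raw data or printed summary statistics, and a
    synthetic dyad-cohort generator with planted metabolite classes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
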