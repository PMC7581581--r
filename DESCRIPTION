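Package: chromassay
Title: Quantification and Statistics for Crustacean Chromatophore
    Background-Adaptation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying physiological colour change in
    crustaceans from staged chromatophore grades and from segment
    photographs. Implements the chromatophore coefficient (20 x mean
    dispersion stage over all graded cells, ranging 20 to 100), a
    deterministic percent-dark-cover image pipeline (8-bit greyscale,
    disk-shaped median filter, Otsu thresholding within a region of
    interest), blinding utilities, and the mixed-design repeated-measures
    ANOVA battery used for background-adaptation assays
    (Greenhouse-Geisser correction, partial eta squared,
    Bonferroni-adjusted pairwise post hocs, Pearson correlation). A
    seeded synthetic-cohort generator built on a latent ordered-category
    model produces ground-truthed stage counts and rendered segment
    images so the whole pipeline can be exercised and validated without
    any laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    EBImage,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
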