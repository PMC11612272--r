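Package: celiachif
Title: Quantitative Human-Interpretable Histology Features for Celiac Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream quantification of celiac-disease histology from
    tissue-class label maps and classified cell point sets. Computes
    human-interpretable features (HIFs) of duodenal mucosa -- villous
    atrophy area proportions, crypt hyperplasia, intraepithelial
    lymphocyte densities and count proportions, lamina propria
    inflammation -- after artifact exclusion; validates cell calls
    against a multi-annotator Dawid-Skene consensus with per-labeler
    sensitivity and specificity; and runs cohort statistics (Spearman
    correlation with ordinal modified Marsh grade, independent t-tests
    normal vs. celiac, including a summary-statistic Welch form). A
    synthetic-histology generator produces graded label maps, cell
    point sets, artifact masks and simulated annotators so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
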