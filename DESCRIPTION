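Package: triadnet
Title: Bayesian Association Networks and Tripartite Triangle Motifs for
    Microbiome-Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links faecal metagenome structure and function to symptom
    severity in clinical cohorts. Provides readers for genus-level
    taxonomic and KEGG-module functional abundance tables, compositional
    preprocessing (prevalence filtering, centred log-ratio transformation,
    nuisance-covariate adjustment), pairwise Bayesian association testing
    with Jeffreys-Zellner-Siow priors, construction of joint
    taxon-module-symptom association networks, and enumeration of
    tripartite triangle motifs. Includes a synthetic cohort generator
    with planted associations so that every stage of the analysis can be
    exercised and calibrated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
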