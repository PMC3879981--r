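Package: clanprof
Title: Phylogenomic Affinity Profiling of a Focal Lineage with Clan
    Analysis and Lateral Gene Transfer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the phylogenomic affinities of a small
    focal clade (modelled on the three sequenced Aquificae genomes) against
    candidate partner lineages such as the Archaea, Epsilonproteobacteria
    and Thermotogae.  Builds homologous clusters from all-vs-all protein
    similarity searches using a two-threshold reciprocal-hit graph,
    constructs phyletic presence/absence profiles with exclusive/inclusive
    pattern labels, classifies ranked homolog profiles as clean or dirty,
    detects homogeneous clans in unrooted gene trees, scores the balance of
    bootstrap support between competing partner lineages, computes the
    Variable Preference Index per functional category, and summarises
    category-by-lineage tree affinities.  Includes a synthetic-data
    generator with planted lateral gene transfer events for end-to-end
    validation against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
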