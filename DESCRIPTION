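Package: fmtpipe
Title: Cross-Host Microbiome Analysis for Fecal Microbiota Transplantation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired donor/recipient microbiome studies built
    around fecal microbiota transplantation (FMT) across host species. Provides
    readers for OTU and KEGG Orthology (KO) abundance tables, sample metadata,
    rooted phylogenies and KO-to-pathway maps; alpha diversity indices;
    a phylogeny-weighted community similarity with a Bray-Curtis star-tree limit;
    PERMANOVA, principal coordinate/component ordination and Procrustes
    Monte-Carlo concordance; Wilcoxon rank-sum marker discovery with
    Benjamini-Hochberg control; reporter-Z pathway enrichment; OTU-KO Spearman
    co-occurrence networks; and donor-versus-recipient overlap and
    amplification-effect statistics. A Dirichlet-multinomial study generator with
    planted differential structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    biomformat,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
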