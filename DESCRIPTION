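Package: resourcescape
Title: Resource-Based Functional Diversity of Communities and Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dendrogram-based functional diversity (FD) for ecological
    communities and for landscapes characterized by the resources their
    habitats provide. Implements Gower distances on mixed binary/ordinal
    resource matrices, UPGMA functional dendrograms, FD as the branch length
    connecting the components present in a sampling unit,
    occurrence-weighted null models and standardized FD (sFD),
    maximum-likelihood simultaneous autoregressive (SAR) spatial-error
    regression with distance-band weights and Moran's I diagnostics,
    LMG (Shapley) decomposition of explained variance, and a synthetic-data
    generator with tunable environmental filtering for end-to-end testing
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
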