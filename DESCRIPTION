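Package: funhill
Title: Distance-Based Functional Diversity via Hill Numbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional diversity measures that extend Hill numbers to
    incorporate species pairwise functional distances. Provides functional
    Hill numbers (the effective number of equally abundant and equally
    distinct species), mean and total functional diversity, Rao's quadratic
    entropy and related legacy measures, multiplicative gamma/alpha/beta
    decomposition over any number of assemblages under absolute- or
    relative-abundance pooling, and four classes of normalized functional
    similarity and differentiation measures generalizing the Sorensen,
    Jaccard, Horn and Morisita-Horn indices. Includes Gower distances from
    mixed quantitative/categorical trait tables, ultrametricity diagnostics,
    readers and writers for community and distance tables, and generators
    for the worked examples used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
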