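Package: trophnet
Title: Directed Trophallaxis Networks and Permutation Inference for Honey Bee Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed, duration-weighted food-sharing (trophallaxis)
    networks from timed event logs of individually marked honey bees, computes
    the standard centrality and mixing measures on them (degree and strength
    split by direction, betweenness, eigenvector centrality, density, nominal
    and numeric assortativity), and tests group differences with restricted
    node-permutation null models. Time-ordered networks support a
    perfect-transmission spread simulation with time-permutation nulls for
    comparing the epidemic reach of worker groups. A synthetic colony
    generator with tunable age-assortative mixing and planted group effects
    provides a ground-truth test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
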