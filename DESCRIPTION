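Package: cascadeflow
Title: Engagement Dynamics and Information Flow in Retweet Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how a tagged content category (for example
    links to vaccine-critical websites) circulates in a stream of tweets and
    retweets. Implements a susceptible-infected-susceptible style estimator of
    daily engagement and disengagement rates and their ratio, the reproduction
    number of content adoption; a directed hyper-graph representation of
    retweet cascades with its random-walk transition operator, stationary
    distribution and edge flows; flow-based community detection by greedy
    maximization of the one-step flow auto-covariance; per-community visit and
    escape probabilities on content-restricted and per-period sub-graphs;
    hashtag and URL over-usage profiling with hierarchical co-clustering; and
    a synthetic event-stream generator with planted communities and known
    ground truth for end-to-end validation.
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
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
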