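Package: isopodSD
Title: Sex Determination System Inference in Terrestrial Isopods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inference machinery for the evolution of sex determination
    systems in terrestrial isopods. Provides a Mendelian model of crosses
    between sex-reversed females (neomales) and their sisters that predicts
    progeny sex ratios under male (XY/XX) and female (ZZ/ZW) heterogamety,
    including Wolbachia cytoplasmic feminization; a brood-filtering and
    chi-square classification pipeline that calls a species' heterogametic
    system and the viability of the WW genotype from F1 sex ratios; and
    discrete-character methods (Sankoff parsimony with exhaustive
    enumeration of most-parsimonious reconstructions, Mk-model likelihood
    with ER and SYM parameterizations, marginal ancestral states, and
    endpoint-conditioned stochastic character mapping) to count transitions
    between sex chromosome systems on a dated phylogeny. Ships a dated
    isopod phylogeny fixture and heterogametic-type state table, plus
    simulators for crossing experiments and Mk character histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
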