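Package: kincomp
Title: Kinship Composition of Mammal Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic model of the kinship composition of mammal social
    groups: the proportions of full siblings, maternal half-siblings, paternal
    half-siblings and non-siblings among juveniles born into a group, as a
    function of group size, male and female reproductive skew, litter size,
    dominance tenure and pair-bond stability. Includes a Monte-Carlo
    parameter-sweep engine ("fitting to idealised outcomes") with Spearman
    rank-correlation sensitivity tables, threshold summaries and histogram
    exports, plus a command-line interface for composing single groups and
    running sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
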