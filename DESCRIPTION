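Package: ednasurvey
Title: Post-Processing and Design Evaluation for eDNA Metabarcoding Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the post-sequencing stages of environmental DNA
    (eDNA) metabarcoding surveys built around replicated sampling events,
    such as waterhole monitoring of terrestrial vertebrates. Provides
    occurrence-catalog plausibility filtering of taxonomic assignments
    with a full audit trail (accept, reassign to a unique documented
    congener, or exclude), pooling of replicate samples into sampling
    events, detection-frequency and richness statistics, species-overlap
    summaries, community distance matrices, permutation species
    accumulation curves, mixed-substrate sampling-design comparison, and
    a two-level Bernoulli survey simulator with known truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
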