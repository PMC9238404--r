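Package: fomitetrack
Title: Invasion-Ecology Analysis of Fomite Transmission on Surface Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking a microbial invader through a network of
    touched surfaces. Builds microbiota-invader networks (MIN) and
    co-occurrence networks (MCN) from genus-level Spearman correlations with
    false-discovery-rate control, fits the Sloan neutral community model with
    hands as source and private inanimate surfaces as sink to classify
    amplicon sequence variants as above-, below- or neutrally distributed,
    constructs surface touch networks from contact logs (geodesic distance,
    eigencentrality, bipartite hand-hand intimacy projection), and quantifies
    the proximity effect of a root carrier on surface contamination. Includes
    a synthetic office simulator that generates ground-truthed touch logs and
    pre/post microbiota count tables for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
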