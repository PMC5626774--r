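Package: codres
Title: Composite Drug Repurposing Score and Consensus Re-Ranking
Version: 1.0.0
Authors@R: person("codres", "maintainers", email = "codres@example.org",
    role = c("aut", "cre"))
Description: Re-ranks candidate inhibitor drugs from connectivity-map style
    repurposing screens with a composite score (CoDReS) that combines a
    per-stage normalized inhibition score with structural druglikeness,
    disease-functional relevance and side-effect severity, each normalized to
    [0, 1]. Includes the surrounding machinery: gene-signature construction
    from differential-expression tables, two-of-three tool and dataset
    consensus filters, rank-shift reporting against the inhibition-only
    ordering, hierarchical clustering of binary molecular fingerprints under
    the Soergel distance with Ward linkage and top-scored cluster
    representatives, pathway-list set consensus, and drug/microRNA common
    gene-target analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
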