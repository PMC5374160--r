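Package: egoident
Title: Agent-Based Dynamics of Bicultural Identification on Ego Networks
Version: 1.0.0
Authors@R:
    person("Egoident", "Maintainers", email = "maintainers@egoident.org",
           role = c("aut", "cre"))
Description: Simulates how a focal individual's (ego's) identification with
    two cultures changes through repeated random interactions with the eight
    members (alters) of their personal network, under three influence
    mechanisms: a positive effect (interaction raises identification with the
    partner's culture), a negative effect (interaction lowers identification
    with the other culture), and an alpha-weighted mixture of the two.
    Influence is weighted by each alter's same-culture degree centrality, and
    identifications are bounded on a 1-6 scale. Provides an ego-network
    representation with generation, validation, I/O and composition/structure
    metrics (group sizes, inter-class tie weights); a full-factorial sweep
    engine over culture ratios, tie counts, mechanisms and replicates with
    per-cell summaries; exhaustive-enumeration and closed-form verification
    oracles; and command-line entry points with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
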