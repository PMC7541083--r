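Package: aplspread
Title: Localized Feedback Inhibition on Neurite Skeletons of the Drosophila Mushroom Body
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models how far activity spreads along the anterior paired lateral
    (APL) neuron of the Drosophila mushroom body and what that implies for
    feedback inhibition between Kenyon cells. Reads SWC neurite skeletons and
    synapse tables, maps synapses onto the skeleton, computes along-skeleton
    distances in real or electrotonic (radius-normalized) space using
    truncated-cone segment geometry, and builds the exponentially weighted
    inhibition matrix s(k1,k2) between Kenyon cell pairs together with
    self- versus lateral-inhibition imbalance summaries and shuffle nulls.
    Also includes passive-cable parameter conversions, a random-point
    activity-spread simulation on the skeleton, backbone/Voronoi segmentation
    of volumetric calcium-imaging movies with dF/F quantification, an
    expression screen over cell-type TPM tables, and seeded synthetic-data
    generators for all inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
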