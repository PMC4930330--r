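Package: glomwire
Title: Analysis of Glomerular Olfactory Wiring Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synapse-resolution wiring diagrams of
    glomerular olfactory circuits, such as the antennal lobe of the Drosophila
    larva. Assembles neuron rosters, skeletons and polyadic synapse tables into
    a validated wiring diagram; builds synapse-count and input-fraction
    matrices with a bilateral-consistency (homologous left/right) filter;
    labels axonal and dendritic compartments and measures cable lengths and
    geodesic distances of postsynaptic sites to the axon initial segment;
    takes a census of circuit motifs (direct, lateral and incoherent
    feedforward-loop inputs, interneuron hierarchies, reciprocal inhibition
    cores); and clusters olfactory receptor neurons by odor tuning via
    principal components, affinity propagation and Otsu thresholding of
    back-projected cluster centroids. A synthetic generator produces mirrored
    left/right diagrams and response matrices with known ground truth so the
    whole pipeline is testable without any reconstruction data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
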