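Package: plimotif
Title: Mining Conserved Motifs at Protein-Ligand Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved interaction motifs at protein-ligand
    interfaces from 3D structures. Complexes in PDB format are reduced to
    typed bipartite graphs in which nodes are heavy atoms labeled by
    physicochemical type (acceptor, aromatic, donor, hydrophobic, negative,
    positive) and edges are non-covalent interactions (aromatic stacking,
    hydrogen bond, hydrophobic, repulsive, salt bridge) classified by
    Euclidean distance criteria. Graphs are featurized by endpoint-property
    path descriptors, reduced with SVD and clustered (k-medoids,
    agglomerative or spectral); each cluster is mined for frequent connected
    labeled subgraphs with a gSpan-style canonical DFS-code search over a
    support sweep, maximal motifs are retained and mapped back onto every
    input graph by labeled subgraph isomorphism. Includes a synthetic-data
    generator for micro-complexes and planted-motif graph collections plus
    brute-force oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    bio3d,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
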