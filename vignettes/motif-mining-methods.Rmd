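---
title: "Methods: interface graphs, clustering and motif mining in plimotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface graphs, clustering and motif mining in plimotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plimotif)
```

plimotif detects conserved interaction motifs across a collection of
protein–ligand complexes by mining frequent labeled subgraphs of typed
bipartite interface graphs. This vignette documents the model, the
parameters that matter, the numerical conventions, and the design choices
made where the design was genuinely open — in enough detail that a
maintainer could re-derive every behavior from this text.

## The interface model

One interface = one (chain, ligand instance) pair. From a parsed PDB
structure we keep the first model only (one geometry per complex;
multi-conformer contact computation is out of scope), collapse alternate
locations to the highest-occupancy conformer (ties broken by the
alphabetically first alt-loc label), and strip all hydrogens and
deuteriums. Hydrogen removal makes X-ray, NMR and neutron structures
comparable: only the latter two record hydrogen positions, and
distance-window classification must not depend on the experimental
method.

Ligands are hetero residues of the query chain that are not water
(HOH/DOD/WAT), not standard amino acids, and have at least 6 heavy atoms —
smaller groups (sulfate, glycerol, ions) are almost always crystallization
additives rather than biological ligands. Each (het code, residue number,
chain) triple is its own ligand instance, so a chain binding two copies of
one compound yields two graphs. Modified residues recorded as HETATM
within the polymer (e.g. MSE) are neither protein nor ligand by default;
their typing is undefined in the residue table, and an override file can
reinstate them. Ligands assigned to other chains are not considered even
if they contact the query chain — the instance list is restricted to the
chain the user asked about, which keeps the per-graph provenance
unambiguous.

## Atom typing

Six types label the nodes: acceptor, aromatic, donor, hydrophobic,
negative, positive; an atom may carry several (a phenylalanine ring carbon
is aromatic *and* hydrophobic). Protein atoms are typed by a shipped,
versioned lookup table (`inst/extdata/protein_atom_types.tsv`) covering
every heavy atom of the 20 standard residues, built from standard
pharmacophore conventions: backbone N donor (except proline), backbone O
acceptor, carboxylates acceptor+negative, LYS NZ and the arginine
guanidinium nitrogens donor+positive, SER/THR/TYR hydroxyls
donor+acceptor, carbons hydrophobic exactly when all their heavy
neighbours are carbon, and the PHE/TYR/TRP/HIS ring atoms aromatic.
Histidine's ring nitrogens are typed donor+acceptor without charge — the
neutral tautomer is the common species at pH 7, and committing to a
charged imidazolium would manufacture salt bridges the data do not
support. Users with their own table can substitute the TSV wholesale.

Ligand atoms have no residue dictionary, so they are typed by rule-based
perception at fixed pH 7 (no titration or pKa computation):

* bonds are perceived from interatomic distances against covalent-radius
  sums plus 0.45 Å of tolerance;
* a 5- or 6-ring of C/N/O/S whose carbons are at most 3-coordinate and
  whose atoms deviate at most 0.10 Å from their best-fit plane is
  aromatic. The planarity threshold separates heteroaromatic rings
  (deviations near zero) from puckered sugars and cyclohexanes
  (envelope/chair deviations well above 0.2 Å);
* terminal oxygens on phosphorus or sulfur, and both oxygens of a
  carboxylate, are acceptor+negative (fully deprotonated at pH 7);
  bridging/ether oxygens are acceptor; a terminal C–O bond shorter than
  1.32 Å is a carbonyl (acceptor), longer is a hydroxyl (donor+acceptor) —
  the bond-length test substitutes for the hydrogen that was stripped;
* amines and guanidinium-like nitrogens are donor+positive (protonated at
  pH 7); amide and aniline-like nitrogens donor only; two-coordinate
  aromatic nitrogens donor+acceptor, mirroring the histidine convention;
* carbons bonded only to carbon are hydrophobic; metals and other exotic
  elements type as the empty set with a warning and simply form no edges.

These rules are a deliberate, documented replacement for proprietary
pharmacophore software; where they disagree with a user's preferred
perception, a TSV override file keyed by (het code, atom name) wins over
the rules atom by atom.

## Contacts and interaction classification

Contacts are cross pairs only (protein × ligand; never within one
molecule), using plain Euclidean distance with inclusive bounds. The
default windows are: aromatic stacking 1.5–3.5 Å (both atoms aromatic),
hydrogen bond 2.0–3.0 Å (one acceptor, one donor, either orientation),
hydrophobic 2.0–3.8 Å (both hydrophobic), repulsive 2.0–6.0 Å (same
charge), salt bridge 2.0–6.0 Å (opposite charge). All five windows are
user-adjustable (`readCriteria()`); the aromatic-stacking lower bound of
1.5 Å admits physically implausible clashes but is kept as the standard
default rather than silently corrected. Classification is evaluated
atom-pairwise — aromatic stacking is not computed ring-centroid-wise,
because the criteria are stated per atom pair. Distances are reported to
0.01 Å; comparisons against the bounds are exact floating-point with ≤ on
both ends.

A pair satisfying several conditions (e.g. donor/positive meeting
acceptor/negative at 2.5 Å) produces parallel edges, one per satisfied
type. The alternative — a priority order collapsing each pair to one
edge — would destroy information the mining stage can use, and no
defensible priority order exists. Mining handles the resulting multigraphs
natively (below). No covalent-bond exclusion is applied: covalently bound
ligands will produce short-distance edges, a documented limitation.
Water-mediated interactions, halogen bonds, cation–π and angular
hydrogen-bond criteria are out of scope.

Atoms with no interaction edge are dropped from the graph; a ligand whose
interface has no classified edge produces no graph at all (logged, not an
error). Every emitted graph is bipartite by construction and validated as
such.

## Featurization and clustering

Each graph becomes a binary vector over (property, path length, property)
keys: `ACC-2-HP` means some simple path of 2 edges joins an acceptor atom
to a hydrophobic atom. All simple (node-repetition-free) paths are
enumerated, not only shortest paths — a deliberate reading of
"every non-cyclic path": presence-style features make the extra lengths
harmless, and shortest-only enumeration would make the feature set
non-monotone under edge addition. Path length is capped at 10 edges by
default (configurable; recorded in the run metadata): interface graphs are
small, but simple-path enumeration is exponential in pathological cases
and the cap bounds the work. Endpoint type sets expand over their
Cartesian product, endpoint order is canonicalized, molecule role is *not*
part of the key, and features record presence, not counts.

The matrix is reduced by SVD; coordinates are the left singular vectors
scaled by singular values. The retained rank is the smallest capturing 90%
of squared singular-value mass, capped at min(n−1, 100) — an energy-based
default chosen because no single rank suits all dataset sizes. Each
component's sign is fixed so its largest-magnitude loading is positive;
without this convention the embedding (and hence seeded clustering) would
not be reproducible across BLAS implementations.

Three clustering algorithms are offered: k-medoids (PAM build+swap on
Euclidean distances in the embedding; the default), agglomerative (Ward on
Euclidean; deterministic), and spectral (RBF affinity with
median-distance bandwidth, symmetric normalized Laplacian, k smallest
eigenvectors row-normalized, then seeded k-means). Model quality uses
average silhouette width (default) or the Calinski–Harabasz index; the k
maximizing the metric over 2..min(15, n−1) wins, ties to the smaller k.
The k range is an explicit, documented default — large enough to cover
group counts seen in realistic interface datasets, small enough to keep
model selection cheap. Degenerate inputs are defined, not fatal: a
point's silhouette is 0 when max(a, b) = 0, singleton clusters contribute
0, and datasets with fewer distinct embedding rows than k receive a
deterministic round-robin labeling. Runs with fewer than 4 graphs skip
clustering and form a single group.

## Motif mining

Within each cluster, frequent connected labeled subgraphs are mined at
every support fraction of the sweep (default 0.1…1.0 step 0.1). The node
label for mining is the molecule role plus the sorted comma-joined type
set (`"L:acceptor,negative"`); label equality is exact — a motif node
typed acceptor+negative does not match a graph atom typed acceptor only.
Subset-compatible matching was considered and rejected: it would make
support counts depend on the direction of the subset relation and blur
what "the same arrangement" means. The minimum support count is
⌈fraction × n⌉ ("at least X% of the input graphs" is a lower bound);
motifs have at least one edge — single nodes are not motifs.

The miner is a gSpan-style canonical search: patterns are DFS codes grown
by rightmost extension, every candidate code is kept only if it is the
minimum DFS code of its pattern (is-min check), and support is counted as
the number of distinct graphs with at least one embedding, maintained via
embedding lists. Because parallel typed edges are first-class, the
extension rule is relaxed relative to simple-graph gSpan: a backward
extension from the rightmost vertex may target *any* rightmost-path vertex
— including its tree parent — provided an unused edge instance exists
between the mapped endpoints. The is-min check applies exactly the same
rule, so canonical completeness carries over to multigraphs; the test
suite verifies exact agreement with an exhaustive brute-force enumerator
(independent route: igraph VF2 on a vertex-colored edge-subdivision
encoding) over dozens of seeded random datasets.

Per (cluster, fraction) result set, only maximal motifs are kept: a motif
contained (by label-preserving subgraph isomorphism) in another retained
motif of the same run is dropped. Maximality is evaluated within one run,
not across fractions or clusters, because the results are presented
segmented that way. Each maximal motif is then mapped onto every input
graph with a VF2-style backtracking matcher. Embeddings are deduplicated
by node-map image: two assignments differing only in which of several
parallel graph edges realizes a motif edge are one embedding. A
per-(motif, graph) cap of 10 000 embeddings guards against pathological
symmetry, with a logged truncation warning. Ligand-atom statistics count
(embedding, motif edge) incidences per ligand atom name — the
motif-edge-incidence reading, chosen over "all graph edges touching the
atom" because the statistic describes the motif, not the whole graph —
plus the number of distinct graphs contributing.

## The synthetic-data generator, and what the tests do and do not show

`makeComplex()` emits PDB text from an explicit atom table, verifying any
intended pair distances to 0.001 Å; the protein side uses real
residue/atom names so the typing table applies unmodified, and the ligand
side exercises the rule-based perceiver (or the override path). The
geometry is deliberately *not* chemically realistic beyond the specified
distances — bond angles and torsions are whatever places atoms in the
requested windows. `makePlantedDataset()` generates labeled bipartite
graph collections in which exactly round(plantFraction × n) graphs carry a
label-exact copy of a chosen motif, plus seeded random noise edges over
fresh nodes.

Consequently, a passing suite shows that the machinery is correct —
parsing, typing rules, window classification, exact miner/matcher
behavior, determinism — on inputs whose ground truth is known by
construction. It does not show that the typing heuristics reproduce any
particular third-party pharmacophore assignment on real chemistry, nor
that motifs found in a real dataset are biologically meaningful; on real
data the typing override file is the escape hatch for the former, and
domain judgment remains responsible for the latter.

Test and acceptance problem sizes (graphs of ≤ 10 nodes, ≤ 6 graphs per
mined dataset, 50 oracle-comparison datasets, 20 planted-recovery seeds, a
6-complex end-to-end family) are chosen so the exhaustive oracles stay
exact and the whole suite runs in minutes on one CPU; the properties they
certify (canonicality, anti-monotonicity, maximality, determinism) are
size-independent.

## Known limitations

* Distance-only interaction criteria: no angular terms, so some
  "hydrogen bonds" are geometrically poor; mitigated by narrow windows.
* Ligand typing is heuristic; exotic chemistry (organometallics, unusual
  tautomers) needs the override file.
* Covalent ligands produce spurious short-distance edges.
* Simple-path featurization ignores edge types; two graphs with identical
  type-path structure but different interaction types featurize
  identically (they still separate at the mining stage).
* Mining cost grows with motif size and label homogeneity; the embedding
  cap and optional `maxEdges` bound the worst case.
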