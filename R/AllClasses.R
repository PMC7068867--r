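## S4 containers for the pipeline. Atom tables are plain data.frames with a
## fixed column contract (see .ATOM_COLS); the classes wrap them with
## validity checks and accessors.

.ATOM_COLS <- c("serial", "atomName", "element", "altLoc", "residueName",
                "residueNumber", "insertionCode", "chainId",
                "x", "y", "z", "occupancy", "recordKind")

#' StructureModel: one parsed structure (first model only)
#'
#' Holds the heavy-atom (after \code{\link{stripHydrogens}}) or all-atom
#' table of the first model of a PDB entry.
#'
#' @slot structureId PDB id or file stem.
#' @slot modelNumber model number retained (always the first model).
#' @slot atoms data.frame with one row per atom; columns
#'   \code{serial, atomName, element, altLoc, residueName, residueNumber,
#'   insertionCode, chainId, x, y, z, occupancy, recordKind}
#'   (\code{recordKind} is \code{"polymer"} for ATOM records and
#'   \code{"hetero"} for HETATM).
#' @export
setClass("StructureModel",
         representation(structureId = "character",
                        modelNumber = "integer",
                        atoms = "data.frame"),
         validity = function(object) {
           a <- object@atoms
           msg <- character()
           if (!all(.ATOM_COLS %in% colnames(a)))
             msg <- c(msg, paste("atoms must have columns:",
                                 paste(setdiff(.ATOM_COLS, colnames(a)),
                                       collapse = ", ")))
           else {
             if (nrow(a) && !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
               msg <- c(msg, "all coordinates must be finite")
             if (nrow(a) && any(!nzchar(a$element)))
               msg <- c(msg, "element must be non-empty after parsing")
             if (anyDuplicated(a$serial))
               msg <- c(msg, "atom serials must be unique within one model")
             if (nrow(a) && !all(a$recordKind %in% c("polymer", "hetero")))
               msg <- c(msg, "recordKind must be 'polymer' or 'hetero'")
           }
           if (length(object@modelNumber) != 1L)
             msg <- c(msg, "exactly one model is retained per structure")
           if (length(msg)) msg else TRUE
         })

#' LigandInstance: one hetero residue kept as a ligand
#'
#' Keyed by (het code, residue number, chain); heavy atoms only, at least 6
#' of them (smaller hetero groups are treated as experimental artifacts).
#'
#' @slot ligandName het code (never water).
#' @slot residueNumber residue sequence number.
#' @slot chainId chain identifier.
#' @slot atoms data.frame of heavy atoms (same columns as
#'   \code{StructureModel} atoms).
#' @export
setClass("LigandInstance",
         representation(ligandName = "character",
                        residueNumber = "integer",
                        chainId = "character",
                        atoms = "data.frame"),
         validity = function(object) {
           msg <- character()
           if (nrow(object@atoms) < 6L)
             msg <- c(msg, "a ligand must have at least 6 heavy atoms")
           if (toupper(object@ligandName) %in% c("HOH", "DOD", "WAT"))
             msg <- c(msg, "water is never a ligand")
           if (any(object@atoms$element %in% c("H", "D")))
             msg <- c(msg, "ligand atoms must be heavy atoms")
           if (length(msg)) msg else TRUE
         })

#' PLIGraph: a labeled bipartite protein-ligand interface graph
#'
#' One graph per (structure chain, ligand instance) interface: protein-side
#' nodes P, ligand-side nodes L and typed interaction edges E, every edge
#' joining P to L. Nodes carry provenance (residue, chain, atom name, serial)
#' and a physicochemical type set; edges carry the interaction type and the
#' atom-atom distance in angstroms.
#'
#' @slot graphId unique graph identifier.
#' @slot structureId,chainId,ligandName,ligandResidueNumber provenance.
#' @slot nodes data.frame: \code{nodeId, role, residueName, residueNumber,
#'   chainId, atomName, serial, types} (types: sorted comma-joined).
#' @slot edges data.frame: \code{from, to, interaction, distance} with
#'   \code{from}/\code{to} referencing \code{nodeId}; parallel edges with
#'   distinct interaction types are allowed.
#' @export
setClass("PLIGraph",
         representation(graphId = "character",
                        structureId = "character",
                        chainId = "character",
                        ligandName = "character",
                        ligandResidueNumber = "integer",
                        nodes = "data.frame",
                        edges = "data.frame"),
         validity = function(object) {
           n <- object@nodes; e <- object@edges
           msg <- character()
           if (!all(c("nodeId", "role", "types") %in% colnames(n)))
             msg <- c(msg, "nodes need nodeId, role, types columns")
           if (!all(c("from", "to", "interaction", "distance") %in% colnames(e)))
             msg <- c(msg, "edges need from, to, interaction, distance columns")
           if (length(msg)) return(msg)
           if (nrow(e) < 1L)
             msg <- c(msg, "a PLIGraph must have at least one edge")
           role <- structure(n$role, names = as.character(n$nodeId))
           if (nrow(e)) {
             rf <- role[as.character(e$from)]; rt <- role[as.character(e$to)]
             if (any(is.na(rf)) || any(is.na(rt)))
               msg <- c(msg, "edge endpoints must reference node ids")
             else if (!all((rf == "protein" & rt == "ligand") |
                           (rf == "ligand" & rt == "protein")))
               msg <- c(msg, "every edge must join a protein node to a ligand node")
             if (!all(e$interaction %in% INTERACTION_TYPES))
               msg <- c(msg, "unknown interaction type on an edge")
           }
           touched <- unique(c(e$from, e$to))
           if (!all(n$nodeId %in% touched))
             msg <- c(msg, "isolated nodes are not allowed")
           if (length(msg)) msg else TRUE
         })

#' FeatureMatrix: binary graph-by-feature matrix
#'
#' Rows are graphs, columns are canonical (property, path length, property)
#' feature keys such as \code{"HP-4-HP"}; entries record presence.
#'
#' @slot matrix integer matrix with graph ids as rownames and feature codes
#'   as colnames.
#' @slot maxPathLength the path-length cap used during enumeration.
#' @export
setClass("FeatureMatrix",
         representation(matrix = "matrix", maxPathLength = "integer"),
         validity = function(object) {
           m <- object@matrix
           msg <- character()
           if (is.null(rownames(m)) || is.null(colnames(m)))
             msg <- c(msg, "matrix needs graph-id rownames and feature colnames")
           if (length(m) && !all(m %in% c(0L, 1L)))
             msg <- c(msg, "entries must be binary")
           if (length(msg)) msg else TRUE
         })

#' GraphEmbedding: SVD-reduced coordinates of the feature matrix
#'
#' @slot coordinates graphs x retained-components matrix (left singular
#'   vectors scaled by singular values).
#' @slot singularValues all singular values, non-increasing.
#' @slot retainedRank number of components kept.
#' @export
setClass("GraphEmbedding",
         representation(coordinates = "matrix",
                        singularValues = "numeric",
                        retainedRank = "integer"),
         validity = function(object) {
           msg <- character()
           if (is.unsorted(rev(object@singularValues), strictly = FALSE))
             msg <- c(msg, "singular values must be non-increasing")
           if (ncol(object@coordinates) != object@retainedRank)
             msg <- c(msg, "coordinate columns must equal retainedRank")
           if (length(msg)) msg else TRUE
         })

#' ClusterModel: a fitted clustering of the graph embedding
#'
#' @slot algorithm one of kmedoids, agglomerative, spectral.
#' @slot k number of groups.
#' @slot labels named integer vector (graph id -> 1-based group index).
#' @slot metric asw or calinski_harabasz.
#' @slot score the metric value of this model.
#' @slot seed RNG seed used for seed-sensitive algorithms.
#' @export
setClass("ClusterModel",
         representation(algorithm = "character", k = "integer",
                        labels = "integer", metric = "character",
                        score = "numeric", seed = "integer"),
         validity = function(object) {
           msg <- character()
           if (!object@algorithm %in% c("kmedoids", "agglomerative", "spectral"))
             msg <- c(msg, "unknown algorithm")
           if (!object@metric %in% c("asw", "calinski_harabasz"))
             msg <- c(msg, "unknown metric")
           if (is.null(names(object@labels)))
             msg <- c(msg, "labels must be named by graph id")
           if (length(object@labels) &&
               !setequal(unique(object@labels), seq_len(object@k)))
             msg <- c(msg, "group indices must be contiguous 1..k")
           if (object@metric == "asw" && is.finite(object@score) &&
               (object@score < -1 - 1e-12 || object@score > 1 + 1e-12))
             msg <- c(msg, "asw must lie in [-1, 1]")
           if (length(msg)) msg else TRUE
         })

#' Motif: a frequent connected labeled subgraph
#'
#' Node labels combine the molecule role and the canonical serialized type
#' set (e.g. \code{"L:acceptor,negative"}); edge labels are interaction
#' types. Support is the number of distinct input graphs containing at least
#' one embedding.
#'
#' @slot motifId identifier, unique within a mining run.
#' @slot nodes data.frame: \code{nodeId, label}.
#' @slot edges data.frame: \code{from, to, label}.
#' @slot supportCount number of supporting graphs.
#' @slot supportFraction the mining support threshold used.
#' @slot clusterId originating cluster (NA when mining ungrouped input).
#' @slot graphIds ids of the supporting graphs.
#' @export
setClass("Motif",
         representation(motifId = "character",
                        nodes = "data.frame", edges = "data.frame",
                        supportCount = "integer", supportFraction = "numeric",
                        clusterId = "integer", graphIds = "character"),
         validity = function(object) {
           msg <- character()
           if (nrow(object@edges) < 1L)
             msg <- c(msg, "a motif has at least one edge (two nodes)")
           if (object@supportCount != length(object@graphIds))
             msg <- c(msg, "supportCount must equal the number of graphIds")
           ## connectivity
           if (nrow(object@nodes) > 1L) {
             adj <- lapply(seq_len(nrow(object@nodes)), function(i) integer())
             names(adj) <- as.character(object@nodes$nodeId)
             for (i in seq_len(nrow(object@edges))) {
               f <- as.character(object@edges$from[i]); t <- as.character(object@edges$to[i])
               adj[[f]] <- c(adj[[f]], object@edges$to[i])
               adj[[t]] <- c(adj[[t]], object@edges$from[i])
             }
             seen <- object@nodes$nodeId[1]; frontier <- seen
             while (length(frontier)) {
               nxt <- setdiff(unique(unlist(adj[as.character(frontier)])), seen)
               seen <- c(seen, nxt); frontier <- nxt
             }
             if (length(seen) < nrow(object@nodes))
               msg <- c(msg, "motif must be connected")
           }
           if (length(msg)) msg else TRUE
         })

#' ResultsBundle: all artifacts of one pipeline run
#'
#' @slot graphs list of \code{PLIGraph}.
#' @slot features \code{FeatureMatrix}.
#' @slot clusters \code{ClusterModel}.
#' @slot motifs list of \code{Motif} (all clusters, all support fractions,
#'   maximal only).
#' @slot embeddings list of embedding records (one per motif/graph match).
#' @slot stats data.frame of per-motif ligand-atom interaction statistics.
#' @slot config the run configuration (echoed for reproducibility).
#' @slot log data.frame of per-complex drop reasons and notes.
#' @export
setClass("ResultsBundle",
         representation(graphs = "list", features = "ANY", clusters = "ANY",
                        motifs = "list", embeddings = "list",
                        stats = "data.frame", config = "list",
                        log = "data.frame"))

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel", object@structureId,
      sprintf("(model %d): %d atoms, chains: %s\n", object@modelNumber,
              nrow(object@atoms),
              paste(sort(unique(object@atoms$chainId)), collapse = " ")))
})

setMethod("show", "LigandInstance", function(object) {
  cat(sprintf("LigandInstance %s %d chain %s: %d heavy atoms\n",
              object@ligandName, object@residueNumber, object@chainId,
              nrow(object@atoms)))
})

setMethod("show", "PLIGraph", function(object) {
  cat(sprintf("PLIGraph %s [%s chain %s ~ %s %d]: |P|=%d |L|=%d |E|=%d\n",
              object@graphId, object@structureId, object@chainId,
              object@ligandName, object@ligandResidueNumber,
              sum(object@nodes$role == "protein"),
              sum(object@nodes$role == "ligand"), nrow(object@edges)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d graphs x %d features (path length <= %d)\n",
              nrow(object@matrix), ncol(object@matrix), object@maxPathLength))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %s, k=%d, %s=%.4f (seed %d)\n",
              object@algorithm, object@k, object@metric, object@score,
              object@seed))
})

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif %s: %d nodes / %d edges, support %d (fraction %.2f), cluster %s\n",
              object@motifId, nrow(object@nodes), nrow(object@edges),
              object@supportCount, object@supportFraction,
              ifelse(is.na(object@clusterId), "-", object@clusterId)))
})

setMethod("show", "ResultsBundle", function(object) {
  cat(sprintf("ResultsBundle: %d graphs, %d maximal motifs, %d embeddings\n",
              length(object@graphs), length(object@motifs),
              length(object@embeddings)))
})

## ---- accessors ----

#' @describeIn StructureModel-class atom table accessor
#' @param object a \code{StructureModel} or \code{LigandInstance}
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @export
setMethod("atoms", "StructureModel", function(object) object@atoms)
#' @export
setMethod("atoms", "LigandInstance", function(object) object@atoms)

#' Node and edge tables of graph-like objects
#' @param object a \code{PLIGraph} or \code{Motif}
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))
#' @rdname graphNodes
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @export
setMethod("graphNodes", "PLIGraph", function(object) object@nodes)
#' @export
setMethod("graphEdges", "PLIGraph", function(object) object@edges)
#' @export
setMethod("graphNodes", "Motif", function(object) object@nodes)
#' @export
setMethod("graphEdges", "Motif", function(object) object@edges)

#' @rdname graphNodes
#' @export
setGeneric("graphId", function(object) standardGeneric("graphId"))
#' @export
setMethod("graphId", "PLIGraph", function(object) object@graphId)

#' Support accessors for motifs
#' @param object a \code{Motif}
#' @export
setGeneric("supportCount", function(object) standardGeneric("supportCount"))
#' @rdname supportCount
#' @export
setGeneric("supportFraction", function(object) standardGeneric("supportFraction"))
#' @export
setMethod("supportCount", "Motif", function(object) object@supportCount)
#' @export
setMethod("supportFraction", "Motif", function(object) object@supportFraction)

#' Cluster labels accessor
#' @param object a \code{ClusterModel}
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @export
setMethod("clusterLabels", "ClusterModel", function(object) object@labels)
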