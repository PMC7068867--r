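## fixtures: synthetic inputs with known ground truth - PDB-format
## micro-complexes realizing chosen interactions, labeled bipartite graph
## collections with planted frequent subgraphs, and brute-force oracles
## (exhaustive FSM and embedding enumeration) used to validate the miner
## and the matcher.

#' Build a PDB-format micro-complex from an atom specification
#'
#' Protein-role atoms become ATOM records of the given residues; ligand
#' atoms become HETATM records of one hetero residue. Coordinates are taken
#' verbatim, so the pipeline's graph builder yields exactly the contact
#' geometry the caller designed. Intended pair distances, when given, are
#' verified against the realized geometry to 0.001 A.
#'
#' @param atomSpec data.frame with columns residueName, residueNumber,
#'   atomName, role ("protein"/"ligand"), element, x, y, z.
#' @param ligandName het code for the ligand residue (default "LIG").
#' @param ligandResidueNumber residue number of the ligand (default 900).
#' @param chainId chain for all atoms (default "A").
#' @param intended optional data.frame (i, j, distance) of atom-row pairs
#'   whose realized Euclidean distance must match to 0.001 A.
#' @return character vector of PDB lines.
#' @export
makeComplex <- function(atomSpec, ligandName = "LIG",
                        ligandResidueNumber = 900L, chainId = "A",
                        intended = NULL) {
  stopifnot(all(c("residueName", "atomName", "role", "element",
                  "x", "y", "z") %in% colnames(atomSpec)),
            all(atomSpec$role %in% c("protein", "ligand")))
  if (sum(atomSpec$role == "ligand") < 6L)
    stop("the ligand part must have at least 6 atoms")
  if (!is.null(intended)) {
    for (r in seq_len(nrow(intended))) {
      i <- intended$i[r]; j <- intended$j[r]
      d <- sqrt(sum((atomSpec[i, c("x", "y", "z")] -
                     atomSpec[j, c("x", "y", "z")])^2))
      if (abs(d - intended$distance[r]) > 0.001)
        stop(sprintf("unsatisfied distance target: atoms %d-%d at %.3f, wanted %.3f",
                     i, j, d, intended$distance[r]))
    }
  }
  lines <- character(nrow(atomSpec))
  for (i in seq_len(nrow(atomSpec))) {
    isLig <- atomSpec$role[i] == "ligand"
    resName <- if (isLig) ligandName else atomSpec$residueName[i]
    resNo <- if (isLig) ligandResidueNumber else atomSpec$residueNumber[i]
    nm <- atomSpec$atomName[i]
    name4 <- if (nchar(nm) < 4 && nchar(atomSpec$element[i]) == 1)
      sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    lines[i] <- sprintf(
      "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (isLig) "HETATM" else "ATOM", i, name4, resName, chainId, resNo,
      atomSpec$x[i], atomSpec$y[i], atomSpec$z[i], 1, 0, atomSpec$element[i])
  }
  c(lines, "END")
}

#' Generate a labeled bipartite graph dataset with a planted motif
#'
#' Exactly \code{round(plantFraction * nGraphs)} graphs (chosen with the
#' seed) receive a label-exact copy of the motif; every graph additionally
#' receives \code{noiseEdges} random bipartite edges over fresh nodes with
#' labels drawn from the alphabet. Generation is deterministic under the
#' seed.
#'
#' @param motif labeled graph list (\code{nodeLabels}, \code{edges}) whose
#'   node labels carry the "P:"/"L:" role prefix.
#' @param nGraphs number of graphs.
#' @param plantFraction fraction of graphs receiving the motif, in (0, 1].
#' @param noiseEdges random extra edges per graph.
#' @param labelAlphabet list with \code{node} (character, "P:"/"L:"
#'   prefixed) and \code{edge} (character) label pools.
#' @param seed RNG seed.
#' @return list of labeled graphs; attribute \code{"planted"} is the
#'   logical vector of graphs that received a copy.
#' @export
makePlantedDataset <- function(motif, nGraphs, plantFraction = 0.7,
                               noiseEdges = 2L,
                               labelAlphabet = list(
                                 node = c("P:hydrophobic", "P:acceptor",
                                          "L:hydrophobic", "L:donor,positive"),
                                 edge = c("hydrophobic", "hydrogen_bond")),
                               seed = 1L) {
  stopifnot(plantFraction > 0, plantFraction <= 1)
  pNode <- labelAlphabet$node[startsWith(labelAlphabet$node, "P:")]
  lNode <- labelAlphabet$node[startsWith(labelAlphabet$node, "L:")]
  stopifnot(length(pNode) > 0, length(lNode) > 0)
  set.seed(seed)
  nPlant <- round(plantFraction * nGraphs)
  plantedIn <- sort(sample(nGraphs, nPlant))
  out <- vector("list", nGraphs)
  for (i in seq_len(nGraphs)) {
    nodeLabels <- character(); edges <- NULL
    if (i %in% plantedIn) {
      nodeLabels <- motif$nodeLabels
      edges <- motif$edges
    }
    nNoise <- max(noiseEdges, if (i %in% plantedIn) 0L else 1L)
    for (k in seq_len(nNoise)) {
      pl <- sample(pNode, 1); ll <- sample(lNode, 1)
      nodeLabels <- c(nodeLabels, pl, ll)
      np <- length(nodeLabels)
      e <- data.frame(from = np - 1L, to = np,
                      label = sample(labelAlphabet$edge, 1),
                      stringsAsFactors = FALSE)
      edges <- if (is.null(edges)) e else rbind(edges, e)
    }
    out[[i]] <- list(graphId = sprintf("synth%03d", i),
                     nodeLabels = nodeLabels, edges = edges)
  }
  attr(out, "planted") <- seq_len(nGraphs) %in% plantedIn
  out
}

## ---- independent isomorphism via igraph (vertex-colored encoding) ----

## Encode a labeled multigraph as a simple vertex-colored igraph: original
## nodes colored by node label, each labeled edge subdivided through a
## fresh node colored by its edge label.
.igraphEncode <- function(lg, nodePool, edgePool) {
  n <- length(lg$nodeLabels)
  m <- nrow(lg$edges)
  colors <- c(match(lg$nodeLabels, nodePool),
              length(nodePool) + match(lg$edges$label, edgePool))
  ends <- integer(0)
  for (e in seq_len(m)) ends <- c(ends, lg$edges$from[e], n + e,
                                  n + e, lg$edges$to[e])
  g <- igraph::make_empty_graph(n + m, directed = FALSE)
  if (m) g <- igraph::add_edges(g, ends)
  igraph::V(g)$color <- colors
  g
}

#' Test two labeled graphs for isomorphism (independent route)
#'
#' Encodes edge labels as colored subdivision nodes and defers to igraph's
#' VF2 graph-isomorphism; used by the brute-force mining oracle, keeping
#' it independent of the DFS-code canonicalization of the miner.
#'
#' @param g1,g2 labeled graph lists.
#' @return logical.
#' @export
labeledGraphIsomorphic <- function(g1, g2) {
  if (length(g1$nodeLabels) != length(g2$nodeLabels) ||
      nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  nodePool <- sort(unique(c(g1$nodeLabels, g2$nodeLabels)), method = "radix")
  edgePool <- sort(unique(c(g1$edges$label, g2$edges$label)), method = "radix")
  igraph::isomorphic(.igraphEncode(g1, nodePool, edgePool),
                     .igraphEncode(g2, nodePool, edgePool), method = "vf2")
}

## connected subgraphs of one graph with <= maxNodes nodes, as edge sets
.connectedEdgeSubsets <- function(lg, maxNodes) {
  m <- nrow(lg$edges)
  if (!m) return(list())
  seen <- new.env(parent = emptyenv())
  out <- list()
  expand <- function(edgeSet, nodeSet) {
    key <- paste(sort(edgeSet), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <<- edgeSet
    for (e in seq_len(m)) {
      if (e %in% edgeSet) next
      f <- lg$edges$from[e]; t <- lg$edges$to[e]
      if (!(f %in% nodeSet) && !(t %in% nodeSet)) next
      newNodes <- union(nodeSet, c(f, t))
      if (length(newNodes) > maxNodes) next
      expand(c(edgeSet, e), newNodes)
    }
    invisible()
  }
  for (e in seq_len(m))
    expand(e, unique(c(lg$edges$from[e], lg$edges$to[e])))
  out
}

.subgraphFromEdges <- function(lg, edgeSet) {
  nodes <- sort(unique(c(lg$edges$from[edgeSet], lg$edges$to[edgeSet])))
  list(graphId = lg$graphId,
       nodeLabels = lg$nodeLabels[nodes],
       edges = data.frame(from = match(lg$edges$from[edgeSet], nodes),
                          to = match(lg$edges$to[edgeSet], nodes),
                          label = lg$edges$label[edgeSet],
                          stringsAsFactors = FALSE))
}

.lgFingerprint <- function(lg) {
  paste(length(lg$nodeLabels), nrow(lg$edges),
        paste(sort(lg$nodeLabels, method = "radix"), collapse = "|"),
        paste(sort(paste(pmin(lg$nodeLabels[lg$edges$from],
                              lg$nodeLabels[lg$edges$to]),
                         lg$edges$label,
                         pmax(lg$nodeLabels[lg$edges$from],
                              lg$nodeLabels[lg$edges$to])),
                   method = "radix"), collapse = "|"),
        sep = "##")
}

#' Brute-force frequent connected subgraph enumeration (oracle)
#'
#' Exhaustively expands connected edge subsets of every graph, groups them
#' into isomorphism classes (igraph VF2 on a vertex-colored encoding) and
#' counts per-class graph support. Intended for tests on small inputs only.
#'
#' @param graphs list of labeled graphs (or \code{PLIGraph}s), each with
#'   at most 10 nodes.
#' @param minSupportCount minimum number of supporting graphs.
#' @param maxNodes subgraph size guard, at most 6.
#' @return list of \code{list(graph = representative labeled graph,
#'   support = integer)}.
#' @export
bruteForceFSM <- function(graphs, minSupportCount, maxNodes = 6L) {
  lgraphs <- lapply(graphs, .asLGraph)
  if (any(vapply(lgraphs, function(g) length(g$nodeLabels), 0L) > 10L))
    stop("brute-force FSM refuses graphs with more than 10 nodes")
  if (maxNodes > 6L) stop("brute-force FSM refuses maxNodes > 6")
  classes <- list()   # list of list(rep, fp, graphs = integer set)
  for (gi in seq_along(lgraphs)) {
    lg <- lgraphs[[gi]]
    subs <- lapply(.connectedEdgeSubsets(lg, maxNodes),
                   function(es) .subgraphFromEdges(lg, es))
    seenHere <- integer()
    for (s in subs) {
      fp <- .lgFingerprint(s)
      hit <- 0L
      for (ci in seq_along(classes)) {
        if (classes[[ci]]$fp != fp) next
        if (labeledGraphIsomorphic(classes[[ci]]$rep, s)) { hit <- ci; break }
      }
      if (!hit) {
        classes[[length(classes) + 1L]] <- list(rep = s, fp = fp,
                                                graphs = integer())
        hit <- length(classes)
      }
      if (!gi %in% classes[[hit]]$graphs)
        classes[[hit]]$graphs <- c(classes[[hit]]$graphs, gi)
    }
  }
  out <- list()
  for (cl in classes) {
    if (length(cl$graphs) < minSupportCount) next
    out[[length(out) + 1L]] <- list(graph = cl$rep,
                                    support = length(cl$graphs))
  }
  out
}

#' Brute-force embedding enumeration (oracle)
#'
#' Enumerates every injective assignment of pattern nodes to same-labeled
#' graph nodes and keeps those under which every pattern edge has enough
#' same-labeled graph edge instances between the mapped endpoints. Node
#' maps only, mirroring the matcher's deduplication.
#'
#' @param pattern labeled graph or \code{Motif}.
#' @param graph labeled graph or \code{PLIGraph} with at most 10 nodes.
#' @return list of integer node maps (pattern node -> graph node).
#' @export
bruteForceEmbeddings <- function(pattern, graph) {
  p <- if (is(pattern, "Motif")) .motifAsLGraph(pattern) else .asLGraph(pattern)
  t <- .asLGraph(graph)
  if (length(t$nodeLabels) > 10L)
    stop("brute-force embedding enumeration refuses graphs with more than 10 nodes")
  np <- length(p$nodeLabels)
  cand <- lapply(seq_len(np), function(u)
    which(t$nodeLabels == p$nodeLabels[u]))
  if (any(lengths(cand) == 0)) return(list())
  tCounts <- .pairLabelCounts(t$edges)
  pKey <- paste(pmin(p$edges$from, p$edges$to),
                pmax(p$edges$from, p$edges$to), p$edges$label, sep = "|")
  pCounts <- table(pKey)
  maps <- list()
  recurse <- function(pos, assign_) {
    if (pos > np) {
      ## full check of every pattern pair requirement
      for (k in names(pCounts)) {
        parts <- strsplit(k, "|", fixed = TRUE)[[1]]
        u <- as.integer(parts[1]); v <- as.integer(parts[2])
        tk <- paste(min(assign_[u], assign_[v]),
                    max(assign_[u], assign_[v]), parts[3], sep = "|")
        have <- tCounts[tk]
        if (is.na(have) || have < pCounts[k]) return(invisible())
      }
      maps[[length(maps) + 1L]] <<- assign_
      return(invisible())
    }
    for (c_ in cand[[pos]]) {
      if (c_ %in% assign_[seq_len(pos - 1L)]) next
      recurse(pos + 1L, c(assign_[seq_len(pos - 1L)], c_, integer(np - pos)))
    }
    invisible()
  }
  recurse(1L, integer(np))
  maps
}
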