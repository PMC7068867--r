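## motif_mining (part 2): mapping motifs back onto input graphs with a
## VF2-style backtracking subgraph-isomorphism matcher (label-preserving,
## injective on nodes, multigraph-aware), maximality filtering, and
## per-motif ligand-atom interaction statistics.

.motifAsLGraph <- function(motif) {
  list(graphId = motif@motifId,
       nodeLabels = motif@nodes$label[order(motif@nodes$nodeId)],
       edges = data.frame(from = match(motif@edges$from, motif@nodes$nodeId),
                          to = match(motif@edges$to, motif@nodes$nodeId),
                          label = motif@edges$label, stringsAsFactors = FALSE))
}

## per-pair edge-label count table: env key "u|v|label" -> count
.pairLabelCounts <- function(edges) {
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
               edges$label, sep = "|")
  table(key)
}

## VF2-style enumeration of label-preserving injective node maps of
## `pattern` into `target` (both .asLGraph lists). Distinct node maps only:
## parallel-edge assignment multiplicity never multiplies the count, the
## feasibility test just requires enough same-labeled edge instances.
.matchNodeMaps <- function(pattern, target, maxMaps = 10000L) {
  np <- length(pattern$nodeLabels)
  pe <- pattern$edges; te <- target$edges
  tCount <- .pairLabelCounts(te)
  ## connected search order starting at node 1's component (pattern is
  ## connected for motifs)
  adj <- vector("list", np)
  for (r in seq_len(nrow(pe))) {
    adj[[pe$from[r]]] <- union(adj[[pe$from[r]]], pe$to[r])
    adj[[pe$to[r]]] <- union(adj[[pe$to[r]]], pe$from[r])
  }
  order_ <- 1L
  while (length(order_) < np) {
    nxt <- setdiff(unique(unlist(adj[order_])), order_)
    if (!length(nxt)) break   # disconnected pattern: remaining appended
    order_ <- c(order_, nxt[1])
  }
  if (length(order_) < np) order_ <- c(order_, setdiff(seq_len(np), order_))

  ## pattern pair requirements grouped by the later-ordered endpoint
  pKey <- paste(pmin(pe$from, pe$to), pmax(pe$from, pe$to), pe$label, sep = "|")
  pCount <- table(pKey)

  maps <- list()
  truncated <- FALSE
  assign_ <- integer(np)
  nt <- length(target$nodeLabels)
  recurse <- function(pos) {
    if (truncated) return(invisible())
    if (pos > np) {
      if (length(maps) >= maxMaps) { truncated <<- TRUE; return(invisible()) }
      maps[[length(maps) + 1L]] <<- assign_
      return(invisible())
    }
    u <- order_[pos]
    placed <- order_[seq_len(pos - 1L)]
    for (cand in seq_len(nt)) {
      if (target$nodeLabels[cand] != pattern$nodeLabels[u]) next
      if (cand %in% assign_[placed]) next
      ok <- TRUE
      for (v in intersect(adj[[u]], placed)) {
        for (lab in unique(pe$label[(pe$from == u & pe$to == v) |
                                    (pe$from == v & pe$to == u)])) {
          pk <- paste(min(u, v), max(u, v), lab, sep = "|")
          tk <- paste(min(cand, assign_[v]), max(cand, assign_[v]), lab,
                      sep = "|")
          need <- pCount[pk]
          have <- tCount[tk]
          if (is.na(have) || have < need) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      assign_[u] <<- cand
      recurse(pos + 1L)
      assign_[u] <<- 0L
    }
    invisible()
  }
  recurse(1L)
  attr(maps, "truncated") <- truncated
  maps
}

#' Map a motif onto an input graph
#'
#' Enumerates all label-preserving subgraph-isomorphism embeddings of the
#' motif in the graph (VF2-style backtracking), deduplicated by the image
#' of the node map. Each embedding also carries one consistent edge
#' assignment (motif edge to a distinct graph edge of the same label).
#'
#' @param motif a \code{\linkS4class{Motif}}.
#' @param graph a \code{PLIGraph} or labeled graph.
#' @param maxEmbeddings guard against pathological symmetry (default
#'   10000; exceeding it truncates with a warning).
#' @return list of embeddings, each a list with \code{motifId},
#'   \code{graphId}, \code{nodeMap} (motif nodeId -> graph node index) and
#'   \code{edgeMap} (data.frame motifEdge, graphEdge).
#' @export
mapEmbeddings <- function(motif, graph, maxEmbeddings = 10000L) {
  pattern <- .motifAsLGraph(motif)
  lg <- .asLGraph(graph)
  maps <- .matchNodeMaps(pattern, lg, maxEmbeddings)
  if (isTRUE(attr(maps, "truncated")))
    warning("embedding enumeration truncated at ", maxEmbeddings,
            " for motif ", motif@motifId, " in graph ", lg$graphId)
  pe <- pattern$edges
  lapply(maps, function(m) {
    ## greedy distinct-edge assignment (guaranteed by the count check)
    usedEdges <- integer()
    gEdge <- integer(nrow(pe))
    for (r in seq_len(nrow(pe))) {
      iu <- m[pe$from[r]]; iv <- m[pe$to[r]]
      cand <- which(((lg$edges$from == iu & lg$edges$to == iv) |
                     (lg$edges$from == iv & lg$edges$to == iu)) &
                    lg$edges$label == pe$label[r])
      cand <- setdiff(cand, usedEdges)
      gEdge[r] <- cand[1]
      usedEdges <- c(usedEdges, cand[1])
    }
    nodeMap <- structure(m, names = as.character(motif@nodes$nodeId))
    list(motifId = motif@motifId, graphId = lg$graphId, nodeMap = nodeMap,
         edgeMap = data.frame(motifEdge = seq_len(nrow(pe)),
                              graphEdge = gEdge))
  })
}

#' Does one labeled graph contain another as a subgraph?
#'
#' @param small,big \code{Motif}, \code{PLIGraph} or labeled-graph lists.
#' @return TRUE when a label-preserving embedding of \code{small} in
#'   \code{big} exists.
#' @export
containsSubgraph <- function(small, big) {
  p <- if (is(small, "Motif")) .motifAsLGraph(small) else .asLGraph(small)
  t <- if (is(big, "Motif")) .motifAsLGraph(big) else .asLGraph(big)
  if (length(p$nodeLabels) > length(t$nodeLabels) ||
      nrow(p$edges) > nrow(t$edges)) return(FALSE)
  length(.matchNodeMaps(p, t, maxMaps = 1L)) > 0
}

#' Keep only maximal motifs of one mining run
#'
#' A motif is dropped when it is subgraph-isomorphic to another motif of
#' the same (cluster, support fraction) result set. Canonical mining
#' guarantees no two motifs of a run are isomorphic, so containment is
#' unambiguous.
#'
#' @param motifs list of \code{Motif} from one mining run.
#' @return the maximal subset, original order preserved.
#' @export
filterMaximal <- function(motifs) {
  if (length(motifs) <= 1L) return(motifs)
  nEdges <- vapply(motifs, function(m) nrow(m@edges), 0L)
  keep <- rep(TRUE, length(motifs))
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      if (i == j || nEdges[j] < nEdges[i]) next
      if (nEdges[j] == nEdges[i] && j > i) next  # equal size: never contained
      if (nEdges[j] == nEdges[i]) next
      if (containsSubgraph(motifs[[i]], motifs[[j]])) { keep[i] <- FALSE; break }
    }
  }
  motifs[keep]
}

#' Ligand-atom interaction statistics of a motif
#'
#' For every ligand atom name appearing in the images of the motif's
#' ligand nodes: \code{interactionCount} is the number of (embedding,
#' motif edge) incidences on that atom and \code{graphCount} the number of
#' distinct graphs contributing at least one incidence.
#'
#' @param motif a \code{Motif}.
#' @param embeddings list of embeddings of this motif (over any graphs),
#'   as from \code{\link{mapEmbeddings}}.
#' @param graphs list of the \code{PLIGraph}s referenced by the
#'   embeddings.
#' @return data.frame: motifId, ligandAtomName, interactionCount,
#'   graphCount, sorted by decreasing interactionCount.
#' @export
ligandAtomStats <- function(motif, embeddings, graphs) {
  gIds <- vapply(graphs, graphId, character(1))
  ligNodeIds <- motif@nodes$nodeId[startsWith(motif@nodes$label, "L:")]
  rows <- list()
  for (emb in embeddings) {
    stopifnot(emb$motifId == motif@motifId)
    g <- graphs[[match(emb$graphId, gIds)]]
    gn <- graphNodes(g)
    for (r in seq_len(nrow(motif@edges))) {
      for (end in c(motif@edges$from[r], motif@edges$to[r])) {
        if (!end %in% ligNodeIds) next
        nodeIdx <- emb$nodeMap[[as.character(end)]]
        rows[[length(rows) + 1L]] <- data.frame(
          atom = gn$atomName[nodeIdx], graph = emb$graphId,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(motifId = character(), ligandAtomName = character(),
                      interactionCount = integer(), graphCount = integer()))
  d <- do.call(rbind, rows)
  atoms <- sort(unique(d$atom), method = "radix")
  out <- data.frame(
    motifId = motif@motifId, ligandAtomName = atoms,
    interactionCount = vapply(atoms, function(a) sum(d$atom == a), 0L),
    graphCount = vapply(atoms, function(a)
      length(unique(d$graph[d$atom == a])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$interactionCount, out$ligandAtomName, method = "radix"), ,
      drop = FALSE]
}
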