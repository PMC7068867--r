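## motif_mining (part 1): frequent connected labeled subgraph mining with a
## gSpan-style canonical DFS-code search: rightmost extension, support
## pruning by the anti-monotone graph count, and is-min canonicality checks
## so every pattern is reported exactly once. Parallel typed edges are
## first-class: backward extensions may revisit any rightmost-path vertex
## through an unused edge instance, and the minimality check applies the
## same rule, preserving canonical completeness on multigraphs.

#' Convert a PLIGraph to a plain labeled graph for mining
#'
#' Node labels combine the molecule role prefix ("P:"/"L:") with the
#' sorted, comma-joined type set (e.g. \code{"L:acceptor,negative"}); edge
#' labels are the interaction types.
#'
#' @param pliGraph a \code{\linkS4class{PLIGraph}}.
#' @return list with \code{graphId}, \code{nodeLabels} (character vector
#'   indexed by node), and \code{edges} (data.frame from, to, label).
#' @export
asLabeledGraph <- function(pliGraph) {
  n <- graphNodes(pliGraph); e <- graphEdges(pliGraph)
  idx <- match(c(e$from, e$to), n$nodeId)
  labels <- paste0(ifelse(n$role == "protein", "P:", "L:"), n$types)
  list(graphId = graphId(pliGraph),
       nodeLabels = labels,
       edges = data.frame(from = idx[seq_len(nrow(e))],
                          to = idx[nrow(e) + seq_len(nrow(e))],
                          label = e$interaction, stringsAsFactors = FALSE))
}

.asLGraph <- function(g) {
  if (is(g, "PLIGraph")) asLabeledGraph(g) else g
}

## ---- DFS-code machinery (integer-encoded labels) ----

## tuple: c(i, j, li, le, lj); forward j > i, backward j < i
.cmpTuple <- function(a, b) {
  afwd <- a[2] > a[1]; bfwd <- b[2] > b[1]
  if (afwd && bfwd) {
    if (a[2] != b[2]) return(if (a[2] < b[2]) -1L else 1L)
    if (a[1] != b[1]) return(if (a[1] > b[1]) -1L else 1L)
  } else if (!afwd && !bfwd) {
    if (a[1] != b[1]) return(if (a[1] < b[1]) -1L else 1L)
    if (a[2] != b[2]) return(if (a[2] < b[2]) -1L else 1L)
  } else if (!afwd && bfwd) {
    return(if (a[1] < b[2]) -1L else 1L)
  } else {
    return(if (a[2] <= b[1]) -1L else 1L)
  }
  for (k in 3:5) if (a[k] != b[k]) return(if (a[k] < b[k]) -1L else 1L)
  0L
}

.rightmostPath <- function(code) {
  ## code: matrix rows (i, j, li, le, lj); forward rows define the DFS tree
  maxv <- max(code[, 1:2])
  parent <- integer(maxv)
  fwd <- code[, 2] > code[, 1]
  parent[code[fwd, 2]] <- code[fwd, 1]
  path <- maxv
  while (path[1] != 1L) path <- c(parent[path[1]], path)
  path
}

.codeToGraph <- function(code) {
  maxv <- max(code[, 1:2])
  nodeLabels <- integer(maxv)
  for (r in seq_len(nrow(code))) {
    nodeLabels[code[r, 1]] <- code[r, 3]
    nodeLabels[code[r, 2]] <- code[r, 5]
  }
  list(nodeLabels = nodeLabels,
       edges = cbind(from = code[, 1], to = code[, 2], label = code[, 4]))
}

## incidence structure for fast extension lookup
.incidence <- function(nNodes, edges) {
  inc <- vector("list", nNodes)
  for (e in seq_len(nrow(edges))) {
    f <- edges[e, 1]; t <- edges[e, 2]
    inc[[f]] <- c(inc[[f]], e)
    inc[[t]] <- c(inc[[t]], e)
  }
  inc
}

## All rightmost extensions of one embedding within its graph.
## emb: list(nodes = dfs-index -> graph node, edges = used edge ids)
## gdat: list(nodeLabels, edges (matrix from,to,label), inc)
.extensions <- function(code, emb, gdat) {
  rmp <- .rightmostPath(code)
  rmv <- rmp[length(rmp)]
  nv <- rmv + 1L
  out <- list()
  ## backward: from rightmost vertex to earlier rightmost-path vertices
  for (v in rmp[-length(rmp)]) {
    gn <- emb$nodes[rmv]; gv <- emb$nodes[v]
    for (e in gdat$inc[[gn]]) {
      if (e %in% emb$edges) next
      f <- gdat$edges[e, 1]; t <- gdat$edges[e, 2]
      other <- if (f == gn) t else f
      if (other != gv) next
      tup <- c(rmv, v, gdat$nodeLabels[gn], gdat$edges[e, 3],
               gdat$nodeLabels[gv])
      out[[length(out) + 1L]] <- list(tuple = tup,
                                      nodes = emb$nodes,
                                      edges = c(emb$edges, e))
    }
  }
  ## forward: from any rightmost-path vertex to an unmapped node
  for (u in rev(rmp)) {
    gu <- emb$nodes[u]
    for (e in gdat$inc[[gu]]) {
      if (e %in% emb$edges) next
      f <- gdat$edges[e, 1]; t <- gdat$edges[e, 2]
      other <- if (f == gu) t else f
      if (other %in% emb$nodes) next
      tup <- c(u, nv, gdat$nodeLabels[gu], gdat$edges[e, 3],
               gdat$nodeLabels[other])
      out[[length(out) + 1L]] <- list(tuple = tup,
                                      nodes = c(emb$nodes, other),
                                      edges = c(emb$edges, e))
    }
  }
  out
}

## Is `code` the minimal DFS code of the pattern it spells?
.isMinCode <- function(code) {
  p <- .codeToGraph(code)
  pdat <- list(nodeLabels = p$nodeLabels, edges = p$edges,
               inc = .incidence(length(p$nodeLabels), p$edges))
  ## step 1: minimal first tuple over all oriented edges
  best <- NULL; embs <- list()
  for (e in seq_len(nrow(p$edges))) {
    for (o in 1:2) {
      u <- p$edges[e, if (o == 1) 1 else 2]; v <- p$edges[e, if (o == 1) 2 else 1]
      tup <- c(1L, 2L, p$nodeLabels[u], p$edges[e, 3], p$nodeLabels[v])
      cmp <- if (is.null(best)) -1L else .cmpTuple(tup, best)
      if (cmp < 0) { best <- tup; embs <- list(list(nodes = c(u, v), edges = e)) }
      else if (cmp == 0) embs[[length(embs) + 1L]] <- list(nodes = c(u, v), edges = e)
    }
  }
  if (.cmpTuple(best, code[1, ]) != 0) return(FALSE)
  minCode <- matrix(best, nrow = 1)
  for (r in seq_len(nrow(code))[-1]) {
    best <- NULL; nextEmbs <- list()
    for (emb in embs) {
      for (ext in .extensions(minCode, emb, pdat)) {
        cmp <- if (is.null(best)) -1L else .cmpTuple(ext$tuple, best)
        if (cmp < 0) { best <- ext$tuple; nextEmbs <- list(ext) }
        else if (cmp == 0) nextEmbs[[length(nextEmbs) + 1L]] <- ext
      }
    }
    if (is.null(best) || .cmpTuple(best, code[r, ]) != 0) return(FALSE)
    minCode <- rbind(minCode, best)
    embs <- lapply(nextEmbs, function(x) list(nodes = x$nodes, edges = x$edges))
  }
  TRUE
}

## ---- the miner ----

.encodeDataset <- function(lgraphs) {
  nodeLabs <- sort(unique(unlist(lapply(lgraphs, `[[`, "nodeLabels"))),
                   method = "radix")
  edgeLabs <- sort(unique(unlist(lapply(lgraphs, function(g) g$edges$label))),
                   method = "radix")
  gdats <- lapply(lgraphs, function(g) {
    edges <- cbind(from = as.integer(g$edges$from),
                   to = as.integer(g$edges$to),
                   label = match(g$edges$label, edgeLabs))
    list(nodeLabels = match(g$nodeLabels, nodeLabs), edges = edges,
         inc = .incidence(length(g$nodeLabels), edges))
  })
  list(gdats = gdats, nodeLabs = nodeLabs, edgeLabs = edgeLabs,
       graphIds = vapply(lgraphs, `[[`, "", "graphId"))
}

.codeToMotif <- function(code, enc, supportGraphs, fraction, clusterId,
                         motifId) {
  p <- .codeToGraph(code)
  nodes <- data.frame(nodeId = seq_along(p$nodeLabels),
                      label = enc$nodeLabs[p$nodeLabels],
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = p$edges[, 1], to = p$edges[, 2],
                      label = enc$edgeLabs[p$edges[, 3]],
                      stringsAsFactors = FALSE)
  new("Motif", motifId = motifId, nodes = nodes, edges = edges,
      supportCount = length(supportGraphs),
      supportFraction = fraction,
      clusterId = as.integer(clusterId),
      graphIds = enc$graphIds[supportGraphs])
}

#' Mine frequent connected labeled subgraphs (gSpan)
#'
#' Finds every connected subgraph with at least one edge whose support -
#' the number of distinct input graphs containing it - reaches
#' \code{ceiling(minSupportFraction * n_graphs)}. The search grows
#' canonical DFS codes by rightmost extension with is-min pruning, so each
#' pattern is reported exactly once.
#'
#' @param graphs list of \code{PLIGraph} or labeled graphs (see
#'   \code{\link{asLabeledGraph}}).
#' @param minSupportFraction support threshold in (0, 1].
#' @param maxEdges optional cap on motif size in edges (default unlimited).
#' @param clusterId originating cluster recorded on the motifs (NA when
#'   mining ungrouped input).
#' @return list of \code{\linkS4class{Motif}}, sorted by (edge count,
#'   canonical code).
#' @export
mineFrequentSubgraphs <- function(graphs, minSupportFraction,
                                  maxEdges = Inf, clusterId = NA_integer_) {
  stopifnot(length(graphs) >= 1,
            minSupportFraction > 0, minSupportFraction <= 1)
  lgraphs <- lapply(graphs, .asLGraph)
  enc <- .encodeDataset(lgraphs)
  n <- length(lgraphs)
  minCount <- as.integer(ceiling(minSupportFraction * n))
  results <- list()

  ## embeddings per pattern: list of (g = graph index, nodes, edges)
  recurse <- function(code, embs) {
    gset <- sort(unique(vapply(embs, `[[`, 0L, "g")))
    key <- paste(t(code), collapse = ",")
    results[[length(results) + 1L]] <<- list(code = code, graphs = gset)
    if (nrow(code) >= maxEdges) return(invisible())
    ## group extensions by tuple
    extMap <- new.env(parent = emptyenv())
    for (emb in embs) {
      gdat <- enc$gdats[[emb$g]]
      for (ext in .extensions(code, list(nodes = emb$nodes, edges = emb$edges),
                              gdat)) {
        k <- paste(ext$tuple, collapse = ",")
        lst <- if (is.null(extMap[[k]])) list() else extMap[[k]]
        lst[[length(lst) + 1L]] <- list(g = emb$g, nodes = ext$nodes,
                                        edges = ext$edges)
        extMap[[k]] <- lst
      }
    }
    for (k in ls(extMap)) {
      newEmbs <- extMap[[k]]
      support <- length(unique(vapply(newEmbs, `[[`, 0L, "g")))
      if (support < minCount) next
      tup <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
      newCode <- rbind(code, tup, deparse.level = 0)
      if (!.isMinCode(newCode)) next
      recurse(newCode, newEmbs)
    }
    invisible()
  }

  ## frequent single-edge seeds (minimal orientation li <= lj)
  seedMap <- new.env(parent = emptyenv())
  for (gi in seq_len(n)) {
    gdat <- enc$gdats[[gi]]
    for (e in seq_len(nrow(gdat$edges))) {
      u <- gdat$edges[e, 1]; v <- gdat$edges[e, 2]
      lu <- gdat$nodeLabels[u]; lv <- gdat$nodeLabels[v]
      orients <- if (lu < lv) list(c(u, v)) else if (lv < lu) list(c(v, u)) else
        list(c(u, v), c(v, u))
      for (o in orients) {
        tup <- c(1L, 2L, gdat$nodeLabels[o[1]], gdat$edges[e, 3],
                 gdat$nodeLabels[o[2]])
        k <- paste(tup, collapse = ",")
        lst <- if (is.null(seedMap[[k]])) list() else seedMap[[k]]
        lst[[length(lst) + 1L]] <- list(g = gi, nodes = o, edges = e)
        seedMap[[k]] <- lst
      }
    }
  }
  for (k in ls(seedMap)) {
    embs <- seedMap[[k]]
    support <- length(unique(vapply(embs, `[[`, 0L, "g")))
    if (support < minCount) next
    tup <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    recurse(matrix(tup, nrow = 1), embs)
  }

  ## deterministic ordering and ids
  ord <- order(vapply(results, function(r) nrow(r$code), 0L),
               vapply(results, function(r) paste(sprintf("%06d", t(r$code)),
                                                 collapse = ","), ""))
  results <- results[ord]
  cid <- if (is.na(clusterId)) "x" else as.character(clusterId)
  lapply(seq_along(results), function(i)
    .codeToMotif(results[[i]]$code, enc, results[[i]]$graphs,
                 minSupportFraction, clusterId,
                 sprintf("c%s_s%02d_m%03d", cid,
                         round(minSupportFraction * 100), i)))
}

#' Mine over a sweep of support fractions
#'
#' Runs \code{\link{mineFrequentSubgraphs}} once per fraction (default 0.1
#' to 1.0 in steps of 0.1). As the fraction grows, the number of frequent
#' subgraphs and their maximum size are non-increasing.
#'
#' @inheritParams mineFrequentSubgraphs
#' @param fractions numeric vector of support fractions in (0, 1].
#' @return named list (fraction -> list of \code{Motif}).
#' @export
supportSweep <- function(graphs, fractions = seq(0.1, 1.0, by = 0.1),
                         maxEdges = Inf, clusterId = NA_integer_) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  out <- lapply(fractions, function(f)
    mineFrequentSubgraphs(graphs, f, maxEdges, clusterId))
  names(out) <- formatC(fractions, format = "f", digits = 1)
  out
}
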