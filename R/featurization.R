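## featurization: (property, path length, property) presence features over
## all simple paths of an interface graph, and the dataset matrix.

.featureCode <- function(typeA, len, typeB) {
  ca <- TYPE_CODES[typeA]; cb <- TYPE_CODES[typeB]
  swap <- ca > cb
  a <- ifelse(swap, cb, ca); b <- ifelse(swap, ca, cb)
  paste0(a, "-", len, "-", b)
}

.asSimpleIgraph <- function(pliGraph) {
  n <- graphNodes(pliGraph); e <- graphEdges(pliGraph)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(n$nodeId), types = n$types))
  igraph::simplify(g)
}

#' Enumerate path features of one interface graph
#'
#' For every simple (node-repetition-free) path of 1..\code{maxLength}
#' edges between any two nodes, and every pair of endpoint properties, the
#' canonical feature \code{"<PROP>-<len>-<PROP>"} is emitted (endpoint
#' order never matters; parallel edges contribute the same node sequences).
#' Property codes: ACC, ARO, DON, HP, NEG, POS.
#'
#' @param pliGraph a \code{\linkS4class{PLIGraph}}.
#' @param maxLength path-length cap in edges (default 10).
#' @return sorted character vector of feature codes.
#' @export
enumeratePathFeatures <- function(pliGraph, maxLength = 10L) {
  stopifnot(maxLength >= 1L)
  n <- graphNodes(pliGraph)
  g <- .asSimpleIgraph(pliGraph)
  nodeTypes <- structure(lapply(n$types, .splitTypes),
                         names = as.character(n$nodeId))
  pairLens <- new.env(parent = emptyenv())
  for (v in igraph::V(g)) {
    vn <- igraph::V(g)$name[v]
    paths <- igraph::all_simple_paths(g, from = v, cutoff = maxLength)
    for (p in paths) {
      len <- length(p) - 1L
      if (len < 1L) next
      endn <- igraph::V(g)$name[p[length(p)]]
      a <- if (vn < endn) vn else endn
      b <- if (vn < endn) endn else vn
      assign(paste(a, b, len, sep = "\r"), TRUE, envir = pairLens)
    }
  }
  feats <- character()
  for (k in ls(pairLens)) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    ta <- nodeTypes[[parts[1]]]; tb <- nodeTypes[[parts[2]]]
    len <- as.integer(parts[3])
    if (!length(ta) || !length(tb)) next
    for (p in ta) for (q in tb)
      feats <- c(feats, .featureCode(p, len, q))
  }
  sort(unique(feats), method = "radix")
}

.sortFeatureCodes <- function(codes) {
  parts <- strsplit(codes, "-", fixed = TRUE)
  pa <- vapply(parts, `[`, "", 1)
  len <- as.integer(vapply(parts, `[`, "", 2))
  pb <- vapply(parts, `[`, "", 3)
  codes[order(pa, len, pb, method = "radix")]
}

#' Assemble the binary graph-by-feature matrix
#'
#' Rows follow the input graph order; columns are the union of feature
#' keys over the dataset, sorted canonically by (first property, length,
#' second property).
#'
#' @param graphs list of \code{PLIGraph} (at least 2).
#' @param maxLength path-length cap passed to
#'   \code{\link{enumeratePathFeatures}}.
#' @return a \code{\linkS4class{FeatureMatrix}}.
#' @export
assembleFeatureMatrix <- function(graphs, maxLength = 10L) {
  if (length(graphs) < 2L)
    stop("assembleFeatureMatrix needs at least 2 graphs")
  featSets <- lapply(graphs, enumeratePathFeatures, maxLength = maxLength)
  cols <- .sortFeatureCodes(unique(unlist(featSets)))
  ids <- vapply(graphs, graphId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate graph ids in dataset")
  m <- matrix(0L, nrow = length(graphs), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(featSets))
    m[i, match(featSets[[i]], cols)] <- 1L
  new("FeatureMatrix", matrix = m, maxPathLength = as.integer(maxLength))
}
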