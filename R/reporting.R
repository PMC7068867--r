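## reporting_cli: pipeline orchestration from a run configuration and the
## analytic tables behind the web views (dataset details, graph-patterns
## heatmap data, atom/interaction histograms), persisted as GraphML, JSON
## and CSV. Outputs carry no timestamps so a rerun with the same config and
## seed is byte-identical.

.xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub('"', "&quot;", s, fixed = TRUE)
  s
}

#' Serialize a PLIGraph (or Motif) to GraphML
#'
#' Node attributes: role, residueName, residueNumber, chain, atomName,
#' types (or label for motifs); edge attributes: interaction and distance
#' (label only for motifs).
#'
#' @param x a \code{PLIGraph} or \code{Motif}.
#' @return character vector of GraphML lines.
#' @export
toGraphML <- function(x) {
  head_ <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  if (is(x, "PLIGraph")) {
    n <- graphNodes(x); e <- graphEdges(x)
    keys <- c('<key id="role" for="node" attr.name="role" attr.type="string"/>',
              '<key id="residueName" for="node" attr.name="residueName" attr.type="string"/>',
              '<key id="residueNumber" for="node" attr.name="residueNumber" attr.type="int"/>',
              '<key id="chain" for="node" attr.name="chain" attr.type="string"/>',
              '<key id="atomName" for="node" attr.name="atomName" attr.type="string"/>',
              '<key id="types" for="node" attr.name="types" attr.type="string"/>',
              '<key id="interaction" for="edge" attr.name="interaction" attr.type="string"/>',
              '<key id="distance" for="edge" attr.name="distance" attr.type="double"/>')
    nodes <- vapply(seq_len(nrow(n)), function(i) paste0(
      '<node id="n', n$nodeId[i], '">',
      '<data key="role">', n$role[i], '</data>',
      '<data key="residueName">', .xmlEscape(n$residueName[i]), '</data>',
      '<data key="residueNumber">', n$residueNumber[i], '</data>',
      '<data key="chain">', .xmlEscape(n$chainId[i]), '</data>',
      '<data key="atomName">', .xmlEscape(n$atomName[i]), '</data>',
      '<data key="types">', .xmlEscape(n$types[i]), '</data>',
      '</node>'), character(1))
    edges <- vapply(seq_len(nrow(e)), function(i) paste0(
      '<edge source="n', e$from[i], '" target="n', e$to[i], '">',
      '<data key="interaction">', e$interaction[i], '</data>',
      '<data key="distance">', formatC(e$distance[i], format = "f", digits = 2),
      '</data></edge>'), character(1))
    gid <- graphId(x)
  } else {
    n <- graphNodes(x); e <- graphEdges(x)
    keys <- c('<key id="label" for="node" attr.name="label" attr.type="string"/>',
              '<key id="elabel" for="edge" attr.name="label" attr.type="string"/>')
    nodes <- vapply(seq_len(nrow(n)), function(i) paste0(
      '<node id="n', n$nodeId[i], '"><data key="label">',
      .xmlEscape(n$label[i]), '</data></node>'), character(1))
    edges <- vapply(seq_len(nrow(e)), function(i) paste0(
      '<edge source="n', e$from[i], '" target="n', e$to[i],
      '"><data key="elabel">', e$label[i], '</data></edge>'), character(1))
    gid <- x@motifId
  }
  c(head_, keys,
    paste0('<graph id="', .xmlEscape(gid), '" edgedefault="undirected">'),
    nodes, edges, '</graph>', '</graphml>')
}

.pliGraphToList <- function(g) {
  list(graphId = graphId(g), structureId = g@structureId,
       chainId = g@chainId, ligandName = g@ligandName,
       ligandResidueNumber = g@ligandResidueNumber,
       nodes = graphNodes(g), edges = graphEdges(g))
}

#' Run the full pipeline from a configuration
#'
#' Executes structure reading, typing, graph building, featurization,
#' clustering and per-cluster motif mining with maximal filtering and
#' embedding mapping. Structures that fail to parse, chains without
#' ligands, artifact-only ligands and contact-free interfaces are skipped
#' with a logged reason; the run aborts only when no graph survives.
#'
#' @param config list with elements: \code{inputs} - data.frame(path,
#'   chain); \code{criteria} (default \code{\link{defaultCriteria}});
#'   \code{overrides} optional ligand typing table; \code{algorithm},
#'   \code{metric}, \code{kRange}, \code{seed} for clustering;
#'   \code{supportFractions} (default 0.1..1.0); \code{maxPathLength}
#'   (default 10); \code{maxEdges} mining cap (default Inf);
#'   \code{outputDir} optional directory to persist all artifacts.
#' @return a \code{\linkS4class{ResultsBundle}}.
#' @export
runProject <- function(config) {
  cfg <- config
  cfg$criteria <- if (is.null(cfg$criteria)) defaultCriteria() else cfg$criteria
  cfg$algorithm <- if (is.null(cfg$algorithm)) "kmedoids" else cfg$algorithm
  cfg$metric <- if (is.null(cfg$metric)) "asw" else cfg$metric
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$supportFractions <- if (is.null(cfg$supportFractions))
    seq(0.1, 1.0, by = 0.1) else cfg$supportFractions
  cfg$maxPathLength <- if (is.null(cfg$maxPathLength)) 10L else cfg$maxPathLength
  cfg$maxEdges <- if (is.null(cfg$maxEdges)) Inf else cfg$maxEdges

  logRows <- list()
  note <- function(source, stage, reason)
    logRows[[length(logRows) + 1L]] <<- data.frame(
      source = source, stage = stage, reason = reason,
      stringsAsFactors = FALSE)

  graphs <- list()
  for (r in seq_len(nrow(cfg$inputs))) {
    path <- cfg$inputs$path[r]; chain <- cfg$inputs$chain[r]
    src <- paste0(basename(path), ":", chain)
    model <- tryCatch(
      stripHydrogens(parsePDB(readLines(path),
                              tools::file_path_sans_ext(basename(path)))),
      error = function(e) { note(src, "parse", conditionMessage(e)); NULL })
    if (is.null(model)) next
    ligs <- tryCatch(extractLigands(model, chain),
                     error = function(e) { note(src, "ligands", conditionMessage(e)); NULL })
    if (is.null(ligs)) next
    if (!length(ligs)) { note(src, "ligands", "no ligand after artifact filter"); next }
    for (lig in ligs) {
      g <- buildPLIGraph(model, chain, lig, overrides = cfg$overrides,
                         criteria = cfg$criteria)
      if (is.null(g))
        note(src, "graph", paste0("no classified contact for ",
                                  lig@ligandName, lig@residueNumber))
      else graphs[[length(graphs) + 1L]] <- g
    }
  }
  if (!length(graphs)) stop("no interface graph survived; aborting run")

  features <- NULL; clusters <- NULL
  n <- length(graphs)
  if (n >= 4L) {
    features <- assembleFeatureMatrix(graphs, cfg$maxPathLength)
    embedding <- svdReduce(features)
    kRange <- if (is.null(cfg$kRange)) seq(2L, min(15L, n - 1L)) else
      cfg$kRange[cfg$kRange >= 2L & cfg$kRange <= n - 1L]
    clusters <- selectClusterModel(embedding, cfg$algorithm, cfg$metric,
                                   kRange, cfg$seed)
    labels <- clusterLabels(clusters)
  } else {
    note("dataset", "clustering",
         sprintf("only %d graph(s): single group, clustering skipped", n))
    labels <- structure(rep(1L, n),
                        names = vapply(graphs, graphId, character(1)))
  }

  motifs <- list()
  for (cid in sort(unique(labels))) {
    members <- graphs[labels[vapply(graphs, graphId, character(1))] == cid]
    sweep_ <- supportSweep(members, cfg$supportFractions, cfg$maxEdges, cid)
    for (f in names(sweep_)) {
      maximal <- filterMaximal(sweep_[[f]])
      motifs <- c(motifs, maximal)
    }
  }

  embeddings <- list()
  for (m in motifs) {
    for (g in graphs) {
      embeddings <- c(embeddings, mapEmbeddings(m, g))
    }
  }

  statsRows <- list()
  gIds <- vapply(graphs, graphId, character(1))
  for (m in motifs) {
    embs <- Filter(function(e) e$motifId == m@motifId, embeddings)
    s <- ligandAtomStats(m, embs, graphs)
    if (nrow(s)) statsRows[[length(statsRows) + 1L]] <- s
  }
  stats <- if (length(statsRows)) do.call(rbind, statsRows) else
    data.frame(motifId = character(), ligandAtomName = character(),
               interactionCount = integer(), graphCount = integer())
  rownames(stats) <- NULL

  log_ <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(source = character(), stage = character(),
               reason = character())
  cfg$labels <- labels
  bundle <- new("ResultsBundle", graphs = graphs, features = features,
                clusters = clusters, motifs = motifs,
                embeddings = embeddings, stats = stats, config = cfg,
                log = log_)
  if (!is.null(cfg$outputDir)) writeResults(bundle, cfg$outputDir)
  bundle
}

#' Persist every artifact of a run
#'
#' Writes per-graph GraphML and a JSON mirror, the feature matrix CSV, the
#' cluster report CSV, per-motif GraphML plus a JSON motif index,
#' embeddings JSON, ligand-atom stats CSV, the patterns and histogram
#' tables, the drop log and \code{run_metadata.json}. No timestamps:
#' reruns with identical config and seed are byte-identical.
#'
#' @param bundle a \code{ResultsBundle}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeResults <- function(bundle, dir) {
  dir.create(file.path(dir, "graphs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motifs"), showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (g in bundle@graphs) {
    writeLines(toGraphML(g), file.path(dir, "graphs",
                                       paste0(graphId(g), ".graphml")))
  }
  wj(lapply(bundle@graphs, .pliGraphToList), "graphs.json")
  if (!is.null(bundle@features))
    write.csv(bundle@features@matrix,
              file.path(dir, "feature_matrix.csv"))
  labels <- bundle@config$labels
  clusterReport <- data.frame(
    graphId = vapply(bundle@graphs, graphId, character(1)),
    structureId = vapply(bundle@graphs, function(g) g@structureId, ""),
    chain = vapply(bundle@graphs, function(g) g@chainId, ""),
    ligand = vapply(bundle@graphs, function(g) g@ligandName, ""),
    group = unname(labels[vapply(bundle@graphs, graphId, character(1))]))
  write.csv(clusterReport, file.path(dir, "clusters.csv"), row.names = FALSE)
  for (m in bundle@motifs)
    writeLines(toGraphML(m), file.path(dir, "motifs",
                                       paste0(m@motifId, ".graphml")))
  wj(lapply(bundle@motifs, function(m) list(
    motifId = m@motifId, cluster = m@clusterId,
    supportFraction = m@supportFraction, supportCount = m@supportCount,
    size = nrow(m@nodes), graphIds = m@graphIds)), "motif_index.json")
  wj(lapply(bundle@embeddings, function(e) list(
    motifId = e$motifId, graphId = e$graphId,
    nodeMap = as.list(e$nodeMap))), "embeddings.json")
  write.csv(bundle@stats, file.path(dir, "ligand_atom_stats.csv"),
            row.names = FALSE)
  write.csv(patternsTable(bundle), file.path(dir, "patterns_table.csv"),
            row.names = FALSE)
  write.csv(histograms(bundle, "interaction_type", "group"),
            file.path(dir, "interaction_histogram.csv"), row.names = FALSE)
  write.csv(histograms(bundle, "atom_type", "group"),
            file.path(dir, "atom_histogram.csv"), row.names = FALSE)
  write.csv(bundle@log, file.path(dir, "drop_log.csv"), row.names = FALSE)
  cfgEcho <- bundle@config
  cfgEcho$inputs <- as.list(as.data.frame(cfgEcho$inputs))
  cfgEcho$criteria <- as.list(as.data.frame(cfgEcho$criteria))
  cfgEcho$labels <- as.list(cfgEcho$labels)
  cfgEcho$overrides <- NULL
  cfgEcho$outputDir <- NULL   # a location, not a parameter of the run
  cfgEcho$maxEdges <- if (is.finite(cfgEcho$maxEdges)) cfgEcho$maxEdges else "Inf"
  meta <- list(package = "plimotif",
               version = as.character(utils::packageVersion("plimotif")),
               config = cfgEcho,
               nGraphs = length(bundle@graphs),
               nMotifs = length(bundle@motifs),
               clustering = if (!is.null(bundle@clusters)) list(
                 algorithm = bundle@clusters@algorithm,
                 k = bundle@clusters@k,
                 metric = bundle@clusters@metric,
                 score = bundle@clusters@score,
                 seed = bundle@clusters@seed) else NULL)
  wj(meta, "run_metadata.json")
  invisible(dir)
}

#' Graph-patterns summary table
#'
#' One row per (group, support fraction, motif size): how many maximal
#' motifs of that node count were found in that group at that support.
#'
#' @param bundle a \code{ResultsBundle}.
#' @return data.frame(group, supportFraction, motifSize, occurrences).
#' @export
patternsTable <- function(bundle) {
  if (!length(bundle@motifs))
    return(data.frame(group = integer(), supportFraction = numeric(),
                      motifSize = integer(), occurrences = integer()))
  d <- data.frame(
    group = vapply(bundle@motifs, function(m) m@clusterId, 0L),
    supportFraction = vapply(bundle@motifs, function(m) m@supportFraction, 0),
    motifSize = vapply(bundle@motifs, function(m) nrow(m@nodes), 0L))
  agg <- aggregate(list(occurrences = rep(1L, nrow(d))),
                   d[, c("group", "supportFraction", "motifSize")], sum)
  agg[order(agg$group, agg$supportFraction, agg$motifSize), , drop = FALSE]
}

#' Motif histograms by atom type or interaction type
#'
#' Counts motif node type incidences (every type of a node's set counts
#' once per node) or motif edge interaction types, grouped by cluster or
#' by support fraction.
#'
#' @param bundle a \code{ResultsBundle}.
#' @param facet "atom_type" or "interaction_type".
#' @param by "group" or "support".
#' @return data.frame(by, value, count).
#' @export
histograms <- function(bundle, facet = c("atom_type", "interaction_type"),
                       by = c("group", "support")) {
  facet <- match.arg(facet); by <- match.arg(by)
  rows <- list()
  for (m in bundle@motifs) {
    key <- if (by == "group") m@clusterId else m@supportFraction
    vals <- if (facet == "interaction_type") m@edges$label else
      unlist(lapply(m@nodes$label, function(l)
        .splitTypes(sub("^[PL]:", "", l))))
    for (v in vals)
      rows[[length(rows) + 1L]] <- data.frame(by = key, value = v,
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(by = numeric(), value = character(), count = integer()))
  d <- do.call(rbind, rows)
  agg <- aggregate(list(count = rep(1L, nrow(d))), d, sum)
  agg[order(agg$by, agg$value), , drop = FALSE]
}

#' Search graphs for a residue, ligand or atom
#'
#' Case-insensitive substring match on residue name + number (e.g.
#' "LEU83"), ligand name and atom name over all graph nodes.
#'
#' @param bundle a \code{ResultsBundle}.
#' @param query search string.
#' @return data.frame(graphId, nodeId, role, residueName, residueNumber,
#'   atomName).
#' @export
searchResidue <- function(bundle, query) {
  q <- toupper(query)
  rows <- list()
  for (g in bundle@graphs) {
    n <- graphNodes(g)
    hay <- toupper(paste0(n$residueName, n$residueNumber))
    hit <- grepl(q, hay, fixed = TRUE) |
      grepl(q, toupper(n$atomName), fixed = TRUE) |
      grepl(q, toupper(n$residueName), fixed = TRUE)
    if (any(hit)) {
      sub <- n[hit, c("nodeId", "role", "residueName", "residueNumber",
                      "atomName")]
      sub$graphId <- graphId(g)
      rows[[length(rows) + 1L]] <- sub
    }
  }
  if (!length(rows))
    return(data.frame(graphId = character(), nodeId = integer(),
                      role = character(), residueName = character(),
                      residueNumber = integer(), atomName = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("graphId", "nodeId", "role", "residueName", "residueNumber",
          "atomName")]
}
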