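## Shared fixture builders and small independent oracles for the test
## suite. Everything is generated in code; nothing is downloaded.

## -- labeled-graph helpers ------------------------------------------------

lgraph <- function(id, nodeLabels, from, to, label) {
  list(graphId = id, nodeLabels = nodeLabels,
       edges = data.frame(from = from, to = to, label = label,
                          stringsAsFactors = FALSE))
}

randomBipartiteLGraph <- function(id, nP = 3, nL = 3, nE = 6,
                                  pLabels = c("P:hydrophobic", "P:acceptor",
                                              "P:donor,positive"),
                                  lLabels = c("L:hydrophobic",
                                              "L:acceptor,negative",
                                              "L:aromatic,hydrophobic"),
                                  eLabels = c("hydrophobic", "hydrogen_bond",
                                              "repulsive", "salt_bridge")) {
  nodeLabels <- c(sample(pLabels, nP, TRUE), sample(lLabels, nL, TRUE))
  edges <- unique(data.frame(from = sample(seq_len(nP), nE, TRUE),
                             to = nP + sample(seq_len(nL), nE, TRUE),
                             label = sample(eLabels, nE, TRUE),
                             stringsAsFactors = FALSE))
  list(graphId = id, nodeLabels = nodeLabels, edges = edges)
}

motifAsLG <- function(m) plimotif:::.motifAsLGraph(m)

## a minimal Motif object from a labeled graph
asMotif <- function(lg, id = "m", support = 1L, fraction = 1.0) {
  new("Motif", motifId = id,
      nodes = data.frame(nodeId = seq_along(lg$nodeLabels),
                         label = lg$nodeLabels, stringsAsFactors = FALSE),
      edges = data.frame(from = lg$edges$from, to = lg$edges$to,
                         label = lg$edges$label, stringsAsFactors = FALSE),
      supportCount = support, supportFraction = fraction,
      clusterId = NA_integer_,
      graphIds = paste0("g", seq_len(support)))
}

## -- PLIGraph builders (no structure parsing involved) --------------------

pathPLIGraph <- function(id, types,
                         interaction = rep("hydrophobic", length(types) - 1)) {
  n <- length(types)
  nodes <- data.frame(nodeId = seq_len(n),
                      role = rep(c("protein", "ligand"), length.out = n),
                      residueName = "GLY", residueNumber = seq_len(n),
                      chainId = "A", atomName = paste0("X", seq_len(n)),
                      serial = seq_len(n), types = types,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = seq_len(n - 1), to = seq_len(n - 1) + 1L,
                      interaction = interaction, distance = 3.0,
                      stringsAsFactors = FALSE)
  new("PLIGraph", graphId = id, structureId = id, chainId = "A",
      ligandName = "LIG", ligandResidueNumber = 1L,
      nodes = nodes, edges = edges)
}

## -- micro-complex PDB fixtures -------------------------------------------

## A hydrophobic-family complex: LEU side-chain carbons facing a bonded
## carbon pair of the ligand, plus a far-away carbon pad to reach 6 ligand
## atoms. `shift` jitters positions without leaving the distance windows.
hydrophobicComplexSpec <- function(shift = 0) {
  data.frame(
    residueName = c("LEU", "LEU", "PHE", rep("LIG", 6)),
    residueNumber = c(83, 83, 82, rep(900, 6)),
    atomName = c("CB", "CD1", "CZ", "C1", "C2", "C3", "C4", "C5", "C6"),
    role = c(rep("protein", 3), rep("ligand", 6)),
    element = c("C", "C", "C", rep("C", 6)),
    x = c(0, 1.5, 3.0, 0, 1.5, 3.0 + shift, 20, 21.5, 23),
    y = c(0, 0, 0, 3.0 + shift, 3.0, 3.0, 0, 0, 0),
    z = 0, stringsAsFactors = FALSE)
}

## A polar-family complex: LYS NZ donor/positive and ASP carboxylate facing
## a phosphate-like ligand group (terminal O on P: acceptor+negative).
polarComplexSpec <- function(shift = 0) {
  data.frame(
    residueName = c("LYS", "ASP", "ASP", rep("LIG", 7)),
    residueNumber = c(33, 86, 86, rep(900, 7)),
    atomName = c("NZ", "OD1", "OD2", "P1", "O1G", "O2G", "O3G",
                 "C1", "C2", "C3"),
    role = c(rep("protein", 3), rep("ligand", 7)),
    element = c("N", "O", "O", "P", "O", "O", "O", "C", "C", "C"),
    x = c(0, 5.0, 5.0 + shift, 1.0, 0, 2.5, 1.0, 20, 21.5, 23),
    y = c(0, 1.0, -1.0, 3.0, 3.5, 3.5, 4.5, 0, 0, 0),
    z = c(0, 0, 0, 0.5, 0, 0, 1.5, 0, 0, 0), stringsAsFactors = FALSE)
}

fixturePDB <- function(kind = c("hydrophobic", "polar"), shift = 0,
                       ligandName = "LIG") {
  kind <- match.arg(kind)
  spec <- if (kind == "hydrophobic") hydrophobicComplexSpec(shift) else
    polarComplexSpec(shift)
  makeComplex(spec, ligandName = ligandName)
}

## write a set of fixture complexes to a directory; returns config inputs
writeFixtureFamily <- function(dir, nPerFamily = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(); kinds <- c("hydrophobic", "polar")
  shifts <- c(0, 0.1, -0.1, 0.05, -0.05)[seq_len(nPerFamily)]
  for (k in kinds) for (i in seq_len(nPerFamily)) {
    p <- file.path(dir, sprintf("%s%d.pdb", substr(k, 1, 2), i))
    writeLines(fixturePDB(k, shifts[i]), p)
    paths <- c(paths, p)
  }
  data.frame(path = paths, chain = "A", stringsAsFactors = FALSE)
}

## -- independent simple-path oracle (recursive DFS) ------------------------

## all simple-path lengths between every node pair of a PLIGraph,
## independent of igraph
oracleSimplePathFeatures <- function(pliGraph, maxLength = 10L) {
  n <- graphNodes(pliGraph); e <- graphEdges(pliGraph)
  ids <- n$nodeId
  adj <- lapply(ids, function(v)
    unique(c(e$to[e$from == v], e$from[e$to == v])))
  names(adj) <- as.character(ids)
  pairs <- new.env(parent = emptyenv())
  walk <- function(path) {
    last <- path[length(path)]
    len <- length(path) - 1L
    if (len >= 1L) {
      a <- min(path[1], last); b <- max(path[1], last)
      assign(paste(a, b, len, sep = "_"), TRUE, envir = pairs)
    }
    if (len >= maxLength) return(invisible())
    for (nb in adj[[as.character(last)]])
      if (!nb %in% path) walk(c(path, nb))
    invisible()
  }
  for (v in ids) walk(v)
  typeOf <- structure(lapply(n$types, plimotif:::.splitTypes),
                      names = as.character(ids))
  feats <- character()
  for (k in ls(pairs)) {
    p <- strsplit(k, "_", fixed = TRUE)[[1]]
    ta <- typeOf[[p[1]]]; tb <- typeOf[[p[2]]]
    for (x in ta) for (y in tb)
      feats <- c(feats, plimotif:::.featureCode(x, as.integer(p[3]), y))
  }
  sort(unique(feats), method = "radix")
}

## hand-written interaction truth table used by the classification grid
oracleClassify <- function(typesI, typesJ, d) {
  out <- character()
  if ("aromatic" %in% typesI && "aromatic" %in% typesJ &&
      d >= 1.5 && d <= 3.5) out <- c(out, "aromatic_stacking")
  if ((("acceptor" %in% typesI) && ("donor" %in% typesJ) ||
       ("donor" %in% typesI) && ("acceptor" %in% typesJ)) &&
      d >= 2.0 && d <= 3.0) out <- c(out, "hydrogen_bond")
  if ("hydrophobic" %in% typesI && "hydrophobic" %in% typesJ &&
      d >= 2.0 && d <= 3.8) out <- c(out, "hydrophobic")
  if ((("negative" %in% typesI) && ("negative" %in% typesJ) ||
       ("positive" %in% typesI) && ("positive" %in% typesJ)) &&
      d >= 2.0 && d <= 6.0) out <- c(out, "repulsive")
  if ((("negative" %in% typesI) && ("positive" %in% typesJ) ||
       ("positive" %in% typesI) && ("negative" %in% typesJ)) &&
      d >= 2.0 && d <= 6.0) out <- c(out, "salt_bridge")
  out
}
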