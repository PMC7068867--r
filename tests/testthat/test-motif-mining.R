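test_that("two identical single-edge graphs yield that motif at full support", {
  g <- lgraph("g1", c("P:hydrophobic", "L:hydrophobic"), 1, 2, "hydrophobic")
  g2 <- g; g2$graphId <- "g2"
  motifs <- mineFrequentSubgraphs(list(g, g2), 1.0)
  expect_length(motifs, 1L)
  expect_equal(supportCount(motifs[[1]]), 2L)
  expect_setequal(motifs[[1]]@graphIds, c("g1", "g2"))
  expect_equal(nrow(graphEdges(motifs[[1]])), 1L)
})

test_that("support is anti-monotone under extension for every mined motif", {
  set.seed(31)
  gs <- lapply(1:5, function(i) randomBipartiteLGraph(paste0("g", i), 3, 3, 7))
  motifs <- mineFrequentSubgraphs(gs, 0.4)
  ## for every pair (m, m2) with m a subgraph of m2: support(m2) <= support(m)
  for (i in seq_along(motifs)) for (j in seq_along(motifs)) {
    if (i == j) next
    if (nrow(motifs[[i]]@edges) < nrow(motifs[[j]]@edges) &&
        containsSubgraph(motifs[[i]], motifs[[j]]))
      expect_lte(supportCount(motifs[[j]]), supportCount(motifs[[i]]))
  }
  expect_gt(length(motifs), 0)
})

test_that("no two motifs of one run are isomorphic (canonicality)", {
  set.seed(37)
  gs <- lapply(1:4, function(i) randomBipartiteLGraph(paste0("g", i), 3, 3, 6))
  motifs <- mineFrequentSubgraphs(gs, 0.5)
  lgs <- lapply(motifs, motifAsLG)
  for (i in seq_along(lgs)) for (j in seq_along(lgs))
    if (i < j) expect_false(labeledGraphIsomorphic(lgs[[i]], lgs[[j]]))
})

test_that("mining handles parallel typed edges between one atom pair", {
  mk <- function(id) lgraph(id, c("P:donor,positive", "L:acceptor,negative"),
                            c(1, 1), c(2, 2),
                            c("hydrogen_bond", "salt_bridge"))
  motifs <- mineFrequentSubgraphs(list(mk("a"), mk("b")), 1.0)
  sizes <- vapply(motifs, function(m) nrow(m@edges), 0L)
  expect_setequal(sizes, c(1L, 1L, 2L))     # each single edge + the pair
  both <- motifs[[which(sizes == 2L)]]
  expect_setequal(both@edges$label, c("hydrogen_bond", "salt_bridge"))
  expect_equal(supportCount(both), 2L)
})

test_that("gSpan equals the brute-force enumerator over random datasets", {
  set.seed(41)
  for (rep_ in 1:10) {
    gs <- lapply(seq_len(sample(3:6, 1)), function(i)
      randomBipartiteLGraph(paste0("g", i), sample(2:4, 1), sample(2:4, 1),
                            sample(3:8, 1)))
    minCount <- sample(2:3, 1)
    mined <- Filter(function(m) nrow(m@nodes) <= 6,
                    mineFrequentSubgraphs(gs, minCount / length(gs)))
    oracle <- bruteForceFSM(gs, minCount, maxNodes = 6)
    expect_equal(length(mined), length(oracle))
    for (b in oracle) {
      hit <- FALSE
      for (m in mined)
        if (labeledGraphIsomorphic(b$graph, motifAsLG(m))) {
          expect_equal(supportCount(m), b$support); hit <- TRUE; break
        }
      expect_true(hit)
    }
  }
})

test_that("the support sweep shrinks motif count and maximum size", {
  set.seed(43)
  planted <- lgraph("pl", c("P:hydrophobic", "L:hydrophobic",
                            "P:acceptor", "L:donor,positive"),
                    c(1, 3, 3), c(2, 2, 4),
                    c("hydrophobic", "hydrogen_bond", "hydrogen_bond"))
  gs <- makePlantedDataset(planted, nGraphs = 8, plantFraction = 0.75,
                           noiseEdges = 2, seed = 17)
  sweep_ <- supportSweep(gs, seq(0.1, 1.0, by = 0.1))
  counts <- vapply(sweep_, length, 0L)
  expect_true(all(diff(counts) <= 0))
  maxSize <- vapply(sweep_, function(ms)
    if (length(ms)) max(vapply(ms, function(m) nrow(m@nodes), 0L)) else 0L, 0L)
  expect_true(all(diff(maxSize[maxSize > 0]) <= 0))
  ## fraction 1.0 keeps only patterns present in every graph
  for (m in sweep_[["1.0"]]) expect_equal(supportCount(m), length(gs))
})

test_that("maximal filtering retains exactly the non-contained motifs", {
  ab <- lgraph("ab", c("P:a", "L:b"), 1, 2, "x")
  abc <- lgraph("abc", c("P:a", "L:b", "P:c"), c(1, 3), c(2, 2), c("x", "y"))
  m1 <- asMotif(ab, "m1"); m2 <- asMotif(abc, "m2")
  kept <- filterMaximal(list(m1, m2))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]@motifId, "m2")
  ## incomparable motifs are both kept
  other <- asMotif(lgraph("o", c("P:z", "L:b"), 1, 2, "x"), "m3")
  expect_length(filterMaximal(list(m1, other)), 2L)
  ## agreement with a pairwise brute-force maximality check on mined sets
  set.seed(47)
  gs <- lapply(1:4, function(i) randomBipartiteLGraph(paste0("g", i), 3, 3, 6))
  motifs <- mineFrequentSubgraphs(gs, 0.5)
  kept2 <- filterMaximal(motifs)
  ids <- vapply(kept2, function(m) m@motifId, "")
  for (i in seq_along(motifs)) {
    contained <- any(vapply(seq_along(motifs), function(j)
      j != i && nrow(motifs[[j]]@edges) > nrow(motifs[[i]]@edges) &&
        length(bruteForceEmbeddings(motifAsLG(motifs[[i]]),
                                    motifAsLG(motifs[[j]]))) > 0, logical(1)))
    expect_equal(!contained, motifs[[i]]@motifId %in% ids)
  }
})

test_that("embedding mapping counts match the enumeration oracle", {
  motif <- asMotif(lgraph("m", c("P:hydrophobic", "L:hydrophobic"),
                          1, 2, "hydrophobic"), "m")
  g3 <- lgraph("g", c("P:hydrophobic", "L:hydrophobic", "L:hydrophobic",
                      "P:hydrophobic"),
               c(1, 1, 4), c(2, 3, 3), rep("hydrophobic", 3))
  embs <- mapEmbeddings(motif, g3)
  expect_length(embs, 3L)
  ## absent motif: no embedding
  gx <- lgraph("gx", c("P:acceptor", "L:donor"), 1, 2, "hydrogen_bond")
  expect_length(mapEmbeddings(motif, gx), 0L)
  ## random cases against the brute-force oracle
  set.seed(53)
  for (rep_ in 1:15) {
    tg <- randomBipartiteLGraph("t", sample(2:5, 1), sample(2:5, 1),
                                sample(3:9, 1))
    subs <- plimotif:::.connectedEdgeSubsets(tg, 6)
    pat <- plimotif:::.subgraphFromEdges(tg, subs[[sample(length(subs), 1)]])
    m <- asMotif(pat, "p")
    expect_equal(length(mapEmbeddings(m, tg)),
                 length(bruteForceEmbeddings(pat, tg)))
  }
})

test_that("mining support equals support recomputed from embeddings", {
  set.seed(59)
  gs <- lapply(1:5, function(i) randomBipartiteLGraph(paste0("g", i), 3, 3, 6))
  motifs <- mineFrequentSubgraphs(gs, 0.4)
  for (m in motifs) {
    supported <- vapply(gs, function(g) length(mapEmbeddings(m, g)) > 0,
                        logical(1))
    expect_equal(sum(supported), supportCount(m))
    expect_setequal(vapply(gs[supported], `[[`, "", "graphId"), m@graphIds)
  }
})

test_that("planted motifs are recovered as (part of) a maximal motif", {
  planted <- lgraph("pl", c("P:acceptor,negative", "L:acceptor,negative",
                            "P:acceptor,negative"),
                    c(1, 3), c(2, 2), c("repulsive", "repulsive"))
  hits <- 0L
  for (seed in 1:20) {
    gs <- makePlantedDataset(planted, nGraphs = 10, plantFraction = 0.7,
                             noiseEdges = 2, seed = seed)
    maximal <- filterMaximal(mineFrequentSubgraphs(gs, 0.6))
    found <- any(vapply(maximal, function(m)
      containsSubgraph(planted, motifAsLG(m)), logical(1)))
    hits <- hits + found
  }
  expect_equal(hits, 20L)
})

test_that("ligand atom statistics count incidences and distinct graphs", {
  ## motif: L:acceptor,negative center with two repulsive edges
  motif <- asMotif(lgraph("m", c("P:acceptor,negative", "L:acceptor,negative",
                                 "P:acceptor,negative"),
                          c(1, 3), c(2, 2), c("repulsive", "repulsive")), "m")
  mkPLI <- function(id, ligAtom) {
    nodes <- data.frame(nodeId = 1:3, role = c("protein", "ligand", "protein"),
                        residueName = c("ASP", "ATP", "ASP"),
                        residueNumber = c(86L, 900L, 88L), chainId = "A",
                        atomName = c("OD1", ligAtom, "OD2"), serial = 1:3,
                        types = "acceptor,negative", stringsAsFactors = FALSE)
    edges <- data.frame(from = c(1L, 3L), to = c(2L, 2L),
                        interaction = "repulsive", distance = 5.0,
                        stringsAsFactors = FALSE)
    new("PLIGraph", graphId = id, structureId = id, chainId = "A",
        ligandName = "ATP", ligandResidueNumber = 900L,
        nodes = nodes, edges = edges)
  }
  gA <- mkPLI("gA", "O1G"); gB <- mkPLI("gB", "O1G"); gC <- mkPLI("gC", "O2B")
  embs <- c(mapEmbeddings(motif, gA), mapEmbeddings(motif, gB),
            mapEmbeddings(motif, gC))
  stats <- ligandAtomStats(motif, embs, list(gA, gB, gC))
  ## each graph: 2 embeddings (symmetric motif) x 2 edge incidences = 4
  o1g <- stats[stats$ligandAtomName == "O1G", ]
  expect_equal(o1g$interactionCount, 8L)   # 2 graphs x 4
  expect_equal(o1g$graphCount, 2L)
  o2b <- stats[stats$ligandAtomName == "O2B", ]
  expect_equal(o2b$interactionCount, 4L)
  expect_equal(o2b$graphCount, 1L)
  expect_true(all(stats$graphCount <= stats$interactionCount))
})
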