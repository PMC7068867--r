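test_that("contacts use <= on the global cutoff and cross pairs only", {
  p <- data.frame(x = 0, y = 0, z = 0)
  l <- data.frame(x = 0, y = 0, z = 6.0)
  expect_equal(nrow(computeContacts(p, l, 6.0)), 1L)
  expect_equal(computeContacts(p, l, 6.0)$distance, 6.0)
  l2 <- data.frame(x = 0, y = 0, z = 6.01)
  expect_equal(nrow(computeContacts(p, l2, 6.0)), 0L)
  p3 <- data.frame(x = c(0, 1, 2), y = 0, z = 0)
  l3 <- data.frame(x = c(0.5, 1.5), y = 1, z = 0)
  expect_equal(nrow(computeContacts(p3, l3, 6.0)), 6L)  # full cross product
})

test_that("classification matches Table-1 style windows and conditions", {
  expect_equal(classifyInteractions("hydrophobic", "hydrophobic", 3.0),
               "hydrophobic")
  expect_equal(classifyInteractions(c("acceptor", "negative"),
                                    c("acceptor", "negative"), 5.0),
               "repulsive")
  expect_setequal(classifyInteractions(c("donor", "positive"),
                                       c("acceptor", "negative"), 2.5),
                  c("hydrogen_bond", "salt_bridge"))
  expect_setequal(classifyInteractions(c("aromatic", "hydrophobic"),
                                       c("aromatic", "hydrophobic"), 3.4),
                  c("aromatic_stacking", "hydrophobic"))
})

test_that("classification is symmetric and window-sound over a random sweep", {
  crit <- defaultCriteria()
  set.seed(7)
  for (i in 1:200) {
    ti <- sample(PHYSCHEM_TYPES, sample(1:3, 1))
    tj <- sample(PHYSCHEM_TYPES, sample(1:3, 1))
    d <- runif(1, 0.5, 7)
    a <- classifyInteractions(ti, tj, d, crit)
    b <- classifyInteractions(tj, ti, d, crit)
    expect_setequal(a, b)
    for (int in a) {
      w <- crit[crit$interaction == int, ]
      expect_true(d >= w$min && d <= w$max)
    }
  }
})

test_that("custom criteria windows add and remove edges", {
  ## hydrophobic pair at 4.5 A: outside the default 3.8 window, inside a
  ## widened one
  expect_length(classifyInteractions("hydrophobic", "hydrophobic", 4.5), 0L)
  wide <- defaultCriteria()
  wide$max[wide$interaction == "hydrophobic"] <- 5.0
  expect_equal(classifyInteractions("hydrophobic", "hydrophobic", 4.5, wide),
               "hydrophobic")
})

test_that("readCriteria parses files and inline overrides", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# custom", "hydrophobic=2.0:4.5"), f)
  crit <- readCriteria(f)
  expect_equal(crit$max[crit$interaction == "hydrophobic"], 4.5)
  crit2 <- readCriteria(NULL, "salt_bridge=2.0:5.0")
  expect_equal(crit2$max[crit2$interaction == "salt_bridge"], 5.0)
  expect_error(readCriteria(NULL, "bogus=1:2"), "unknown interaction")
  expect_error(readCriteria(NULL, "hydrophobic=oops"), "malformed")
})

test_that("an engineered complex yields exactly the intended edge multiset", {
  ## 1 hydrogen bond (SER OG ~ hydroxyl O at 2.5) + 2 hydrophobic contacts
  spec <- data.frame(
    residueName = c("SER", "LEU", rep("LIG", 6)),
    residueNumber = c(10, 11, rep(900, 6)),
    atomName = c("OG", "CD1", "O1", "C1", "C2", "C3", "C4", "C5"),
    role = c("protein", "protein", rep("ligand", 6)),
    element = c("O", "C", "O", "C", "C", "C", "C", "C"),
    ##         OG   CD1   O1  C1   C2    C3  C4  C5
    x = c(0,    8,   0,   8, 9.5,  20, 21.5, 23),
    y = c(0,    0, 2.5, 3.0, 3.0,  0,    0,  0),
    z = 0, stringsAsFactors = FALSE)
  m <- stripHydrogens(parsePDB(makeComplex(spec), "eng"))
  lig <- extractLigands(m, "A")[[1]]
  g <- buildPLIGraph(m, "A", lig)
  e <- graphEdges(g)
  expect_equal(sort(e$interaction), c("hydrogen_bond", "hydrophobic",
                                      "hydrophobic"))
  ## bipartite, no isolated nodes (validity enforces both; sanity check)
  n <- graphNodes(g)
  role <- structure(n$role, names = as.character(n$nodeId))
  expect_true(all(role[as.character(e$from)] != role[as.character(e$to)]))
  expect_true(all(n$nodeId %in% c(e$from, e$to)))
})

test_that("a far-away ligand yields no graph", {
  spec <- hydrophobicComplexSpec()
  spec$y[spec$role == "ligand"] <- spec$y[spec$role == "ligand"] + 50
  m <- stripHydrogens(parsePDB(makeComplex(spec), "far"))
  lig <- extractLigands(m, "A")[[1]]
  expect_null(buildPLIGraph(m, "A", lig))
})

test_that("edge set equals a brute-force double loop with rule evaluation", {
  for (kind in c("hydrophobic", "polar")) {
    m <- stripHydrogens(parsePDB(fixturePDB(kind), kind))
    lig <- extractLigands(m, "A")[[1]]
    g <- buildPLIGraph(m, "A", lig)
    prot <- proteinAtoms(m, "A")
    prot$types <- plimotif:::.typeProteinAtoms(prot)
    ligT <- typeLigandAtoms(lig)
    expected <- list()
    for (i in seq_len(nrow(prot))) for (j in seq_len(nrow(ligT))) {
      d <- sqrt(sum((prot[i, c("x", "y", "z")] - ligT[j, c("x", "y", "z")])^2))
      ints <- oracleClassify(plimotif:::.splitTypes(prot$types[i]),
                             plimotif:::.splitTypes(ligT$types[j]), d)
      for (int in ints)
        expected[[length(expected) + 1L]] <- c(prot$serial[i],
                                               ligT$serial[j], int)
    }
    n <- graphNodes(g); e <- graphEdges(g)
    got <- lapply(seq_len(nrow(e)), function(r) c(
      n$serial[match(e$from[r], n$nodeId)],
      n$serial[match(e$to[r], n$nodeId)], e$interaction[r]))
    expect_setequal(vapply(got, paste, "", collapse = "|"),
                    vapply(expected, paste, "", collapse = "|"))
  }
})

test_that("enlarging every max distance never removes edges", {
  m <- stripHydrogens(parsePDB(fixturePDB("polar"), "mono"))
  lig <- extractLigands(m, "A")[[1]]
  base <- defaultCriteria()
  g1 <- buildPLIGraph(m, "A", lig, criteria = base)
  wide <- base; wide$max <- wide$max + 1.5
  g2 <- buildPLIGraph(m, "A", lig, criteria = wide)
  expect_gte(nrow(graphEdges(g2)), nrow(graphEdges(g1)))
  key <- function(g) { e <- graphEdges(g); paste(e$from, e$to, e$interaction) }
  expect_true(all(key(g1) %in% key(g2)))
})
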