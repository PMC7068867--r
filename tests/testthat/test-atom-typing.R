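test_that("the shipped table covers all heavy atoms of the 20 standard residues", {
  tab <- defaultTypingTable()
  residues <- unique(tab$residueName)
  expect_length(residues, 20L)
  ## every emitted type is in the closed vocabulary
  for (t in tab$types) {
    parsed <- plimotif:::.splitTypes(t)
    expect_true(all(parsed %in% PHYSCHEM_TYPES))
  }
  ## backbone conventions
  expect_setequal(typeProteinAtom("GLY", "O"), "acceptor")
  expect_setequal(typeProteinAtom("GLY", "N"), "donor")
  expect_length(typeProteinAtom("PRO", "N"), 0L)   # no amide hydrogen
})

test_that("key side-chain typings follow pharmacophore conventions", {
  expect_setequal(typeProteinAtom("PHE", "CZ"), c("aromatic", "hydrophobic"))
  expect_setequal(typeProteinAtom("ASP", "OD1"), c("acceptor", "negative"))
  expect_setequal(typeProteinAtom("LYS", "NZ"), c("donor", "positive"))
  expect_setequal(typeProteinAtom("ARG", "NH1"), c("donor", "positive"))
  expect_setequal(typeProteinAtom("SER", "OG"), c("acceptor", "donor"))
  expect_setequal(typeProteinAtom("HIS", "ND1"),
                  c("acceptor", "aromatic", "donor"))
  expect_error(typeProteinAtom("ALA", "XX9"), "no typing entry")
  ## determinism across calls
  expect_identical(typeProteinAtom("GLY", "CA"), typeProteinAtom("GLY", "CA"))
})

test_that("phosphate-like terminal oxygens perceive as acceptor+negative", {
  ## gamma-phosphate-like fragment: P with three terminal O at ~1.5 A and
  ## one bridging O to a carbon chain
  spec <- data.frame(
    residueName = "ATP", residueNumber = 900,
    atomName = c("PG", "O1G", "O2G", "O3G", "O3B", "C1", "C2"),
    role = "ligand",
    element = c("P", "O", "O", "O", "O", "C", "C"),
    x = c(0, 1.5, -0.75, -0.75, 0, 1.0, 1.0),
    y = c(0, 0, 1.3, -1.3, 0, 1.1, 2.6),
    z = c(0, 0, 0, 0, 1.52, 2.1, 2.1), stringsAsFactors = FALSE)
  lig <- new("LigandInstance", ligandName = "ATP", residueNumber = 900L,
             chainId = "A", atoms = within(spec, {
               serial <- seq_len(nrow(spec)); chainId <- "A"
               altLoc <- ""; insertionCode <- ""; occupancy <- 1
               recordKind <- "hetero"
             }))
  ty <- typeLigandAtoms(lig)
  getT <- function(a) plimotif:::.splitTypes(ty$types[ty$atomName == a])
  expect_setequal(getT("O1G"), c("acceptor", "negative"))
  expect_setequal(getT("O2G"), c("acceptor", "negative"))
  expect_setequal(getT("O3B"), c("acceptor"))          # bridging ester O
  expect_length(getT("PG"), 0L)
})

test_that("aromatic rings perceive as aromatic (and all-carbon as hydrophobic)", {
  ## planar benzene hexagon, C-C 1.39 A
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  spec <- data.frame(
    residueName = "BNZ", residueNumber = 900,
    atomName = paste0("C", 1:6), role = "ligand", element = "C",
    x = 1.39 * cos(ang) / (2 * sin(pi / 6)),
    y = 1.39 * sin(ang) / (2 * sin(pi / 6)),
    z = 0, stringsAsFactors = FALSE)
  lig <- new("LigandInstance", ligandName = "BNZ", residueNumber = 900L,
             chainId = "A", atoms = within(spec, {
               serial <- seq_len(nrow(spec)); chainId <- "A"
               altLoc <- ""; insertionCode <- ""; occupancy <- 1
               recordKind <- "hetero"
             }))
  ty <- typeLigandAtoms(lig)
  for (t in ty$types)
    expect_setequal(plimotif:::.splitTypes(t), c("aromatic", "hydrophobic"))
  ## puckered (chair-like) ring must not be aromatic
  spec$z <- rep(c(0.25, -0.25), 3)
  lig2 <- new("LigandInstance", ligandName = "CHX", residueNumber = 900L,
              chainId = "A", atoms = within(spec, {
                serial <- seq_len(nrow(spec)); chainId <- "A"
                altLoc <- ""; insertionCode <- ""; occupancy <- 1
                recordKind <- "hetero"
              }))
  ty2 <- typeLigandAtoms(lig2)
  expect_false(any(grepl("aromatic", ty2$types)))
})

test_that("override entries supersede rule-based ligand types", {
  spec <- data.frame(
    residueName = "DDP", residueNumber = 900,
    atomName = c("N1", "C1", "C2", "C3", "C4", "C5"),
    role = "ligand", element = c("N", rep("C", 5)),
    x = c(-10, 1.47, 2.97, 4.47, 5.97, 7.47), y = 0, z = 0,
    stringsAsFactors = FALSE)
  lig <- new("LigandInstance", ligandName = "DDP", residueNumber = 900L,
             chainId = "A", atoms = within(spec, {
               serial <- seq_len(nrow(spec)); chainId <- "A"
               altLoc <- ""; insertionCode <- ""; occupancy <- 1
               recordKind <- "hetero"
             }))
  ovPath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# override", "DDP\tN1\tdonor,positive"), ovPath)
  ov <- readTypingTable(ovPath)
  ty <- typeLigandAtoms(lig, overrides = ov)
  expect_equal(ty$types[ty$atomName == "N1"], "donor,positive")
  ## untouched atoms keep their rule result
  expect_equal(ty$types[ty$atomName == "C3"], "hydrophobic")
})

test_that("metals are typed empty with a warning, not an error", {
  spec <- data.frame(
    residueName = "MGX", residueNumber = 900,
    atomName = c("MG", paste0("C", 1:5)),
    role = "ligand", element = c("MG", rep("C", 5)),
    x = c(0, 10, 11.5, 13, 14.5, 16), y = 0, z = 0, stringsAsFactors = FALSE)
  lig <- new("LigandInstance", ligandName = "MGX", residueNumber = 900L,
             chainId = "A", atoms = within(spec, {
               serial <- seq_len(nrow(spec)); chainId <- "A"
               altLoc <- ""; insertionCode <- ""; occupancy <- 1
               recordKind <- "hetero"
             }))
  expect_warning(ty <- typeLigandAtoms(lig), "untypeable")
  expect_equal(ty$types[ty$atomName == "MG"], "")
})
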