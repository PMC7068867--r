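## atom_typing: assign physicochemical type sets (acceptor, aromatic, donor,
## hydrophobic, negative, positive) to protein atoms (table lookup) and to
## ligand atoms (rule-based perception at pH 7, with optional overrides).

.COVALENT_RADII <- c(H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71,
                     O = 0.66, F = 0.57, SI = 1.11, P = 1.07, S = 1.05,
                     CL = 1.02, BR = 1.20, SE = 1.20, I = 1.39)
.BOND_TOLERANCE <- 0.45      # A added to radius sum for bond perception
.CARBONYL_MAX <- 1.32        # A: C-O below this is a double bond
.RING_PLANARITY_MAX <- 0.10  # A: max out-of-plane deviation for aromaticity

.canonTypes <- function(types) {
  types <- sort(unique(types))
  stopifnot(all(types %in% PHYSCHEM_TYPES))
  paste(types, collapse = ",")
}

.splitTypes <- function(s) {
  if (is.na(s) || !nzchar(s) || s == "-") character() else
    strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Read a typing table (or override file)
#'
#' Plain-text tab-separated columns residue_name, atom_name, comma-separated
#' types; '#' starts a comment; '-' marks an untyped atom.
#'
#' @param path file path.
#' @return data.frame with columns residueName, atomName, types.
#' @export
readTypingTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed typing-table line: '", lines[bad[1]], "'")
  tab <- data.frame(residueName = vapply(parts, `[`, "", 1),
                    atomName = vapply(parts, `[`, "", 2),
                    types = vapply(parts, `[`, "", 3),
                    stringsAsFactors = FALSE)
  for (t in tab$types) .splitTypes(t)  # validates the vocabulary
  tab
}

.typingCache <- new.env(parent = emptyenv())

#' The packaged protein typing table
#'
#' Covers every heavy atom of the 20 standard amino acids; built from
#' standard pharmacophore conventions and shipped as a plain TSV
#' (\code{inst/extdata/protein_atom_types.tsv}) so users can substitute
#' their own table.
#'
#' @return data.frame with columns residueName, atomName, types.
#' @export
defaultTypingTable <- function() {
  if (is.null(.typingCache$table)) {
    path <- system.file("extdata", "protein_atom_types.tsv",
                        package = "plimotif", mustWork = TRUE)
    .typingCache$table <- readTypingTable(path)
  }
  .typingCache$table
}

.tableLookup <- function(table) {
  structure(table$types, names = paste(table$residueName, table$atomName,
                                       sep = "\r"))
}

#' Look up the type set of one protein atom
#'
#' @param residueName standard amino-acid three-letter code.
#' @param atomName heavy-atom name (e.g. "CZ", "OD1").
#' @param table typing table (default: the packaged one).
#' @return character vector of types (possibly empty: typeless atoms form
#'   no edges).
#' @export
typeProteinAtom <- function(residueName, atomName, table = defaultTypingTable()) {
  lut <- .tableLookup(table)
  hit <- lut[paste(residueName, atomName, sep = "\r")]
  if (is.na(hit))
    stop("no typing entry for (", residueName, ", ", atomName, ")")
  .splitTypes(unname(hit))
}

## Vectorized lookup used by the graph builder; returns comma-joined sets.
.typeProteinAtoms <- function(atomTable, table = defaultTypingTable()) {
  lut <- .tableLookup(table)
  hit <- lut[paste(atomTable$residueName, atomTable$atomName, sep = "\r")]
  miss <- which(is.na(hit))
  if (length(miss))
    stop("no typing entry for (", atomTable$residueName[miss[1]], ", ",
         atomTable$atomName[miss[1]], ")")
  vapply(unname(hit), function(s) .canonTypes(.splitTypes(s)), character(1))
}

## ---- ligand perception ----

## Bond perception from interatomic distances and covalent radii.
.perceiveBonds <- function(at) {
  n <- nrow(at)
  if (n < 2) return(data.frame(i = integer(), j = integer(), d = numeric()))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .COVALENT_RADII[at$element]
  rad[is.na(rad)] <- 1.5  # generous default for exotic elements
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    cut <- rad[i] + rad[(i + 1):n] + .BOND_TOLERANCE
    hit <- which(d <= cut & d > 0.4)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = i, j = i + hit, d = d[hit])
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), d = numeric()))
  do.call(rbind, out)
}

## Simple cycles of length 5 or 6 in an adjacency list, deduplicated.
.findRings <- function(adj, n) {
  rings <- list()
  seen <- character()
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen) { seen <<- c(seen, key); rings[[length(rings) + 1L]] <<- path }
      } else if (!(nb %in% path) && length(path) < 6 && nb > path[1]) {
        dfs(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  rings
}

.ringPlanar <- function(xyz) {
  c0 <- scale(xyz, scale = FALSE)
  normal <- svd(c0)$v[, 3]
  max(abs(c0 %*% normal)) <= .RING_PLANARITY_MAX
}

## Rule-based pH-7 typing of a ligand's heavy atoms.
.perceiveLigandTypes <- function(at) {
  n <- nrow(at)
  bonds <- .perceiveBonds(at)
  adj <- lapply(seq_len(n), function(i)
    sort(c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])))
  blen <- function(i, j) {
    hit <- which((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))
    if (length(hit)) bonds$d[hit[1]] else NA_real_
  }
  el <- at$element
  xyz <- as.matrix(at[, c("x", "y", "z")])

  ## aromatic perception: planar 5/6-rings of C/N/O/S whose carbons are
  ## at most 3-coordinate
  aromatic <- rep(FALSE, n)
  if (n >= 5) {
    for (ring in .findRings(adj, n)) {
      if (!all(el[ring] %in% c("C", "N", "O", "S"))) next
      if (any(el[ring] == "C" & lengths(adj[ring]) > 3)) next
      if (!.ringPlanar(xyz[ring, , drop = FALSE])) next
      aromatic[ring] <- TRUE
    }
  }

  types <- vector("list", n)
  warn <- character()
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    deg <- length(nb)
    t <- character()
    if (aromatic[i]) t <- c(t, "aromatic")
    if (el[i] == "C") {
      if (deg > 0 && all(el[nb] == "C")) t <- c(t, "hydrophobic")
    } else if (el[i] == "O") {
      if (deg == 0) t <- c(t, "acceptor", "donor")
      else if (any(el[nb] %in% c("P", "S"))) {
        if (deg == 1) t <- c(t, "acceptor", "negative") else t <- c(t, "acceptor")
      } else if (deg >= 2) t <- c(t, "acceptor")
      else { # terminal O on carbon
        cn <- nb[1]
        termO <- sum(el[adj[[cn]]] == "O" &
                     vapply(adj[[cn]], function(k) length(adj[[k]]) == 1, logical(1)))
        if (el[cn] == "C" && termO >= 2) t <- c(t, "acceptor", "negative")
        else if (!is.na(blen(i, cn)) && blen(i, cn) < .CARBONYL_MAX)
          t <- c(t, "acceptor")              # carbonyl
        else t <- c(t, "acceptor", "donor")  # hydroxyl
      }
    } else if (el[i] == "N") {
      if (aromatic[i]) {
        if (deg <= 2) t <- c(t, "acceptor", "donor")  # neutral tautomer
        ## 3-coordinate aromatic N: substituted, no polar hydrogen
      } else if (deg == 1) {
        cn <- nb[1]
        guanidinium <- el[cn] == "C" && sum(el[adj[[cn]]] == "N") >= 2
        if (guanidinium || (el[cn] == "C" && !aromatic[cn] &&
                            !any(el[adj[[cn]]] == "O")))
          t <- c(t, "donor", "positive")    # amine / guanidinium at pH 7
        else t <- c(t, "donor")             # aniline-like or amide N
      } else if (deg == 2) {
        amide <- any(vapply(nb, function(cn) el[cn] == "C" &&
          any(el[adj[[cn]]] == "O" &
              vapply(adj[[cn]], function(k) length(adj[[k]]) == 1, logical(1))),
          logical(1)))
        if (amide) t <- c(t, "donor") else t <- c(t, "donor", "positive")
      } else if (deg >= 3) {
        sp3 <- all(el[nb] == "C" & !aromatic[nb])
        if (deg == 4 || sp3) t <- c(t, "positive")
      }
    } else if (el[i] == "S") {
      if (deg == 1) t <- c(t, "donor")
    } else if (!el[i] %in% c("P", "C")) {
      warn <- c(warn, el[i])
    }
    types[[i]] <- sort(unique(t))
  }
  if (length(warn))
    warning("untypeable element(s) in ligand: ",
            paste(unique(warn), collapse = ", "), " (typed as empty set)")
  vapply(types, function(t) paste(t, collapse = ","), character(1))
}

#' Type the atoms of a ligand instance
#'
#' Rule-based perception at fixed pH 7: bonds are inferred from
#' interatomic distances and covalent radii; planar 5/6-rings give
#' aromaticity; phosphate/sulfate/carboxylate oxygens become
#' acceptor+negative, hydroxyls donor+acceptor, amines and guanidinium
#' donor+positive, carbons bonded only to carbon hydrophobic. Entries of an
#' override table (keyed by het code and atom name) win over the rules.
#'
#' @param ligand a \code{\linkS4class{LigandInstance}}.
#' @param overrides optional typing table (as from
#'   \code{\link{readTypingTable}}) keyed by het code.
#' @return data.frame: the ligand atoms plus \code{moleculeRole} and a
#'   \code{types} column (sorted comma-joined set; empty string for
#'   untypeable atoms such as metals).
#' @export
typeLigandAtoms <- function(ligand, overrides = NULL) {
  at <- atoms(ligand)
  types <- .perceiveLigandTypes(at)
  if (!is.null(overrides)) {
    lut <- .tableLookup(overrides)
    key <- paste(ligand@ligandName, at$atomName, sep = "\r")
    hit <- lut[key]
    use <- !is.na(hit)
    types[use] <- vapply(unname(hit[use]),
                         function(s) .canonTypes(.splitTypes(s)), character(1))
  }
  at$moleculeRole <- "ligand"
  at$types <- types
  at
}
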