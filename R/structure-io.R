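## structure_io: PDB reading, hydrogen stripping, ligand extraction.
## Parsing is delegated to bio3d::read.pdb; model selection, alt-loc
## resolution, element inference and the ligand/artifact filters follow the
## package's documented rules.

.STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
.WATER <- c("HOH", "DOD", "WAT")

.TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "MG", "ZN", "MN", "NA", "CA",
                          "CU", "NI", "CO", "SE", "CD", "HG", "AS", "LI",
                          "AL", "SI", "RB", "SR", "CS", "BA", "PT", "AU")

## Element inference for one atom: PDB element columns when present,
## otherwise bio3d's name lookup, otherwise the first alphabetic character
## of the atom name (two-letter symbols recognized for hetero records).
.inferElement <- function(atomName, elementCol, isHet) {
  el <- toupper(trimws(elementCol))
  if (!is.na(el) && nzchar(el)) return(el)
  nm <- toupper(trimws(atomName))
  guess <- tryCatch(suppressWarnings(bio3d::atom2ele(nm)),
                    error = function(e) NA_character_)
  if (!is.na(guess) && nzchar(guess)) return(toupper(guess))
  letters_only <- gsub("[^A-Z]", "", nm)
  if (isHet && nchar(letters_only) >= 2 &&
      substr(letters_only, 1, 2) %in% .TWO_LETTER_ELEMENTS)
    return(substr(letters_only, 1, 2))
  if (nchar(letters_only) >= 1) return(substr(letters_only, 1, 1))
  stop("cannot infer element for atom name '", atomName, "'")
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records of the first model. Alternate locations are
#' collapsed to the conformer with the highest occupancy (ties broken by the
#' alphabetically first alt-loc label); elements come from columns 77-78
#' when present and are inferred from the atom name otherwise.
#'
#' @param pdbText character: PDB file content (single string or vector of
#'   lines).
#' @param structureId identifier for the structure (PDB id or file stem).
#' @return a \code{\linkS4class{StructureModel}}.
#' @export
parsePDB <- function(pdbText, structureId) {
  lines <- unlist(strsplit(paste(pdbText, collapse = "\n"), "\n", fixed = TRUE))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("no ATOM or HETATM record found in input for '", structureId, "'")
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop("unparseable coordinate record at line ", bad[1], ": '",
         lines[bad[1]], "'")
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  pdb <- bio3d::read.pdb(f, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (!nrow(a)) stop("no atoms parsed from '", structureId, "'")

  atoms <- data.frame(
    serial = as.integer(a$eleno),
    atomName = trimws(a$elety),
    element = vapply(seq_len(nrow(a)), function(i)
      .inferElement(a$elety[i], a$elesy[i], a$type[i] == "HETATM"),
      character(1)),
    altLoc = ifelse(is.na(a$alt), "", a$alt),
    residueName = trimws(a$resid),
    residueNumber = as.integer(a$resno),
    insertionCode = ifelse(is.na(a$insert), "", a$insert),
    chainId = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    recordKind = ifelse(a$type == "HETATM", "hetero", "polymer"),
    stringsAsFactors = FALSE)

  ## alt-loc collapse: per atom site, keep highest occupancy, ties by the
  ## alphabetically first alt-loc label
  key <- paste(atoms$chainId, atoms$residueNumber, atoms$insertionCode,
               atoms$residueName, atoms$atomName, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altLoc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(match(atoms$serial, sort(atoms$serial))), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new("StructureModel", structureId = structureId, modelNumber = 1L,
      atoms = atoms)
}

#' Write a StructureModel back to PDB format
#'
#' Emits ATOM/HETATM records preserving the fields the pipeline consumes
#' (name, residue, chain, coordinates); re-parsing the output reproduces
#' them.
#'
#' @param model a \code{StructureModel}.
#' @return character vector of PDB lines (including END).
#' @export
writePDB <- function(model) {
  a <- atoms(model)
  fmt <- function(i) {
    nm <- a$atomName[i]
    ## PDB name layout: element right-justified in cols 13-14 for 1-letter
    ## elements with short names
    name4 <- if (nchar(nm) < 4 && nchar(a$element[i]) == 1)
      sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$recordKind[i] == "hetero", "HETATM", "ATOM"),
            a$serial[i], name4, substr(a$altLoc[i], 1, 1), a$residueName[i],
            a$chainId[i], a$residueNumber[i], substr(a$insertionCode[i], 1, 1),
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0,
            a$element[i])
  }
  c(vapply(seq_len(nrow(a)), fmt, character(1)), "END")
}

#' Remove hydrogen and deuterium atoms
#'
#' @param model a \code{StructureModel}.
#' @return the model without atoms of element H or D, order preserved.
#' @export
stripHydrogens <- function(model) {
  a <- atoms(model)
  keep <- !(a$element %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  new("StructureModel", structureId = model@structureId,
      modelNumber = model@modelNumber, atoms = a)
}

.checkChain <- function(model, chainId) {
  if (!chainId %in% atoms(model)$chainId)
    stop("chain '", chainId, "' not present in structure '",
         model@structureId, "'")
}

#' Extract ligand instances from one chain
#'
#' A ligand is a hetero residue on the requested chain that is not water,
#' not a standard amino acid, and has at least 6 heavy atoms (smaller
#' groups are discarded as experimental artifacts). Each (het code, residue
#' number, chain) triple yields one instance, so several copies of the same
#' het code give several ligands.
#'
#' @param model a hydrogen-stripped \code{StructureModel}.
#' @param chainId chain identifier.
#' @return list of \code{\linkS4class{LigandInstance}} (possibly empty).
#' @export
extractLigands <- function(model, chainId) {
  .checkChain(model, chainId)
  a <- atoms(model)
  het <- a[a$recordKind == "hetero" & a$chainId == chainId &
           !(toupper(a$residueName) %in% .WATER) &
           !(a$residueName %in% .STD_AA), , drop = FALSE]
  if (!nrow(het)) return(list())
  key <- paste(het$residueName, het$residueNumber, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    grp <- het[key == k, , drop = FALSE]
    if (nrow(grp) < 6L) next          # experimental-artifact filter
    rownames(grp) <- NULL
    out[[length(out) + 1L]] <- new("LigandInstance",
                                   ligandName = grp$residueName[1],
                                   residueNumber = grp$residueNumber[1],
                                   chainId = chainId, atoms = grp)
  }
  out
}

#' Protein atoms of one chain
#'
#' Polymer-record atoms of standard amino-acid residues only; modified
#' residues recorded as HETATM (e.g. MSE) are excluded.
#'
#' @param model a hydrogen-stripped \code{StructureModel}.
#' @param chainId chain identifier.
#' @return data.frame of atom records (possibly empty).
#' @export
proteinAtoms <- function(model, chainId) {
  .checkChain(model, chainId)
  a <- atoms(model)
  out <- a[a$recordKind == "polymer" & a$chainId == chainId &
           a$residueName %in% .STD_AA, , drop = FALSE]
  rownames(out) <- NULL
  out
}
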