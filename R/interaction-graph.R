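## interaction_graph: cross contacts under Euclidean cutoffs, classification
## into the five interaction types, assembly of labeled bipartite PLI graphs.

#' Default distance criteria (in angstroms)
#'
#' Per interaction type, the inclusive [min, max] distance window:
#' aromatic stacking 1.5-3.5, hydrogen bond 2.0-3.0, hydrophobic 2.0-3.8,
#' repulsive 2.0-6.0, salt bridge 2.0-6.0.
#'
#' @return data.frame with columns interaction, min, max.
#' @export
defaultCriteria <- function() {
  data.frame(
    interaction = c("aromatic_stacking", "hydrogen_bond", "hydrophobic",
                    "repulsive", "salt_bridge"),
    min = c(1.5, 2.0, 2.0, 2.0, 2.0),
    max = c(3.5, 3.0, 3.8, 6.0, 6.0),
    stringsAsFactors = FALSE)
}

.checkCriteria <- function(criteria) {
  stopifnot(all(c("interaction", "min", "max") %in% colnames(criteria)),
            setequal(criteria$interaction, INTERACTION_TYPES),
            all(criteria$min > 0), all(criteria$min < criteria$max))
  criteria[match(INTERACTION_TYPES, criteria$interaction), , drop = FALSE]
}

#' Read distance criteria from a key-value file
#'
#' One line per interaction type, e.g. \code{hydrophobic=2.0:3.8}; types
#' not mentioned keep their defaults. '#' starts a comment.
#'
#' @param path file path (or NULL for defaults).
#' @param overrides optional character vector of inline \code{type=min:max}
#'   entries applied after the file.
#' @return criteria data.frame.
#' @export
readCriteria <- function(path = NULL, overrides = character()) {
  crit <- defaultCriteria()
  entries <- character()
  if (!is.null(path)) {
    lines <- readLines(path)
    entries <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  }
  for (e in c(entries, overrides)) {
    m <- regmatches(e, regexec("^\\s*([a-z_]+)\\s*=\\s*([0-9.]+)\\s*:\\s*([0-9.]+)\\s*$", e))[[1]]
    if (length(m) != 4) stop("malformed criteria entry: '", e, "'")
    if (!m[2] %in% INTERACTION_TYPES)
      stop("unknown interaction type in criteria: '", m[2], "'")
    i <- match(m[2], crit$interaction)
    crit$min[i] <- as.numeric(m[3]); crit$max[i] <- as.numeric(m[4])
  }
  .checkCriteria(crit)
}

#' All protein-ligand atom pairs within a global cutoff
#'
#' A contact is a cross pair whose Euclidean distance is less than or equal
#' to the cutoff (boundary included). Only protein-to-ligand pairs are
#' considered, never pairs within one molecule.
#'
#' @param protein,ligand data.frames with x, y, z columns.
#' @param globalCutoff distance cutoff in angstroms (normally the maximum
#'   of all criteria windows).
#' @return data.frame with columns \code{pIdx, lIdx, distance} indexing the
#'   input rows.
#' @export
computeContacts <- function(protein, ligand, globalCutoff) {
  stopifnot(nrow(protein) > 0, nrow(ligand) > 0)
  px <- as.matrix(protein[, c("x", "y", "z")])
  lx <- as.matrix(ligand[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * (px %*% t(lx))
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  hit <- which(d <= globalCutoff, arr.ind = TRUE)
  out <- data.frame(pIdx = hit[, 1], lIdx = hit[, 2],
                    distance = d[hit])
  out[order(out$pIdx, out$lIdx), , drop = FALSE]
}

#' Classify a typed atom pair at a given distance
#'
#' Returns every interaction type whose physicochemical condition and
#' distance window are both satisfied: aromatic stacking (two aromatic
#' atoms), hydrogen bond (an acceptor and a donor, either orientation),
#' hydrophobic (two hydrophobic atoms), repulsive (same charge), salt
#' bridge (opposite charge). Symmetric in its two type sets; windows are
#' inclusive on both ends.
#'
#' @param typesI,typesJ character vectors of physicochemical types.
#' @param distance distance in angstroms.
#' @param criteria criteria data.frame (see \code{\link{defaultCriteria}}).
#' @return character vector of satisfied interaction types (possibly empty).
#' @export
classifyInteractions <- function(typesI, typesJ, distance,
                                 criteria = defaultCriteria()) {
  criteria <- .checkCriteria(criteria)
  inWin <- function(type) {
    i <- match(type, criteria$interaction)
    distance >= criteria$min[i] && distance <= criteria$max[i]
  }
  out <- character()
  if ("aromatic" %in% typesI && "aromatic" %in% typesJ &&
      inWin("aromatic_stacking")) out <- c(out, "aromatic_stacking")
  hb <- ("acceptor" %in% typesI && "donor" %in% typesJ) ||
        ("donor" %in% typesI && "acceptor" %in% typesJ)
  if (hb && inWin("hydrogen_bond")) out <- c(out, "hydrogen_bond")
  if ("hydrophobic" %in% typesI && "hydrophobic" %in% typesJ &&
      inWin("hydrophobic")) out <- c(out, "hydrophobic")
  rep_ <- ("negative" %in% typesI && "negative" %in% typesJ) ||
          ("positive" %in% typesI && "positive" %in% typesJ)
  if (rep_ && inWin("repulsive")) out <- c(out, "repulsive")
  sb <- ("negative" %in% typesI && "positive" %in% typesJ) ||
        ("positive" %in% typesI && "negative" %in% typesJ)
  if (sb && inWin("salt_bridge")) out <- c(out, "salt_bridge")
  out
}

#' Build the labeled bipartite interface graph for one ligand instance
#'
#' Computes cross contacts up to the largest criteria window, classifies
#' each contact, and emits one edge per (atom pair, satisfied interaction
#' type) - parallel typed edges between one pair are kept. Atoms without
#' any edge are excluded; when no edge exists at all, \code{NULL} is
#' returned and the caller logs the drop.
#'
#' @param model a hydrogen-stripped \code{StructureModel}.
#' @param chainId the target chain.
#' @param ligand a \code{LigandInstance} from \code{\link{extractLigands}}.
#' @param table protein typing table.
#' @param overrides optional ligand typing override table.
#' @param criteria distance criteria.
#' @return a \code{\linkS4class{PLIGraph}} or \code{NULL}.
#' @export
buildPLIGraph <- function(model, chainId, ligand,
                          table = defaultTypingTable(), overrides = NULL,
                          criteria = defaultCriteria()) {
  criteria <- .checkCriteria(criteria)
  prot <- proteinAtoms(model, chainId)
  if (!nrow(prot)) return(NULL)
  prot$moleculeRole <- "protein"
  prot$types <- .typeProteinAtoms(prot, table)
  lig <- typeLigandAtoms(ligand, overrides)

  contacts <- computeContacts(prot, lig, max(criteria$max))
  if (!nrow(contacts)) return(NULL)

  edges <- list()
  for (r in seq_len(nrow(contacts))) {
    ti <- .splitTypes(prot$types[contacts$pIdx[r]])
    tj <- .splitTypes(lig$types[contacts$lIdx[r]])
    if (!length(ti) || !length(tj)) next
    ints <- classifyInteractions(ti, tj, contacts$distance[r], criteria)
    for (int in ints)
      edges[[length(edges) + 1L]] <- data.frame(
        pIdx = contacts$pIdx[r], lIdx = contacts$lIdx[r],
        interaction = int, distance = round(contacts$distance[r], 2),
        stringsAsFactors = FALSE)
  }
  if (!length(edges)) return(NULL)
  e <- do.call(rbind, edges)

  pKeep <- sort(unique(e$pIdx)); lKeep <- sort(unique(e$lIdx))
  mkNodes <- function(df, keep, role, offset) {
    data.frame(nodeId = offset + seq_along(keep), role = role,
               residueName = df$residueName[keep],
               residueNumber = df$residueNumber[keep],
               chainId = df$chainId[keep], atomName = df$atomName[keep],
               serial = df$serial[keep], types = df$types[keep],
               stringsAsFactors = FALSE)
  }
  pn <- mkNodes(prot, pKeep, "protein", 0L)
  ln <- mkNodes(lig, lKeep, "ligand", nrow(pn))
  edgeDf <- data.frame(
    from = pn$nodeId[match(e$pIdx, pKeep)],
    to = ln$nodeId[match(e$lIdx, lKeep)],
    interaction = e$interaction, distance = e$distance,
    stringsAsFactors = FALSE)
  gid <- sprintf("%s_%s_%s%d", model@structureId, chainId,
                 ligand@ligandName, ligand@residueNumber)
  new("PLIGraph", graphId = gid, structureId = model@structureId,
      chainId = chainId, ligandName = ligand@ligandName,
      ligandResidueNumber = ligand@residueNumber,
      nodes = rbind(pn, ln), edges = edgeDf)
}

#' All interface graphs of one structure chain
#'
#' Convenience wrapper: extracts the ligand instances of a chain and builds
#' one graph per instance, dropping those without any classified edge.
#'
#' @inheritParams buildPLIGraph
#' @return list of \code{PLIGraph}.
#' @export
buildChainGraphs <- function(model, chainId, table = defaultTypingTable(),
                             overrides = NULL, criteria = defaultCriteria()) {
  ligs <- extractLigands(model, chainId)
  out <- list()
  for (lig in ligs) {
    g <- buildPLIGraph(model, chainId, lig, table, overrides, criteria)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}
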