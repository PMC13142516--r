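# Structure input: PDB (and, where bio3d parses them, mmCIF) files are read
# into ChainStructure objects. Hydrogens, waters and heteroatoms are dropped
# by default; alternate locations keep the highest-occupancy conformer.

THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read protein chains from a structure file
#'
#' Parses a PDB (or mmCIF, when the underlying reader supports it) file and
#' returns one [ChainStructure-class] per polypeptide chain. Waters and
#' heteroatom records are excluded, hydrogens dropped, and alternate
#' locations resolved to the highest-occupancy conformer. Element radii are
#' assigned from the package's van der Waals table.
#'
#' @param path Structure file path.
#' @param chains Optional character vector restricting which chain IDs to
#'   return.
#' @return Named list of [ChainStructure-class] objects.
#' @export
readChains <- function(path, chains = NULL) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(trimws(at$elety), 1L, 1L), trimws(at$elesy)))
  keep <- elem != "H"
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  # highest-occupancy alternate conformer per (chain, resno, atom name)
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -replace(at$o, is.na(at$o), 1))
    at <- at[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    elem <- elem[ord][!duplicated(sort(key))]
  }
  wanted <- if (is.null(chains)) unique(at$chain) else chains
  out <- list()
  for (cid in wanted) {
    sub <- at[at$chain == cid, , drop = FALSE]
    if (!nrow(sub)) next
    resKey <- paste(sub$resno, sub$insert)
    uniq <- !duplicated(resKey)
    residues <- data.frame(resNo = sub$resno[uniq],
                           resName = sub$resid[uniq],
                           stringsAsFactors = FALSE)
    resIdx <- match(resKey, resKey[uniq])
    el <- elem[at$chain == cid]
    atoms <- data.frame(element = el, resIdx = resIdx,
                        x = sub$x, y = sub$y, z = sub$z,
                        radius = unname(ifelse(is.na(ELEMENT_RADII[el]),
                                               DEFAULT_RADIUS,
                                               ELEMENT_RADII[el])),
                        stringsAsFactors = FALSE)
    out[[cid]] <- chainStructure(cid, residues, atoms)
  }
  out
}

#' One-letter sequence of a chain
#' @param chain A [ChainStructure-class].
#' @return Character string; unrecognised residue types become `X`.
#' @export
chainSequence <- function(chain) {
  one <- THREE_TO_ONE[chainResidues(chain)$resName]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Write chains as a minimal PDB file
#'
#' Emits ATOM records (single conformer, occupancy 1.00) for a list of
#' chains — enough structure for the package's own reader and the SASA
#' labeler; used mainly to materialise synthetic toy complexes.
#'
#' @param chains List of [ChainStructure-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeChainsPdb <- function(chains, path) {
  if (is(chains, "ChainStructure")) chains <- list(chains)
  lines <- character(0)
  serial <- 0L
  for (ch in chains) {
    res <- chainResidues(ch); at <- chainAtoms(ch)
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", at$element[i]), res$resName[at$resIdx[i]],
        chainId(ch), res$resNo[at$resIdx[i]],
        at$x[i], at$y[i], at$z[i], 1.0, 0.0, at$element[i]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
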