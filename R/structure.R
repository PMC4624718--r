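# Two-chain complex structures: parsing, construction, writing.

#' Construct a complex structure from an atom table
#'
#' Low-level constructor used by the PDB reader and the fixture generators.
#' Atoms are grouped into residues by (chain, author number, insertion code),
#' ordered by chain (in the order of `chain_ids`) and author numbering.
#' Internally residues carry contiguous 1-based indices (`res_idx`); all
#' reports map back to author numbering.
#'
#' @param id text identifier for the complex.
#' @param atoms data frame with columns chain, resno, ins, resname, elety,
#'   element, x, y, z (heavy atoms only, protein residues only).
#' @param chain_ids the two chain identifiers, in order.
#' @return An object of class `complex_structure` with elements `id`,
#'   `chain_ids`, `atoms` (with a `res_idx` column) and `residues`
#'   (one row per residue: res_idx, chain, resno, ins, resname, aa).
#' @export
complex_structure <- function(id, atoms, chain_ids) {
  stopifnot(length(chain_ids) == 2L)
  atoms <- atoms[atoms$chain %in% chain_ids, , drop = FALSE]
  for (ch in chain_ids) {
    if (!any(atoms$chain == ch)) {
      stop("chain not found: ", ch)
    }
  }
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  ord <- order(match(atoms$chain, chain_ids), atoms$resno, atoms$ins)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  res_idx <- match(key, unique(key))
  atoms$res_idx <- res_idx
  first <- !duplicated(res_idx)
  residues <- data.frame(
    res_idx = res_idx[first],
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    ins = atoms$ins[first],
    resname = atoms$resname[first],
    stringsAsFactors = FALSE)
  residues$aa <- aa321(residues$resname)
  if (anyNA(residues$aa)) {
    bad <- unique(residues$resname[is.na(residues$aa)])
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  structure(list(id = id, chain_ids = chain_ids, atoms = atoms,
                 residues = residues),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  n <- table(factor(x$residues$chain, levels = x$chain_ids))
  cat("complex_structure '", x$id, "': chains ",
      paste(sprintf("%s (%d res)", x$chain_ids, as.integer(n)),
            collapse = ", "),
      ", ", nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' @param complex a `complex_structure`.
#' @param chain chain identifier.
#' @return Character scalar, the one-letter amino-acid sequence.
#' @export
chain_sequence <- function(complex, chain) {
  paste(complex$residues$aa[complex$residues$chain == chain], collapse = "")
}

#' Parse a dimeric complex from a PDB file
#'
#' Reads ATOM records via bio3d, strips waters, hetero ligands and hydrogens,
#' and restricts to the two requested protein chains. Residues are ordered by
#' author numbering (insertion codes respected).
#'
#' @param file path to a PDB file.
#' @param chain_ids two chain identifiers, e.g. `c("A", "B")`.
#' @param id identifier for the complex (defaults to the file base name).
#' @return A [complex_structure()].
#' @export
read_complex <- function(file, chain_ids, id = NULL) {
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(file))
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", file,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[toupper(at$resid) %in% names(AA1_FROM_3), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9']", "", at$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("no protein residues in '", file, "'")
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      ins = ifelse(is.na(at$insert), "", at$insert),
                      resname = toupper(at$resid), elety = at$elety,
                      element = elem, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  for (ch in chain_ids) {
    if (!any(atoms$chain == ch)) stop("chain not found: ", ch)
  }
  complex_structure(id, atoms, chain_ids)
}

#' Write a complex structure as a PDB file
#'
#' @param complex a `complex_structure`.
#' @param file output path.
#' @return Invisibly, the path written.
#' @export
write_pdb <- function(complex, file) {
  a <- complex$atoms
  lines <- character(nrow(a) + length(complex$chain_ids) + 1L)
  li <- 0L
  serial <- 0L
  for (ch in complex$chain_ids) {
    idx <- which(a$chain == ch)
    for (i in idx) {
      serial <- serial + 1L
      li <- li + 1L
      name <- a$elety[i]
      # PDB atom-name column convention: 1-char elements start in column 14
      name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
      lines[li] <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name_fmt, a$resname[i], ch, a$resno[i],
        ifelse(a$ins[i] == "", " ", a$ins[i]),
        a$x[i], a$y[i], a$z[i], 1, 0, a$element[i])
    }
    li <- li + 1L
    lines[li] <- "TER"
  }
  li <- li + 1L
  lines[li] <- "END"
  writeLines(lines[seq_len(li)], file)
  invisible(file)
}

# Extract one chain as a stand-alone single-chain structure's atom table.
chain_atoms <- function(complex, chain) {
  complex$atoms[complex$atoms$chain == chain, , drop = FALSE]
}
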