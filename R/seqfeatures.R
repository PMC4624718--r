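# Sequence-derived mutation features and the energy-combination contract.

#' Parse a semicolon-joined mutation string
#'
#' Tokens have the form "L45D": wild-type residue, author position, mutant
#' residue. Multi-site mutations are separated by ";".
#'
#' @param x character scalar, e.g. `"L45D;K12E"`.
#' @return Data frame with columns wt, resno, mut.
#' @export
parse_mutations <- function(x) {
  toks <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty mutation string")
  m <- regmatches(toks, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", toks))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed mutation token(s): ",
                     paste(toks[bad], collapse = ", "))
  out <- data.frame(wt = toupper(vapply(m, `[`, character(1), 2L)),
                    resno = as.integer(vapply(m, `[`, character(1), 3L)),
                    mut = toupper(vapply(m, `[`, character(1), 4L)),
                    stringsAsFactors = FALSE)
  if (!all(c(out$wt, out$mut) %in% AA1)) stop("nonstandard amino acid code")
  if (any(out$wt == out$mut)) stop("wild-type equals mutant at position(s) ",
                                   paste(out$resno[out$wt == out$mut],
                                         collapse = ", "))
  out
}

#' A single mutation event on one side of an interface
#'
#' @param complex_id complex identifier.
#' @param chain chain carrying all substitutions (mutations are restricted
#'   to one side of the interface).
#' @param mutations mutation string, see [parse_mutations()].
#' @param ddg_exp optional experimental ddG (kcal/mol).
#' @param temperature optional temperature (K).
#' @return Object of class `mutation_record`.
#' @export
mutation_record <- function(complex_id, chain, mutations, ddg_exp = NA_real_,
                            temperature = NA_real_) {
  sites <- parse_mutations(mutations)
  structure(list(complex_id = complex_id, chain = chain, sites = sites,
                 ddg_exp = ddg_exp, temperature = temperature),
            class = "mutation_record")
}

#' Pharmacophore count differences between mutant and wild type
#'
#' For each of five (intentionally overlapping) residue categories --
#' hydrophobic (V, I, L, M, F, W, C), aromatic (Y, F, W), charged
#' (R, K, D, E), hydrogen-bond acceptors (D, E, N, H, Q, S, T, Y) and
#' donors (R, K, W, N, Q, H, S, T, Y) -- the signed count difference
#' (mutant minus wild type), summed over substitution sites.
#'
#' @param wt,mut one-letter codes of wild-type and mutant residues (equal
#'   length; one entry per substituted site).
#' @return Named numeric vector: d_hydrophobic, d_aromatic, d_charged,
#'   d_acceptors, d_donors.
#' @export
pharmacophore_deltas <- function(wt, mut) {
  wt <- toupper(wt); mut <- toupper(mut)
  stopifnot(length(wt) == length(mut))
  if (!all(c(wt, mut) %in% AA1)) stop("nonstandard amino acid code")
  v <- vapply(PHARMACOPHORE, function(set)
    sum(mut %in% set) - sum(wt %in% set), numeric(1))
  setNames(v, paste0("d_", names(PHARMACOPHORE)))
}

#' Residue volume difference between mutant and wild type
#'
#' Signed difference of mean residue volumes (Zamyatnin table, Angstrom^3),
#' summed over substitution sites.
#'
#' @inheritParams pharmacophore_deltas
#' @return Numeric scalar, Angstrom^3.
#' @export
volume_delta <- function(wt, mut) {
  wt <- toupper(wt); mut <- toupper(mut)
  if (!all(c(wt, mut) %in% AA1)) stop("nonstandard amino acid code")
  sum(AA_VOLUME[mut] - AA_VOLUME[wt])
}

#' All six sequence features of a mutation record
#'
#' @param record a [mutation_record()].
#' @return Named numeric vector: five pharmacophore deltas plus d_volume.
#' @export
sequence_features <- function(record) {
  s <- record$sites
  c(pharmacophore_deltas(s$wt, s$mut),
    d_volume = volume_delta(s$wt, s$mut))
}

#' Combine external energy terms into a ddG
#'
#' Four-term form: `ddG = [E_WT(complex) - E_WT(monomers)] -
#' [E_Mut(complex) - E_Mut(monomers)]`. When the monomer energies are
#' omitted (potentials that perform the monomer subtraction internally), the
#' two-term form `E_WT(complex) - E_Mut(complex)` is used.
#'
#' @param e_wt_complex,e_mut_complex energies of the wild-type and mutant
#'   complexes (kcal/mol).
#' @param e_wt_monomers,e_mut_monomers optional summed monomer energies.
#' @return ddG in kcal/mol.
#' @export
combine_energy_terms <- function(e_wt_complex, e_mut_complex,
                                 e_wt_monomers = NULL,
                                 e_mut_monomers = NULL) {
  vals <- c(e_wt_complex, e_mut_complex, e_wt_monomers, e_mut_monomers)
  if (!all(is.finite(vals))) stop("non-finite energy input")
  if (is.null(e_wt_monomers) != is.null(e_mut_monomers)) {
    stop("supply both monomer energies or neither")
  }
  if (is.null(e_wt_monomers)) {
    e_wt_complex - e_mut_complex
  } else {
    (e_wt_complex - e_wt_monomers) - (e_mut_complex - e_mut_monomers)
  }
}

#' Read a mutation table
#'
#' Tab-separated with columns complex_id, chain, mutations (semicolon-joined
#' tokens like "L45D"), ddg_exp, temperature (a simplified experimental
#' mutation-table dialect).
#'
#' @param file path to the TSV.
#' @return Data frame of the raw rows; malformed rows raise an error naming
#'   the row number.
#' @export
read_mutation_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("complex_id", "chain", "mutations")
  if (!all(need %in% names(df))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$ddg_exp)) df$ddg_exp <- NA_real_
  if (is.null(df$temperature)) df$temperature <- NA_real_
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ parse_mutations(df$mutations[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("row ", i, ": ", ok)
  }
  df
}
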