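# Binding interface extraction, cross-chain contacts, residue classification.

# All cross-chain residue pairs whose closest heavy atoms lie within `cutoff`.
cross_chain_pairs <- function(complex, cutoff) {
  a1 <- chain_atoms(complex, complex$chain_ids[1])
  a2 <- chain_atoms(complex, complex$chain_ids[2])
  x1 <- as.matrix(a1[, c("x", "y", "z")])
  x2 <- as.matrix(a2[, c("x", "y", "z")])
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- cbind(i = a1$res_idx[hit[, 1]], j = a2$res_idx[hit[, 2]])
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Extract the binding interface of a dimeric complex
#'
#' A residue is interfacial iff any of its heavy atoms lies within `cutoff`
#' of any heavy atom of the other chain. Cross-chain residue-residue contacts
#' (used by the contact-overlap terms of the similarity scores) use a
#' slightly looser distance, `contact_cutoff`.
#'
#' @param complex a [complex_structure()].
#' @param cutoff interface depth in Angstrom (any heavy atom).
#' @param contact_cutoff cross-chain contact distance in Angstrom.
#' @return An object of class `interface_model`: `interface` (residue indices
#'   ordered by chain then author number), `contacts` (two-column matrix of
#'   contacting res_idx pairs, chain 1 first), `L_Q` (total interface residue
#'   count), plus the originating complex.
#' @export
extract_interface <- function(complex, cutoff = 4.0, contact_cutoff = 4.5) {
  iface_pairs <- cross_chain_pairs(complex, cutoff)
  if (nrow(iface_pairs) == 0L) stop("no interface: no cross-chain heavy-atom ",
                                    "pair within ", cutoff, " A")
  iface <- sort(unique(c(iface_pairs)))
  contacts <- cross_chain_pairs(complex, contact_cutoff)
  # contacts are defined between interface residues only
  contacts <- contacts[contacts[, 1] %in% iface & contacts[, 2] %in% iface,
                       , drop = FALSE]
  structure(list(complex = complex, interface = iface, contacts = contacts,
                 L_Q = length(iface), cutoff = cutoff,
                 contact_cutoff = contact_cutoff),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  res <- x$complex$residues
  n <- table(factor(res$chain[x$interface], levels = x$complex$chain_ids))
  cat("interface_model of '", x$complex$id, "': L_Q = ", x$L_Q, " (",
      paste(sprintf("%s: %d", names(n), as.integer(n)), collapse = ", "),
      "), ", nrow(x$contacts), " cross-chain contacts\n", sep = "")
  invisible(x)
}

#' Classify residues by burial change upon complex formation
#'
#' Five-class partition driven by relative accessibility in the monomer
#' (rASA) and in the complex (rASA_c) with a 25% exposure threshold, plus
#' cross-chain contact: core (exposed in the monomer, buried in the complex),
#' rim (exposed in both, in contact), support (buried in the monomer, in
#' contact), interior (buried in both, no contact), surface (exposed in both,
#' no contact). A rASA of exactly 0.25 counts as buried. The partition is
#' total: every (rasa, rasa_c, contact) triple receives exactly one class.
#'
#' @param rasa relative accessibility in the monomer.
#' @param rasa_c relative accessibility in the complex.
#' @param in_contact logical; does the residue form a cross-chain contact?
#' @return Character vector of classes.
#' @export
classify_residue <- function(rasa, rasa_c, in_contact) {
  n <- length(rasa)
  stopifnot(length(rasa_c) == n, length(in_contact) == n)
  exposed_m <- rasa > 0.25      # exactly 0.25 counts as buried
  exposed_c <- rasa_c > 0.25
  cls <- ifelse(exposed_m,
                ifelse(!exposed_c, "core",
                       ifelse(in_contact, "rim", "surface")),
                ifelse(in_contact, "support", "interior"))
  as.character(cls)
}

#' Build a fully annotated interface model
#'
#' Combines interface extraction, relative accessibility and residue
#' classification so every residue of the complex carries exactly one of the
#' five burial classes.
#'
#' @inheritParams extract_interface
#' @param n_points Shrake-Rupley test points per atom.
#' @return An `interface_model` whose `accessibility` element holds the
#'   per-residue rASA table with a `class` column.
#' @export
build_interface_model <- function(complex, cutoff = 4.0,
                                  contact_cutoff = 4.5, n_points = 960L) {
  im <- extract_interface(complex, cutoff, contact_cutoff)
  acc <- relative_accessibility(complex, n_points = n_points)
  in_contact <- acc$res_idx %in% c(im$contacts)
  # classification clamps relative accessibilities above 1
  acc$class <- classify_residue(pmin(acc$rasa, 1), pmin(acc$rasa_c, 1),
                                in_contact)
  im$accessibility <- acc
  im
}

# Interface residues of one chain with Calpha coordinates and amino acids,
# in author-number order. Used by the alignment module.
interface_chain_data <- function(im, chain) {
  cx <- im$complex
  idx <- im$interface[cx$residues$chain[im$interface] == chain]
  at <- cx$atoms
  ca <- at[at$elety == "CA" & at$res_idx %in% idx, , drop = FALSE]
  ca <- ca[match(idx, ca$res_idx), , drop = FALSE]
  list(res_idx = idx,
       ca = as.matrix(ca[, c("x", "y", "z")]),
       aa = cx$residues$aa[idx])
}

# Number of cross-chain contacts per residue, as a named vector over res_idx.
contact_counts <- function(im) {
  tab <- table(c(im$contacts))
  setNames(as.integer(tab), names(tab))
}
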