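# Solvent accessible surface area (Shrake-Rupley) and relative accessibility.

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# construction).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Computes per-atom SASA by rolling a probe sphere over each atom and
#' counting test points not occluded by any neighbouring atom. Deterministic:
#' test points come from a fixed golden-spiral construction.
#'
#' @param xyz N x 3 matrix of heavy-atom coordinates (Angstrom).
#' @param elements character vector of element symbols (C, N, O, S, P, SE),
#'   used to assign van der Waals radii; alternatively supply `radii`.
#' @param radii optional numeric vector of atom radii (Angstrom), overriding
#'   the element table.
#' @param probe_radius probe radius in Angstrom (water, 1.4).
#' @param n_points number of test points per atom.
#' @return Numeric vector of per-atom SASA values (Angstrom^2).
#' @export
compute_sasa <- function(xyz, elements = NULL, radii = NULL,
                         probe_radius = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, probe_radius > 0)
  if (is.null(radii)) {
    if (is.null(elements)) stop("supply either elements or radii")
    radii <- ELEMENT_RADII[toupper(elements)]
    if (anyNA(radii)) {
      bad <- unique(elements[is.na(radii)])
      stop("unknown element(s): ", paste(bad, collapse = ", "))
    }
  }
  stopifnot(length(radii) == nrow(xyz))
  pts <- sphere_points(n_points)
  frac <- .sr_accessible(xyz, as.numeric(radii), probe_radius, pts)
  4 * pi * (radii + probe_radius)^2 * frac
}

# Per-residue SASA sums for one atom table.
residue_sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  s <- compute_sasa(as.matrix(atoms[, c("x", "y", "z")]),
                    elements = atoms$element, probe_radius = probe_radius,
                    n_points = n_points)
  tapply(s, atoms$res_idx, sum)
}

#' Relative solvent accessibility in monomer and complex
#'
#' Computes each residue's SASA twice -- with its chain in isolation
#' (monomeric state) and in the assembled complex -- and normalizes both by a
#' fixed per-residue-type theoretical maximum, yielding rASA and rASA_c.
#' Burial can only increase upon binding, so rASA_c <= rASA up to numerical
#' tolerance.
#'
#' @param complex a [complex_structure()].
#' @param probe_radius probe radius in Angstrom.
#' @param n_points Shrake-Rupley test points per atom.
#' @return Data frame with one row per residue: res_idx, chain, resno, aa,
#'   sasa_monomer, sasa_complex, rasa, rasa_c.
#' @export
relative_accessibility <- function(complex, probe_radius = 1.4,
                                   n_points = 960L) {
  res <- complex$residues
  if (!all(res$resname %in% names(MAX_ASA))) {
    bad <- unique(res$resname[!res$resname %in% names(MAX_ASA)])
    stop("residue type(s) absent from reference table: ",
         paste(bad, collapse = ", "))
  }
  sasa_c <- rep(NA_real_, nrow(res))
  cx <- residue_sasa(complex$atoms, probe_radius, n_points)
  sasa_c[as.integer(names(cx))] <- cx
  sasa_m <- rep(NA_real_, nrow(res))
  for (ch in complex$chain_ids) {
    at <- chain_atoms(complex, ch)
    mm <- residue_sasa(at, probe_radius, n_points)
    sasa_m[as.integer(names(mm))] <- mm
  }
  maxref <- MAX_ASA[res$resname]
  data.frame(res_idx = res$res_idx, chain = res$chain, resno = res$resno,
             ins = res$ins, aa = res$aa,
             sasa_monomer = sasa_m, sasa_complex = sasa_c,
             rasa = unname(sasa_m / maxref),
             rasa_c = unname(sasa_c / maxref),
             stringsAsFactors = FALSE)
}
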