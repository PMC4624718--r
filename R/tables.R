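# Reference tables shared across modules. All are fixed conventions of the
# method; none are fit to data.

#' Amino-acid one-letter codes in canonical order
#' @format Character vector of the 20 standard one-letter codes.
#' @export
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
names(AA3) <- AA1
AA1_FROM_3 <- setNames(AA1, AA3)

#' Convert three-letter residue names to one-letter codes
#'
#' @param resname character vector of three-letter residue names.
#' @return One-letter codes; `NA` for non-standard residues.
#' @export
aa321 <- function(resname) unname(AA1_FROM_3[toupper(resname)])

# Bondi-style van der Waals radii (Angstrom) for heavy elements found in
# protein structures.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                   SE = 1.90)

# Theoretical maximum solvent accessibility (Angstrom^2) per residue type in a
# Gly-X-Gly context (Tien et al.-style theoretical values), used to normalize
# SASA to relative accessibility.
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
             GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
             LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
             SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Six non-overlapping physicochemical classes used by the PCscore chemical
# match indicator.
CHEM_CLASS <- c(
  K = "pos", R = "pos",
  E = "neg", D = "neg",
  N = "donor_acceptor", Q = "donor_acceptor", S = "donor_acceptor",
  T = "donor_acceptor",
  F = "aromatic", W = "aromatic",
  C = "hydrophobic", A = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", P = "hydrophobic",
  V = "hydrophobic", G = "hydrophobic",
  H = "his_tyr", Y = "his_tyr")

# Pharmacophore category sets for sequence feature counting. Categories
# intentionally overlap (e.g. W is hydrophobic, aromatic and a donor).
PHARMACOPHORE <- list(
  hydrophobic = c("V", "I", "L", "M", "F", "W", "C"),
  aromatic    = c("Y", "F", "W"),
  charged     = c("R", "K", "D", "E"),
  acceptors   = c("D", "E", "N", "H", "Q", "S", "T", "Y"),
  donors      = c("R", "K", "W", "N", "Q", "H", "S", "T", "Y"))

# Zamyatnin mean residue volumes (Angstrom^3).
AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# BLOSUM62 background amino-acid frequencies (Henikoff counts), renormalized.
BG_FREQ <- local({
  f <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
         E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
         M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
         Y = 0.032, V = 0.073)
  f / sum(f)
})

#' Retrieve a substitution matrix restricted to the 20 standard amino acids
#'
#' @param name matrix name as provided by Biostrings (default "BLOSUM62").
#' @return 20 x 20 numeric matrix with rows/columns in canonical order.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  m[AA1, AA1]
}

#' Physicochemical class of an amino acid
#'
#' Assigns each standard amino acid to one of six non-overlapping classes:
#' positively charged (K, R), negatively charged (E, D), mixed hydrogen-bond
#' donor/acceptor (N, Q, S, T), aromatic (F, W), hydrophobic
#' (C, A, I, L, M, P, V, G) and mixed donor/acceptor-or-aromatic (H, Y).
#'
#' @param aa character vector of one-letter amino-acid codes.
#' @return Character vector of class labels.
#' @export
chemical_class <- function(aa) {
  cls <- CHEM_CLASS[toupper(aa)]
  if (anyNA(cls)) {
    bad <- unique(aa[is.na(cls)])
    stop("nonstandard amino acid code(s): ", paste(bad, collapse = ", "))
  }
  unname(cls)
}
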