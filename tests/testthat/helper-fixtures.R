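# Shared fixture builders. Everything is generated in code; no files on disk
# beyond temporary ones created inside tests.

# A minimal two-chain complex with one single-atom residue per chain,
# separated by `gap` Angstrom (carbon atoms), for interface cutoff tests.
two_atom_complex <- function(gap, resname = c("GLY", "ALA")) {
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), ins = "",
    resname = resname,
    elety = "CA", element = "C",
    x = c(0, gap), y = 0, z = 0, stringsAsFactors = FALSE)
  complex_structure("twoatom", atoms, c("A", "B"))
}

# Fake template hits for profile tests: aligned sequences over L positions
# (NA = gap), with optional per-position distances and contact fractions.
fake_hits <- function(seqs, sims = NULL, d = NULL, f = NULL,
                      positions = NULL) {
  L <- length(seqs[[1]])
  if (is.null(sims)) sims <- seq(1, 0.5, length.out = length(seqs))
  hits <- lapply(seq_along(seqs), function(k) {
    s <- seqs[[k]]
    list(id = sprintf("fake%02d", k), similarity = sims[k], report = NULL,
         aligned_seq = s,
         d = if (is.null(d)) ifelse(is.na(s), NA_real_, 0.5) else d[[k]],
         f = if (is.null(f)) ifelse(is.na(s), NA_real_, 1.0) else f[[k]])
  })
  if (is.null(positions)) {
    positions <- data.frame(chain = "A", resno = seq_len(L), ins = "",
                            aa = rep("A", L), stringsAsFactors = FALSE)
  }
  structure(hits, positions = positions)
}

# Apply a random rigid motion (and optional Gaussian coordinate noise) to a
# complex; used for alignment invariance and noise-degradation tests.
perturb_complex <- function(cx, sigma = 0, seed = 1L) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")])
  if (sigma > 0) xyz <- xyz + matrix(rnorm(length(xyz), sd = sigma),
                                     ncol = 3)
  xyz <- xyz %*% (Rx %*% Rz)
  xyz <- sweep(xyz, 2, runif(3, -10, 10), "+")
  cx$atoms[, c("x", "y", "z")] <- xyz
  cx
}

# Independent brute-force score summations (kept deliberately plain).
oracle_itm <- function(d, L, d0v) {
  s <- 0
  for (di in d) s <- s + 1 / (1 + di^2 / d0v^2)
  s / L
}
oracle_iscore <- function(d, f, L, d0v) {
  s <- 0
  for (i in seq_along(d)) s <- s + f[i] / (1 + d[i]^2 / d0v^2)
  s / L
}
oracle_pc <- function(d, I, L, fc) {
  s <- 0
  for (i in seq_along(d)) s <- s + 1 / (1 + 0.25 * (1 - I[i]) + d[i]^2 / 16)
  fc * s / L
}
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  tot <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) tot <- tot + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) tot <- tot + 0.5 * q[i] * log2(q[i] / m[i])
  }
  tot
}
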