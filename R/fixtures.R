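# Deterministic synthetic fixtures: toy dimers, template families drawn from
# a known per-position amino-acid distribution, and mutation tables with
# replicates and injected outliers. These exist to exercise code paths and
# formulas with known ground truth, not to be physically realistic proteins.

#' Specification for synthetic fixtures
#'
#' @param seed mandatory RNG seed; all generators are byte-deterministic
#'   given the spec.
#' @param interface_length residues per chain posed in cross-chain contact.
#' @param flank extra non-interface residues on each end of the first chain.
#' @param n_templates family size for [make_template_family()].
#' @param noise_max maximum coordinate noise sigma (Angstrom); the family
#'   grades sigma from 0 to this value so similarities span loose to 1.
#' @param lambda concentration of the default per-position amino-acid
#'   distribution (see [make_position_distribution()]).
#' @param pi optional positions x 20 probability matrix overriding the
#'   default distribution.
#' @param duplicate_rate fraction of templates that reuse the previous
#'   template's interface sequence (exercises deduplication).
#' @param n_mutations rows in [make_mutation_table()].
#' @param replicate_rate fraction of mutation rows receiving replicates.
#' @param outlier_rate fraction of replicate groups receiving one high
#'   outlier.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, interface_length = 12L, flank = 3L,
                         n_templates = 50L, noise_max = 2.0, lambda = 0.5,
                         pi = NULL, duplicate_rate = 0,
                         n_mutations = 60L, replicate_rate = 0.2,
                         outlier_rate = 0.1) {
  stopifnot(!missing(seed), interface_length >= 1L, flank >= 0L,
            noise_max >= 0,
            duplicate_rate >= 0, duplicate_rate <= 1,
            replicate_rate >= 0, replicate_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  structure(list(seed = as.integer(seed),
                 interface_length = as.integer(interface_length),
                 flank = as.integer(flank),
                 n_templates = as.integer(n_templates),
                 noise_max = noise_max, lambda = lambda, pi = pi,
                 duplicate_rate = duplicate_rate,
                 n_mutations = as.integer(n_mutations),
                 replicate_rate = replicate_rate,
                 outlier_rate = outlier_rate),
            class = "fixture_spec")
}

# Idealized residue: backbone (N, CA, C, O) + CB in a zig-zag extended
# geometry. `s` alternates the pleat, `zdir` points CB toward the partner
# chain. CA sits at (x0, y0, z0).
residue_atoms <- function(resno, resname, chain, x0, y0, z0, s, zdir) {
  data.frame(chain = chain, resno = resno, ins = "", resname = resname,
             elety = c("N", "CA", "C", "O", "CB"),
             element = c("N", "C", "C", "O", "C"),
             x = x0 + c(-1.20, 0, 1.25, 1.65, 0),
             y = y0 + c(0.95 * s, 0, 0.90 * s, 2.06 * s, -0.55 * s),
             z = z0 + c(0, 0, 0, 0, 1.43 * zdir),
             stringsAsFactors = FALSE)
}

#' Generate an idealized two-chain dimer with a defined contact interface
#'
#' Two antiparallel extended chains are posed so that `interface_length`
#' residues of each chain fall within 4 Angstrom of the partner (CB atoms
#' face each other across the interface). Chain A carries `flank` extra
#' residues on each end that stay out of contact. Heavy atoms are backbone
#' plus CB with ideal local geometry. Deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @param id identifier for the complex.
#' @return A [complex_structure()] with chains "A" and "B".
#' @export
make_toy_dimer <- function(spec, id = "toy") {
  set.seed(spec$seed)
  nb <- spec$interface_length
  na <- nb + 2L * spec$flank
  if (na < 1L || nb < 1L) stop("infeasible geometry request")
  seq_a <- sample(AA1, na, replace = TRUE)
  seq_b <- sample(AA1, nb, replace = TRUE)
  dz <- 5.0
  # the two chains deliberately differ in residue spacing, pleat amplitude
  # and curvature so the interface has no chain-swap pseudo-symmetry and the
  # correct chain pairing is uniquely optimal
  rows <- vector("list", na + nb)
  for (i in seq_len(na)) {
    rows[[i]] <- residue_atoms(i, unname(AA3[seq_a[i]]), "A",
                               x0 = 3.8 * (i - 1),
                               y0 = 0.35 * (-1)^i, z0 = 0,
                               s = (-1)^i, zdir = +1)
  }
  cb <- (nb + 1) / 2
  for (j in seq_len(nb)) {
    # antiparallel, laterally aligned with the central nb residues of A
    xj <- 3.8 * (spec$flank + nb - 1) - 3.7 * (j - 1)
    rows[[na + j]] <- residue_atoms(j, unname(AA3[seq_b[j]]), "B",
                                    x0 = xj,
                                    y0 = 0.55 * (-1)^j + 0.02 * (j - cb)^2,
                                    z0 = dz,
                                    s = (-1)^j, zdir = -1)
  }
  atoms <- do.call(rbind, rows)
  # small seeded jitter so different seeds give distinct coordinates
  # without disturbing the designed contact geometry
  jit <- matrix(rnorm(3L * nrow(atoms), sd = 0.03), ncol = 3)
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] + jit
  complex_structure(id, atoms, c("A", "B"))
}

#' Default per-position amino-acid distribution
#'
#' Each interface position draws a consensus residue and tolerates other
#' residues in proportion to their substitution-matrix similarity to it:
#' `pi(p, a) propto exp(lambda * M(a, consensus_p))`. This gives every
#' residue positive probability (so log pi is finite) while concentrating
#' mass on chemically compatible residues, mimicking the tolerance patterns
#' of real binding interfaces.
#'
#' @param n_positions number of interface positions.
#' @param lambda concentration; larger values concentrate the distribution.
#' @param seed RNG seed.
#' @param substitution substitution matrix name.
#' @return `n_positions` x 20 matrix of probabilities (rows sum to 1) with
#'   the consensus residues as attribute `consensus`.
#' @export
make_position_distribution <- function(n_positions, lambda = 0.5, seed = 1L,
                                       substitution = "BLOSUM62") {
  set.seed(seed)
  M <- substitution_matrix(substitution)
  consensus <- sample(AA1, n_positions, replace = TRUE)
  pi <- t(vapply(consensus, function(a) {
    w <- exp(lambda * M[, a])
    w / sum(w)
  }, numeric(20)))
  dimnames(pi) <- list(NULL, AA1)
  attr(pi, "consensus") <- consensus
  pi
}

# Random proper rotation from a random unit quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

#' Generate a family of perturbed templates with known sequence truth
#'
#' Each template is the base dimer with (i) Gaussian coordinate noise whose
#' sigma grades linearly from 0 to `noise_max` across the family, so
#' interface similarities span from 1 down toward the loose cutoff, (ii) a
#' random rigid motion (alignment scores are invariant to it), and (iii)
#' interface residue identities resampled from the known per-position
#' distribution `pi`. The ground-truth `pi` is attached as attribute
#' `truth`.
#'
#' @param base a [complex_structure()] (typically [make_toy_dimer()]).
#' @param spec a [fixture_spec()]; `spec$pi` may supply the distribution,
#'   otherwise the default of [make_position_distribution()] over the base
#'   interface positions is used.
#' @return Named list of `complex_structure` templates with attributes
#'   `truth` (the pi matrix) and `positions` (base interface residue table).
#' @export
make_template_family <- function(base, spec) {
  im <- extract_interface(base)
  L <- im$L_Q
  pi <- spec$pi
  if (is.null(pi)) {
    pi <- make_position_distribution(L, spec$lambda, spec$seed)
  }
  stopifnot(nrow(pi) == L)
  set.seed(spec$seed + 1L)
  n <- spec$n_templates
  sigmas <- if (n > 1L) spec$noise_max * (seq_len(n) - 1) / (n - 1) else 0
  xyz_cols <- c("x", "y", "z")
  out <- vector("list", n)
  prev_seq <- NULL
  for (k in seq_len(n)) {
    at <- base$atoms
    xyz <- as.matrix(at[, xyz_cols])
    xyz <- xyz + matrix(rnorm(length(xyz), sd = sigmas[k]), ncol = 3)
    R <- random_rotation()
    xyz <- xyz %*% R + matrix(runif(3, -20, 20), nrow(xyz), 3, byrow = TRUE)
    at[, xyz_cols] <- xyz
    if (!is.null(prev_seq) && runif(1) < spec$duplicate_rate) {
      new_aa <- prev_seq
    } else {
      new_aa <- vapply(seq_len(L), function(p)
        sample(AA1, 1L, prob = pi[p, ]), character(1))
    }
    prev_seq <- new_aa
    for (p in seq_len(L)) {
      ridx <- im$interface[p]
      at$resname[at$res_idx == ridx] <- AA3[new_aa[p]]
    }
    at$res_idx <- NULL
    out[[k]] <- complex_structure(sprintf("tmpl%03d", k), at,
                                  base$chain_ids)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  attr(out, "truth") <- pi
  attr(out, "positions") <- base$residues[im$interface, ]
  out
}

#' Generate a mutation table with replicates and injected outliers
#'
#' Rows follow the experimental mutation-table dialect (complex_id, chain,
#' mutations, ddg_exp, temperature). True ddG values are a linear function
#' of the sequence features (given weights) plus Gaussian noise; a fraction
#' of rows receive replicate measurements and some replicate groups one
#' strongly high outlier, exercising the curation rules. The record-level
#' truth is attached as attribute `truth`.
#'
#' @param spec a [fixture_spec()].
#' @param weights named weights over sequence features (subset of
#'   d_hydrophobic, d_aromatic, d_charged, d_acceptors, d_donors, d_volume).
#' @param sigma measurement noise sd (kcal/mol).
#' @param n_complexes number of distinct complex ids used.
#' @return Data frame of raw rows with attribute `truth` (data frame:
#'   record_id, ddg_true).
#' @export
make_mutation_table <- function(spec,
                                weights = c(d_hydrophobic = 0.8,
                                            d_charged = -0.5,
                                            d_volume = 0.01),
                                sigma = 0.1, n_complexes = 5L) {
  set.seed(spec$seed + 2L)
  n <- spec$n_mutations
  rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    k <- 1L + sample.int(3L, 1L, prob = c(0.8, 0.15, 0.05)) - 1L
    pos <- sample(5:60, k)
    wt <- sample(AA1, k, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(AA1, w), 1L), character(1))
    muts <- paste0(wt, pos, mut, collapse = ";")
    cid <- sprintf("cpx%02d", sample.int(n_complexes, 1L))
    feats <- c(pharmacophore_deltas(wt, mut),
               d_volume = volume_delta(wt, mut))
    ddg_true <- sum(weights * feats[names(weights)])
    rid <- paste(cid, "A", canonical_mutations(muts), sep = "|")
    n_rep <- if (runif(1) < spec$replicate_rate) sample(2:3, 1L) else 1L
    vals <- ddg_true + rnorm(n_rep, sd = sigma)
    if (n_rep > 1L && runif(1) < spec$outlier_rate) {
      vals <- c(vals, ddg_true + 3 + runif(1))
    }
    for (v in vals) {
      rows[[length(rows) + 1L]] <- data.frame(
        complex_id = cid, chain = "A", mutations = muts, ddg_exp = v,
        temperature = 298, stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(record_id = rid, ddg_true = ddg_true,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  tr <- unique(do.call(rbind, truth))
  attr(out, "truth") <- tr
  out
}

#' Generate a synthetic feature table with linear ground truth
#'
#' Features are standard normal; the target is a linear combination of the
#' first `length(weights)` features plus an optional protein-specific
#' intercept (clustering records into complexes) and Gaussian noise. Used to
#' probe what the cross-validation machinery can and cannot recover.
#'
#' @param n rows.
#' @param weights coefficients of the informative features.
#' @param sigma residual noise sd.
#' @param n_features total feature count (extra ones are pure noise).
#' @param n_proteins number of complex ids.
#' @param protein_sd sd of protein-specific intercepts (0 = none).
#' @param seed RNG seed.
#' @return Data frame: complex_id, feature_01..feature_p, ddg_exp; true
#'   coefficients as attribute `truth`.
#' @export
make_synthetic_feature_table <- function(n, weights = c(2, -1), sigma = 0.1,
                                         n_features = 6L, n_proteins = 12L,
                                         protein_sd = 0, seed = 1L) {
  stopifnot(n_features >= length(weights))
  set.seed(seed)
  x <- matrix(rnorm(n * n_features), n, n_features)
  colnames(x) <- sprintf("feature_%02d", seq_len(n_features))
  prot <- sample(sprintf("cpx%02d", seq_len(n_proteins)), n, replace = TRUE)
  intercepts <- setNames(rnorm(n_proteins, sd = protein_sd),
                         sprintf("cpx%02d", seq_len(n_proteins)))
  y <- drop(x[, seq_along(weights), drop = FALSE] %*% weights) +
    intercepts[prot] + rnorm(n, sd = sigma)
  out <- data.frame(complex_id = prot, x, ddg_exp = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(weights = weights, sigma = sigma,
                             protein_sd = protein_sd)
  out
}
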