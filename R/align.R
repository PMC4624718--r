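# Interface structural alignment and the iTM-score / Iscore / PCscore
# similarity metrics.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via SVD of the covariance matrix with the usual
#' determinant correction.
#'
#' @param coords_a,coords_b N x 3 matrices of paired coordinates (Angstrom).
#' @return List with `R` (3 x 3 proper rotation), `t` (translation) such that
#'   `coords_a %*% R + t` best fits `coords_b`, and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 paired points")
  stopifnot(nrow(coords_b) == n, ncol(coords_a) == 3L, ncol(coords_b) == 3L)
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    warning("nearly collinear coordinates; superposition may be ill-defined")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tvec <- cb - drop(ca %*% R)
  fit <- sweep(A %*% R, 2, -cb)
  rmsd <- sqrt(mean(rowSums((fit - coords_b)^2)))
  list(R = R, t = tvec, rmsd = rmsd)
}

#' Length-dependent distance scale d0 for interface TM-type scores
#'
#' The TM-score scaling `1.24 (L - 15)^(1/3) - 1.8`, floored at `d0_min` so
#' the scale stays positive for short interfaces.
#'
#' @param L_Q interface length (residue count of the query interface).
#' @param d0_min floor value in Angstrom.
#' @return d0 in Angstrom.
#' @export
d0 <- function(L_Q, d0_min = 0.5) {
  stopifnot(all(L_Q >= 1))
  raw <- ifelse(L_Q > 15, 1.24 * (L_Q - 15)^(1 / 3) - 1.8, d0_min)
  pmax(d0_min, raw)
}

#' Interface TM-score from an alignment
#'
#' `iTM = (1 / L_Q) * sum_i 1 / (1 + d_i^2 / d0^2)` over aligned residue
#' pairs, normalized by the query interface length.
#'
#' @param d per-pair Calpha distances (Angstrom) under the optimal
#'   superposition.
#' @param L_Q query interface length.
#' @param d0_val distance scale; defaults to [d0()] of `L_Q`.
#' @return Score in (0, 1].
#' @export
itm_score <- function(d, L_Q, d0_val = d0(L_Q)) {
  if (L_Q < 1) stop("L_Q must be positive")
  sum(1 / (1 + (d / d0_val)^2)) / L_Q
}

#' Contact-weighted interface score
#'
#' `Iscore = (1 / L_Q) * sum_i f_i / (1 + d_i^2 / d0^2)` where `f_i` is the
#' per-pair fraction of conserved cross-chain contacts. Term-wise bounded by
#' the iTM-score since `f_i <= 1`.
#'
#' @inheritParams itm_score
#' @param f per-pair contact-overlap fractions in [0, 1].
#' @return Score in [0, 1].
#' @export
i_score <- function(d, f, L_Q, d0_val = d0(L_Q)) {
  if (L_Q < 1) stop("L_Q must be positive")
  sum(f / (1 + (d / d0_val)^2)) / L_Q
}

#' Physicochemistry-weighted interface score
#'
#' `PCscore = (f_c / L_Q) * sum_i 1 / (1 + 0.25 (1 - I_i) + d_i^2 / 4^2)`,
#' with a fixed distance scale of 4 Angstrom, `I_i = 1` when the aligned
#' residues share a physicochemical class (see [chemical_class()]) and `f_c`
#' the ratio of common contacts between the two aligned interfaces.
#'
#' @inheritParams itm_score
#' @param I per-pair chemical-match indicators (0/1).
#' @param f_c common-contact ratio in [0, 1].
#' @return Score in [0, 1].
#' @export
pc_score <- function(d, I, L_Q, f_c) {
  if (L_Q < 1) stop("L_Q must be positive")
  f_c / L_Q * sum(1 / (1 + 0.25 * (1 - I) + d^2 / 16))
}

#' Per-pair contact overlap fraction
#'
#' For aligned residue pair i, `f_i = (c_i / a_i + c_i / b_i) / 2` where
#' `a_i` and `b_i` are the cross-chain contact counts of the template and
#' query residues and `c_i` the number of contacts preserved under the
#' alignment (a contact is preserved when both partners are aligned to
#' residues that are also in contact). `f_i = 0` when either count is zero.
#'
#' @param map named integer vector mapping query res_idx -> template res_idx
#'   for all aligned pairs.
#' @param query_contacts,template_contacts two-column matrices of contacting
#'   res_idx pairs.
#' @return Numeric vector of f_i, one per entry of `map`, with attribute
#'   `overlapped_total` (the total number of preserved query contacts).
#' @export
contact_overlap <- function(map, query_contacts, template_contacts) {
  qkeys <- c(paste(query_contacts[, 1], query_contacts[, 2]),
             paste(query_contacts[, 2], query_contacts[, 1]))
  tkeys <- c(paste(template_contacts[, 1], template_contacts[, 2]),
             paste(template_contacts[, 2], template_contacts[, 1]))
  q_res <- as.integer(names(map))
  # adjacency of each query/template residue
  f <- numeric(length(map))
  total_overlap <- 0L
  qc_all <- rbind(query_contacts, query_contacts[, 2:1, drop = FALSE])
  for (k in seq_along(map)) {
    qr <- q_res[k]; tr <- map[[k]]
    partners_q <- qc_all[qc_all[, 1] == qr, 2]
    b <- length(partners_q)
    a <- sum(template_contacts == tr)
    if (a == 0L || b == 0L) { f[k] <- 0; next }
    mapped <- map[as.character(partners_q)]
    cnt <- sum(!is.na(mapped) & paste(tr, mapped) %in% tkeys)
    f[k] <- (cnt / a + cnt / b) / 2
    total_overlap <- total_overlap + cnt
  }
  # each preserved contact was seen from both ends
  attr(f, "overlapped_total") <- total_overlap / 2
  f
}

# Gapless threading seed offsets for aligning two lists of lengths n and m:
# start-aligned, end-aligned, centred.
seed_offsets <- function(n, m) {
  unique(c(0L, m - n, as.integer(round((m - n) / 2))))
}

# Build the correspondence implied by threading offset o (query position i
# maps to template position i + o), truncated to valid range.
thread_pairs <- function(n, m, o) {
  i <- seq_len(n)
  j <- i + o
  ok <- j >= 1L & j <= m
  cbind(i[ok], j[ok])
}

#' Align two binding interfaces and score their similarity
#'
#' Heuristic search for the residue correspondence between two interfaces:
#' gapless threading seeds in both chain pairings, then iterated
#' {superpose on current pairs; rebuild pairs by dynamic programming on
#' `S(i,j) = 1 / (1 + d_ij^2 / d0^2)` with zero gap penalty} until the pair
#' set is stable (at most `max_iter` rounds). Correspondences are
#' order-preserving within each chain pairing. The alignment maximizing the
#' requested metric is returned, ties broken by smaller RMSD.
#'
#' @param query,template `interface_model` objects (see
#'   [extract_interface()]).
#' @param metric which similarity score to maximize ("iscore", "itm",
#'   "pcscore").
#' @param max_iter maximum refinement iterations per seed.
#' @param f_c_mode normalization of the common-contact ratio: "query" (total
#'   preserved contacts over the query's interface contacts).
#' @return Object of class `similarity_report`: `itm`, `iscore`, `pcscore`,
#'   and `alignment` (pairs in res_idx and query-interface positions, d_i,
#'   f_i, I_i, N_a, rmsd, rotation/translation, chain pairing). If no
#'   correspondence with at least 3 pairs exists, all scores are 0 and the
#'   alignment is empty.
#' @export
align_interfaces <- function(query, template,
                             metric = c("iscore", "itm", "pcscore"),
                             max_iter = 20L, f_c_mode = "query") {
  metric <- match.arg(metric)
  qch <- query$complex$chain_ids
  tch <- template$complex$chain_ids
  qd <- lapply(qch, function(ch) interface_chain_data(query, ch))
  L_Q <- query$L_Q
  d0q <- d0(L_Q)
  best <- NULL
  for (perm in list(c(1L, 2L), c(2L, 1L))) {
    td <- lapply(tch[perm], function(ch) interface_chain_data(template, ch))
    n1 <- length(qd[[1]]$res_idx); m1 <- length(td[[1]]$res_idx)
    n2 <- length(qd[[2]]$res_idx); m2 <- length(td[[2]]$res_idx)
    if (m1 == 0L || m2 == 0L) next
    for (o1 in seed_offsets(n1, m1)) {
      for (o2 in seed_offsets(n2, m2)) {
        pr <- list(thread_pairs(n1, m1, o1), thread_pairs(n2, m2, o2))
        for (iter in seq_len(max_iter)) {
          npair <- nrow(pr[[1]]) + nrow(pr[[2]])
          if (npair < 3L) break
          qca <- rbind(qd[[1]]$ca[pr[[1]][, 1], , drop = FALSE],
                       qd[[2]]$ca[pr[[2]][, 1], , drop = FALSE])
          tca <- rbind(td[[1]]$ca[pr[[1]][, 2], , drop = FALSE],
                       td[[2]]$ca[pr[[2]][, 2], , drop = FALSE])
          fit <- kabsch_superpose(qca, tca)
          new_pr <- vector("list", 2L)
          for (cp in 1:2) {
            qx <- sweep(qd[[cp]]$ca %*% fit$R, 2, -fit$t)
            tx <- td[[cp]]$ca
            d2 <- outer(rowSums(qx^2), rowSums(tx^2), "+") -
              2 * tcrossprod(qx, tx)
            d2[d2 < 0] <- 0
            S <- 1 / (1 + d2 / d0q^2)
            new_pr[[cp]] <- .nw_gapless(S)
          }
          if (identical(new_pr, pr)) { pr <- new_pr; break }
          pr <- new_pr
        }
        cand <- score_alignment(query, template, qd, td, perm, pr, d0q,
                                f_c_mode)
        if (is.null(cand)) next
        if (is.null(best) ||
            cand[[metric]] > best[[metric]] + 1e-12 ||
            (abs(cand[[metric]] - best[[metric]]) <= 1e-12 &&
             cand$alignment$rmsd < best$alignment$rmsd)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    best <- structure(list(itm = 0, iscore = 0, pcscore = 0,
                           alignment = NULL), class = "similarity_report")
  }
  best
}

# Evaluate all three metrics for a converged pair set.
score_alignment <- function(query, template, qd, td, perm, pr, d0q,
                            f_c_mode) {
  n_a <- nrow(pr[[1]]) + nrow(pr[[2]])
  if (n_a < 3L) return(NULL)
  q_res <- c(qd[[1]]$res_idx[pr[[1]][, 1]], qd[[2]]$res_idx[pr[[2]][, 1]])
  t_res <- c(td[[1]]$res_idx[pr[[1]][, 2]], td[[2]]$res_idx[pr[[2]][, 2]])
  qca <- rbind(qd[[1]]$ca[pr[[1]][, 1], , drop = FALSE],
               qd[[2]]$ca[pr[[2]][, 1], , drop = FALSE])
  tca <- rbind(td[[1]]$ca[pr[[1]][, 2], , drop = FALSE],
               td[[2]]$ca[pr[[2]][, 2], , drop = FALSE])
  fit <- kabsch_superpose(qca, tca)
  qfit <- sweep(qca %*% fit$R, 2, -fit$t)
  d <- unname(sqrt(rowSums((qfit - tca)^2)))
  map <- setNames(t_res, q_res)
  f <- contact_overlap(map, query$contacts, template$contacts)
  q_aa <- query$complex$residues$aa[q_res]
  t_aa <- template$complex$residues$aa[t_res]
  I <- as.integer(chemical_class(q_aa) == chemical_class(t_aa))
  n_qc <- nrow(query$contacts)
  f_c <- if (n_qc > 0) attr(f, "overlapped_total") / n_qc else 0
  L_Q <- query$L_Q
  aln <- list(q_res = q_res, t_res = t_res,
              q_pos = match(q_res, query$interface),
              d = d, f = as.numeric(f), I = I, N_a = n_a,
              rmsd = fit$rmsd, R = fit$R, t = fit$t, f_c = f_c,
              chain_pairing = perm)
  structure(list(itm = itm_score(d, L_Q),
                 iscore = i_score(d, as.numeric(f), L_Q),
                 pcscore = pc_score(d, I, L_Q, f_c),
                 alignment = aln),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "similarity_report: iTM = %.4f, Iscore = %.4f, PCscore = %.4f, N_a = %d\n",
    x$itm, x$iscore, x$pcscore,
    if (is.null(x$alignment)) 0L else x$alignment$N_a))
  invisible(x)
}
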