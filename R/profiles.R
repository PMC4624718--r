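# Interface profiles: template collection, Henikoff-weighted BLOSUM-mixed
# position-specific scores, the adaptive strict/loose profile, and
# profile-quality features.

#' Collect template hits for a query interface
#'
#' Aligns every library entry to the query interface, keeps hits whose
#' similarity (under the chosen metric) reaches the cutoff, projects each
#' hit's aligned residues onto the query interface positions, removes hits
#' with exactly redundant aligned interface sequences, and sorts by
#' descending similarity (ties by template id).
#'
#' @param query an `interface_model` for the query complex.
#' @param library named list of `interface_model` (or `complex_structure`)
#'   objects.
#' @param metric similarity metric ("iscore", "itm", "pcscore").
#' @param cutoff minimum similarity to retain a hit.
#' @param ... passed to [align_interfaces()].
#' @return List of template hits; each hit has `id`, `similarity`, `report`,
#'   and per-query-position vectors `aligned_seq` (one-letter code or NA),
#'   `d` (Calpha distance, Angstrom) and `f` (contact overlap). The query
#'   position table is attached as attribute `positions`.
#' @export
collect_templates <- function(query, library, metric = "iscore",
                              cutoff = 0.19, ...) {
  L <- query$L_Q
  pos <- query$complex$residues[query$interface,
                                c("chain", "resno", "ins", "aa")]
  hits <- list()
  ids <- names(library)
  if (is.null(ids)) ids <- sprintf("template%03d", seq_along(library))
  for (k in seq_along(library)) {
    tmpl <- library[[k]]
    if (inherits(tmpl, "complex_structure")) tmpl <- extract_interface(tmpl)
    rep <- align_interfaces(query, tmpl, metric = metric, ...)
    sim <- rep[[metric]]
    if (sim < cutoff || is.null(rep$alignment)) next
    aligned_seq <- rep(NA_character_, L)
    dvec <- rep(NA_real_, L)
    fvec <- rep(NA_real_, L)
    al <- rep$alignment
    aligned_seq[al$q_pos] <- tmpl$complex$residues$aa[al$t_res]
    dvec[al$q_pos] <- al$d
    fvec[al$q_pos] <- al$f
    hits[[length(hits) + 1L]] <- list(id = ids[k], similarity = sim,
                                      report = rep,
                                      aligned_seq = aligned_seq,
                                      d = dvec, f = fvec)
  }
  if (length(hits) == 0L) {
    return(structure(list(), positions = pos))
  }
  sims <- vapply(hits, `[[`, numeric(1), "similarity")
  hid <- vapply(hits, `[[`, character(1), "id")
  hits <- hits[order(-sims, hid)]
  seqs <- vapply(hits, function(h)
    paste(ifelse(is.na(h$aligned_seq), "-", h$aligned_seq), collapse = ""),
    character(1))
  hits <- hits[!duplicated(seqs)]
  structure(hits, positions = pos)
}

#' Position-based Henikoff sequence weights
#'
#' In each alignment column with `r` distinct residue types, a sequence
#' showing a type shared by `s` sequences receives `1 / (r * s)`; gaps
#' contribute nothing. Raw weights are summed over columns and normalized to
#' sum 1, down-weighting redundant sequences.
#'
#' @param msa character matrix (sequences x positions) of one-letter codes;
#'   gaps as NA or "-".
#' @return Numeric vector of normalized weights, one per sequence.
#' @export
henikoff_weights <- function(msa) {
  msa <- as.matrix(msa)
  n <- nrow(msa)
  if (n == 0L) stop("empty alignment")
  msa[is.na(msa)] <- "-"
  w <- numeric(n)
  for (p in seq_len(ncol(msa))) {
    col <- msa[, p]
    obs <- col != "-"
    if (!any(obs)) next
    tab <- table(col[obs])
    r <- length(tab)
    w[obs] <- w[obs] + 1 / (r * as.numeric(tab[col[obs]]))
  }
  if (sum(w) == 0) return(rep(1 / n, n))
  w / sum(w)
}

#' Build a position-specific interface profile
#'
#' Henikoff-weighted amino-acid frequencies `g(p, a)` are computed per query
#' interface position over the non-gap aligned template residues, then mixed
#' through a substitution matrix: `F(p, A) = sum_a g(p, a) M(A, a)`. The
#' BLOSUM mixing compensates for sparse template coverage.
#'
#' @param hits template hits from [collect_templates()].
#' @param substitution substitution matrix name (see
#'   [substitution_matrix()]).
#' @return Object of class `interface_profile`: `g` and `F` (positions x 20
#'   matrices), `n_seq` (per-position non-gap sequence counts), `positions`,
#'   and the matrix name.
#' @export
build_profile <- function(hits, substitution = "BLOSUM62") {
  if (length(hits) == 0L) stop("no template hits to build a profile from")
  msa <- do.call(rbind, lapply(hits, `[[`, "aligned_seq"))
  if (all(is.na(msa))) stop("all-gap profile")
  L <- ncol(msa)
  w <- henikoff_weights(msa)
  g <- matrix(0, L, 20, dimnames = list(NULL, AA1))
  n_seq <- integer(L)
  for (p in seq_len(L)) {
    obs <- !is.na(msa[, p])
    n_seq[p] <- sum(obs)
    if (n_seq[p] == 0L) next
    wp <- tapply(w[obs], factor(msa[obs, p], levels = AA1), sum)
    wp[is.na(wp)] <- 0
    tot <- sum(wp)
    if (tot > 0) g[p, ] <- wp / tot
  }
  M <- substitution_matrix(substitution)
  Fm <- g %*% M   # symmetric M: F(p, A) = sum_a g(p, a) M(A, a)
  colnames(Fm) <- AA1
  structure(list(positions = attr(hits, "positions"), g = g, F = Fm,
                 n_seq = n_seq, substitution = substitution,
                 n_templates = length(hits)),
            class = "interface_profile")
}

#' @export
print.interface_profile <- function(x, ...) {
  cat("interface_profile: ", nrow(x$g), " positions, ",
      x$n_templates, " templates (", x$substitution, " mixing), median ",
      "n_seq = ", median(x$n_seq), "\n", sep = "")
  invisible(x)
}

#' Mutant profile score (predicted ddG contribution)
#'
#' The difference between the profile scores of the wild-type and mutant
#' amino acids at the mutated interface position(s):
#' `sum_p [F(p, A_WT) - F(p, A_Mut)]`. Strictly additive over sites. At
#' positions with no aligned sequences the profile is uninformative and the
#' score falls back to the raw substitution-matrix difference
#' `M(WT, WT) - M(WT, Mut)`.
#'
#' @param profile an `interface_profile`.
#' @param site integer vector of interface position indices (rows of the
#'   profile).
#' @param wt,mut one-letter codes of the wild-type and mutant residues, one
#'   per site.
#' @return Numeric scalar score (higher = mutation less compatible with the
#'   interface ensemble; proportional to destabilization).
#' @export
mutant_profile_score <- function(profile, site, wt, mut) {
  stopifnot(length(site) == length(wt), length(wt) == length(mut))
  if (any(site < 1L | site > nrow(profile$F))) {
    stop("site not in interface: ",
         paste(site[site < 1L | site > nrow(profile$F)], collapse = ", "))
  }
  wt <- toupper(wt); mut <- toupper(mut)
  if (!all(c(wt, mut) %in% AA1)) stop("nonstandard amino acid code")
  M <- substitution_matrix(profile$substitution)
  total <- 0
  for (k in seq_along(site)) {
    p <- site[k]
    if (profile$n_seq[p] > 0L) {
      total <- total + profile$F[p, wt[k]] - profile$F[p, mut[k]]
    } else {
      total <- total + M[wt[k], wt[k]] - M[wt[k], mut[k]]
    }
  }
  unname(total)
}

#' Select templates for an adaptive profile
#'
#' All hits at or above the strict cutoff are taken; up to `n` further hits
#' with similarity in [loose, strict) are added in descending-similarity
#' order.
#'
#' @param similarities numeric vector of hit similarities sorted descending.
#' @param strict,loose similarity cutoffs, `strict > loose`.
#' @param n maximum number of sub-strict sequences added.
#' @return Integer indices of the selected hits.
#' @export
adaptive_select <- function(similarities, strict = 0.25, loose = 0.19,
                            n = 80L) {
  stopifnot(strict > loose, n >= 0)
  if (is.unsorted(rev(similarities))) {
    stop("similarities must be sorted in descending order")
  }
  keep_strict <- which(similarities >= strict)
  mid <- which(similarities >= loose & similarities < strict)
  sort(c(keep_strict, head(mid, n)))
}

#' Build the adaptive interface profile
#'
#' @param hits template hits sorted by descending similarity (as returned by
#'   [collect_templates()]).
#' @inheritParams adaptive_select
#' @param substitution substitution matrix name.
#' @return An `interface_profile` built from the adaptive template set.
#' @export
adaptive_profile <- function(hits, strict = 0.25, loose = 0.19, n = 80L,
                             substitution = "BLOSUM62") {
  sims <- vapply(hits, `[[`, numeric(1), "similarity")
  if (length(sims) == 0L || max(sims) < loose) stop("no usable templates")
  sel <- adaptive_select(sims, strict, loose, n)
  sub <- hits[sel]
  attr(sub, "positions") <- attr(hits, "positions")
  build_profile(sub, substitution)
}

#' Jensen-Shannon divergence between two distributions
#'
#' Symmetric 0.5/0.5 mixture, log base 2, so the value lies in [0, 1] bits.
#'
#' @param p,q probability vectors over the same support.
#' @return Divergence in bits.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Profile-quality features at a mutation site
#'
#' Five measures of how trustworthy the profile is at one interface
#' position: the mean alignment distance (RMSD proxy) at the site, the mean
#' fraction of preserved contacts, the number of aligned sequences, the
#' Jensen-Shannon divergence of the site's amino-acid distribution from the
#' background distribution, and its Z-score across interface sites (0 when
#' the across-site spread is zero). Sites no template aligns receive
#' sentinel values (distance 10 Angstrom, contacts 0, JS 0, Z 0) so feature
#' vectors stay finite.
#'
#' @param hits template hits used to build `profile`.
#' @param profile the `interface_profile`.
#' @param site interface position index.
#' @param background background amino-acid distribution (default BLOSUM62
#'   marginal frequencies).
#' @return Named numeric vector: mean_rmsd_at_site, mean_preserved_contacts,
#'   n_seq_at_site, js_divergence, js_zscore.
#' @export
profile_quality_features <- function(hits, profile, site,
                                     background = BG_FREQ) {
  stopifnot(site >= 1L, site <= nrow(profile$g))
  ds <- vapply(hits, function(h) h$d[site], numeric(1))
  fs <- vapply(hits, function(h) h$f[site], numeric(1))
  covered <- !is.na(ds)
  js_all <- vapply(seq_len(nrow(profile$g)), function(p) {
    if (profile$n_seq[p] == 0L) return(NA_real_)
    js_divergence(profile$g[p, ], background)
  }, numeric(1))
  js_site <- if (profile$n_seq[site] > 0L) js_all[site] else 0
  mu <- mean(js_all, na.rm = TRUE)
  sg <- sd(js_all, na.rm = TRUE)
  z <- if (is.na(sg) || sg == 0 || profile$n_seq[site] == 0L) 0 else
    (js_site - mu) / sg
  c(mean_rmsd_at_site = if (any(covered)) mean(ds[covered]) else 10,
    mean_preserved_contacts = if (any(covered)) mean(fs[covered]) else 0,
    n_seq_at_site = sum(covered),
    js_divergence = js_site,
    js_zscore = z)
}

#' Assemble the 13 profile-derived model features for a mutation
#'
#' Three mutant profile scores (strict-cutoff, loose-cutoff and adaptive
#' profiles) plus the five quality features of [profile_quality_features()]
#' for the strict and loose profiles. Multi-site mutations sum the scores
#' (they are strictly additive) and average the quality features over sites.
#' When no hit reaches the strict cutoff the strict-profile score falls back
#' to the substitution-matrix difference and its quality features take the
#' uncovered-site sentinels.
#'
#' @param hits hits from [collect_templates()] at the loose cutoff, sorted
#'   descending.
#' @param site,wt,mut mutation site index(es) and residues as in
#'   [mutant_profile_score()].
#' @param strict,loose,n_add adaptive-profile parameters.
#' @param substitution substitution matrix name.
#' @param background background distribution for the JS features.
#' @return Named numeric vector of the 13 features.
#' @export
profile_feature_set <- function(hits, site, wt, mut, strict = 0.25,
                                loose = 0.19, n_add = 80L,
                                substitution = "BLOSUM62",
                                background = BG_FREQ) {
  sims <- vapply(hits, `[[`, numeric(1), "similarity")
  M <- substitution_matrix(substitution)
  blosum_fallback <- sum(M[cbind(wt, wt)] - M[cbind(wt, mut)])
  subset_hits <- function(keep) {
    h <- hits[keep]
    attr(h, "positions") <- attr(hits, "positions")
    h
  }
  level <- function(h) {
    if (length(h) == 0L) {
      return(list(score = blosum_fallback,
                  quality = c(mean_rmsd_at_site = 10,
                              mean_preserved_contacts = 0,
                              n_seq_at_site = 0, js_divergence = 0,
                              js_zscore = 0)))
    }
    prof <- build_profile(h, substitution)
    q <- sapply(site, function(p)
      profile_quality_features(h, prof, p, background))
    list(score = mutant_profile_score(prof, site, wt, mut),
         quality = rowMeans(q))
  }
  hi <- level(subset_hits(sims >= strict))
  lo <- level(subset_hits(sims >= loose))
  ad <- if (length(hits) > 0L && max(sims) >= loose) {
    prof <- adaptive_profile(hits, strict, loose, n_add, substitution)
    mutant_profile_score(prof, site, wt, mut)
  } else blosum_fallback
  out <- c(score_high = hi$score, score_low = lo$score, score_adaptive = ad,
           setNames(hi$quality, paste0(names(hi$quality), "_high")),
           setNames(lo$quality, paste0(names(lo$quality), "_low")))
  out
}

#' Write an interface profile to a tab-separated file
#'
#' One row per interface position (chain + author number) with the 20
#' profile-score columns `F(p, A)` and the per-position aligned-sequence
#' count.
#'
#' @param profile an `interface_profile`.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
write_profile <- function(profile, file) {
  pos <- profile$positions
  df <- data.frame(chain = pos$chain, resno = pos$resno, aa = pos$aa,
                   n_seq = profile$n_seq,
                   round(profile$F, 6), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an interface profile written by [write_profile()]
#'
#' @param file path to a profile TSV.
#' @param substitution matrix name recorded with the profile scores.
#' @return An `interface_profile` (score matrix and counts; weighted
#'   frequencies are not stored in the file).
#' @export
read_profile <- function(file, substitution = "BLOSUM62") {
  df <- read.delim(file, check.names = FALSE)
  Fm <- as.matrix(df[, AA1])
  structure(list(positions = df[, c("chain", "resno", "aa")], g = NULL,
                 F = Fm, n_seq = df$n_seq, substitution = substitution,
                 n_templates = NA_integer_),
            class = "interface_profile")
}
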