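# Mutation-table curation, dataset splitting, and the non-redundant dimeric
# template library.

canonical_mutations <- function(x) {
  vapply(x, function(s) {
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    paste(sort(toks[nzchar(toks)]), collapse = ";")
  }, character(1))
}

#' Curate a raw mutation table
#'
#' Keeps only entries whose substitutions all lie on one chain, groups
#' identical (complex, chain, mutation-set) entries, and within each
#' replicate group discards measurements lying more than one standard
#' deviation above the group mean (the outlier rule is deliberately
#' one-sided) before averaging the remainder.
#'
#' @param raw data frame with columns complex_id, chain, mutations, ddg_exp
#'   (and optionally temperature); see [read_mutation_table()].
#' @return Data frame of curated records (one per unique mutation set) with
#'   the averaged ddg_exp and an `n_replicates` column. The indices of the
#'   raw rows merged into each record are attached as attribute
#'   `provenance`; excluded two-sided rows as attribute `excluded`.
#' @export
curate_mutations <- function(raw) {
  stopifnot(all(c("complex_id", "chain", "mutations", "ddg_exp") %in%
                  names(raw)))
  for (i in seq_len(nrow(raw))) {
    ok <- tryCatch({ parse_mutations(raw$mutations[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("row ", i, ": ", ok)
  }
  one_sided <- !grepl("[,;]", trimws(raw$chain))
  excluded <- which(!one_sided)
  df <- raw[one_sided, , drop = FALSE]
  raw_idx <- which(one_sided)
  key <- paste(df$complex_id, trimws(df$chain),
               canonical_mutations(df$mutations), sep = "|")
  groups <- split(seq_len(nrow(df)), key)
  recs <- lapply(groups, function(g) {
    vals <- df$ddg_exp[g]
    keep <- g
    if (length(vals) > 1L && !anyNA(vals)) {
      m <- mean(vals); s <- sd(vals)
      keep <- g[vals <= m + s]
      vals <- df$ddg_exp[keep]
    }
    list(row = data.frame(complex_id = df$complex_id[g[1]],
                          chain = trimws(df$chain[g[1]]),
                          mutations = canonical_mutations(df$mutations[g[1]]),
                          ddg_exp = mean(vals),
                          temperature = if (is.null(df$temperature))
                            NA_real_ else df$temperature[g[1]],
                          n_replicates = length(g),
                          stringsAsFactors = FALSE),
         prov = raw_idx[keep])
  })
  out <- do.call(rbind, lapply(recs, `[[`, "row"))
  ord <- order(out$complex_id, out$chain, out$mutations)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- lapply(recs, `[[`, "prov")[ord]
  attr(out, "excluded") <- excluded
  out
}

#' Deterministic train/test/validation split
#'
#' @param n number of records (or a data frame, whose row count is used).
#' @param fractions named fractions summing to 1, e.g.
#'   `c(train = 0.6, test = 0.15, validation = 0.25)`.
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return Named list of disjoint index vectors covering `1:n`.
#' @export
split_dataset <- function(n, fractions = c(train = 0.60, test = 0.15,
                                           validation = 0.25), seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(abs(sum(fractions) - 1) < 1e-8, n >= length(fractions))
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * fractions - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  set.seed(seed)
  idx <- sample.int(n)
  out <- vector("list", length(fractions))
  names(out) <- names(fractions)
  at <- 0L
  for (k in seq_along(fractions)) {
    out[[k]] <- sort(idx[at + seq_len(sizes[k])])
    at <- at + sizes[k]
  }
  out
}

#' Split a multi-chain assembly into candidate dimers
#'
#' @param atoms heavy-atom table as in [complex_structure()] covering any
#'   number of chains.
#' @param chain_ids chains present.
#' @param id assembly identifier; dimers are named `id_XY`.
#' @return List of two-chain [complex_structure()] objects, one per chain
#'   pair.
#' @export
split_dimers <- function(atoms, chain_ids, id) {
  pairs <- utils::combn(chain_ids, 2, simplify = FALSE)
  lapply(pairs, function(p)
    complex_structure(paste0(id, "_", p[1], p[2]),
                      atoms[atoms$chain %in% p, , drop = FALSE], p))
}

#' Global sequence identity between two chains
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via Biostrings;
#' identity is the fraction of identical positions over aligned columns.
#'
#' @param s1,s2 one-letter sequences.
#' @return Identity fraction in [0, 1].
#' @export
seq_identity <- function(s1, s2) {
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(s1),
                                      Biostrings::AAString(s2),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  Biostrings::pid(al) / 100
}

# Matched residue-index pairs implied by a global sequence alignment.
aligned_index_pairs <- function(s1, s2) {
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(s1),
                                      Biostrings::AAString(s2),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  p1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  p2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  i1 <- cumsum(p1 != "-")
  i2 <- cumsum(p2 != "-")
  keep <- p1 != "-" & p2 != "-"
  cbind(i1[keep], i2[keep])
}

#' Approximate whole-complex TM-score between two dimers
#'
#' Chains are paired by best summed sequence identity, sequences aligned
#' globally per paired chain, and the matched Calpha pairs superposed with
#' iterative distance trimming; the TM-score is normalized by the shorter
#' complex. This stands in for a full multichain structural alignment and is
#' intended for the coarse redundancy test of the template library.
#'
#' @param c1,c2 two-chain [complex_structure()] objects.
#' @return List with `tm` (score) and `identity` (sequence identity of the
#'   paired, concatenated chains).
#' @export
complex_tm_score <- function(c1, c2) {
  ch1 <- c1$chain_ids; ch2 <- c2$chain_ids
  seqs1 <- lapply(ch1, function(ch) chain_sequence(c1, ch))
  seqs2 <- lapply(ch2, function(ch) chain_sequence(c2, ch))
  id_mat <- outer(1:2, 1:2, Vectorize(function(i, j)
    seq_identity(seqs1[[i]], seqs2[[j]])))
  pairings <- list(c(1L, 2L), c(2L, 1L))
  sums <- vapply(pairings, function(p) id_mat[1, p[1]] + id_mat[2, p[2]],
                 numeric(1))
  perm <- pairings[[which.max(sums)]]
  identity <- max(sums) / 2
  ca_xyz <- function(cx, ch) {
    at <- chain_atoms(cx, ch)
    as.matrix(at[at$elety == "CA", c("x", "y", "z")])
  }
  xyz1 <- NULL; xyz2 <- NULL
  for (k in 1:2) {
    pr <- aligned_index_pairs(seqs1[[k]], seqs2[[perm[k]]])
    a1 <- ca_xyz(c1, ch1[k]); a2 <- ca_xyz(c2, ch2[perm[k]])
    ok <- pr[, 1] <= nrow(a1) & pr[, 2] <= nrow(a2)
    xyz1 <- rbind(xyz1, a1[pr[ok, 1], , drop = FALSE])
    xyz2 <- rbind(xyz2, a2[pr[ok, 2], , drop = FALSE])
  }
  L <- min(nrow(c1$residues), nrow(c2$residues))
  if (is.null(xyz1) || nrow(xyz1) < 3L) return(list(tm = 0,
                                                    identity = identity))
  d0_tm <- d0(L)
  subset <- seq_len(nrow(xyz1))
  best_tm <- 0
  for (it in 1:5) {
    if (length(subset) < 3L) break
    fit <- kabsch_superpose(xyz1[subset, , drop = FALSE],
                            xyz2[subset, , drop = FALSE])
    x1 <- sweep(xyz1 %*% fit$R, 2, -fit$t)
    d <- sqrt(rowSums((x1 - xyz2)^2))
    tm <- sum(1 / (1 + (d / d0_tm)^2)) / L
    best_tm <- max(best_tm, tm)
    new_subset <- which(d < d0_tm + 1.5)
    if (length(new_subset) < 3L || identical(new_subset, subset)) break
    subset <- new_subset
  }
  list(tm = best_tm, identity = identity)
}

#' Build a non-redundant dimeric template library
#'
#' Higher-order assemblies are split into all pairwise dimers; dimers whose
#' chains do not both have at least `min_interface` interface residues are
#' removed; then, scanning in input order, a dimer is dropped if it shares at
#' least `id_threshold` sequence identity AND a complex TM-score of at least
#' `tm_threshold` with an already-kept entry (first-kept wins).
#'
#' @param complexes list of [complex_structure()] objects, or entries of the
#'   form `list(id=, atoms=, chain_ids=)` for assemblies with more than two
#'   chains.
#' @param cutoff interface depth (Angstrom).
#' @param min_interface minimum interface residues per chain.
#' @param id_threshold,tm_threshold redundancy rule thresholds (conjunctive).
#' @return List with `entries` (kept `complex_structure`s), `index` (data
#'   frame: id, chains, per-chain interface sizes) and `removed` (ids with
#'   reasons).
#' @export
build_template_library <- function(complexes, cutoff = 4.0,
                                   min_interface = 10L, id_threshold = 0.70,
                                   tm_threshold = 0.80) {
  dimers <- list()
  for (cx in complexes) {
    if (inherits(cx, "complex_structure")) {
      dimers <- c(dimers, list(cx))
    } else {
      dimers <- c(dimers, split_dimers(cx$atoms, cx$chain_ids, cx$id))
    }
  }
  kept <- list()
  index <- NULL
  removed <- character(0)
  for (cx in dimers) {
    im <- tryCatch(extract_interface(cx, cutoff = cutoff),
                   error = function(e) NULL)
    if (is.null(im)) { removed[cx$id] <- "no interface"; next }
    ch_of <- cx$residues$chain[im$interface]
    n1 <- sum(ch_of == cx$chain_ids[1])
    n2 <- sum(ch_of == cx$chain_ids[2])
    if (n1 < min_interface || n2 < min_interface) {
      removed[cx$id] <- sprintf("interface too small (%d/%d)", n1, n2)
      next
    }
    redundant <- FALSE
    for (prev in kept) {
      cmp <- complex_tm_score(cx, prev)
      if (cmp$identity >= id_threshold && cmp$tm >= tm_threshold) {
        removed[cx$id] <- paste0("redundant with ", prev$id)
        redundant <- TRUE
        break
      }
    }
    if (redundant) next
    kept <- c(kept, list(cx))
    index <- rbind(index, data.frame(id = cx$id,
                                     chains = paste(cx$chain_ids,
                                                    collapse = ""),
                                     n_iface_1 = n1, n_iface_2 = n2,
                                     stringsAsFactors = FALSE))
  }
  names(kept) <- if (is.null(index)) character(0) else index$id
  list(entries = kept, index = index, removed = removed)
}
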