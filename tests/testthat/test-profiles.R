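test_that("Henikoff weights reproduce hand-computed and oracle values", {
  # k identical sequences share weight equally
  msa <- matrix(rep(c("A", "L", "K"), each = 4), 4, 3)
  expect_equal(henikoff_weights(msa), rep(0.25, 4))
  # single column {A, A, B}: raw 1/(2*2), 1/(2*2), 1/(2*1) -> (.25, .25, .5)
  expect_equal(henikoff_weights(matrix(c("A", "A", "B"), 3, 1)),
               c(0.25, 0.25, 0.5))
  # random MSAs vs independent per-column recomputation
  set.seed(501)
  for (rep in 1:20) {
    n <- sample(2:8, 1); L <- sample(2:10, 1)
    msa <- matrix(sample(c(AA1, NA), n * L, replace = TRUE), n, L)
    if (all(is.na(msa))) next
    w <- henikoff_weights(msa)
    raw <- numeric(n)
    for (p in seq_len(L)) {
      col <- msa[, p]
      for (i in seq_len(n)) {
        if (is.na(col[i])) next
        r <- length(unique(col[!is.na(col)]))
        s <- sum(col == col[i], na.rm = TRUE)
        raw[i] <- raw[i] + 1 / (r * s)
      }
    }
    expect_equal(w, if (sum(raw) > 0) raw / sum(raw) else rep(1 / n, n),
                 tolerance = 1e-12)
  }
})

test_that("profile construction mixes frequencies through BLOSUM62", {
  M <- substitution_matrix("BLOSUM62")
  # delta distribution: a single sequence with L at a position gives the
  # BLOSUM row of L
  h1 <- fake_hits(list(rep("L", 3)))
  p1 <- build_profile(h1)
  expect_equal(p1$F[1, ], M[, "L"], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rowSums(p1$g), rep(1, 3))
  # uniform distribution: 20 sequences covering each residue once
  h20 <- fake_hits(lapply(AA1, function(a) rep(a, 2)))
  p20 <- build_profile(h20)
  expect_equal(p20$F[1, ], rowMeans(M), tolerance = 1e-12,
               ignore_attr = TRUE)
  # 3-sequence fixture vs hand-rolled double loop
  h3 <- fake_hits(list(c("A", "K", NA), c("A", "R", "W"), c("C", "K", "W")))
  p3 <- build_profile(h3)
  for (p in 1:3) {
    for (A in AA1) {
      want <- sum(p3$g[p, ] * M[A, ])
      expect_equal(p3$F[p, A], want, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  expect_equal(p3$n_seq, c(3L, 3L, 2L))
})

test_that("duplicating every hit leaves the profile unchanged", {
  h <- fake_hits(list(c("A", "K"), c("L", "K"), c("A", "W")))
  p1 <- build_profile(h)
  hd <- fake_hits(list(c("A", "K"), c("L", "K"), c("A", "W"),
                       c("A", "K"), c("L", "K"), c("A", "W")))
  p2 <- build_profile(hd)
  expect_equal(p1$g, p2$g, tolerance = 1e-12)
  expect_equal(p1$F, p2$F, tolerance = 1e-12)
})

test_that("mutant profile score is zero at identity, antisymmetric, additive", {
  h <- fake_hits(list(c("L", "K", "W"), c("L", "R", "W"), c("I", "K", "F")))
  prof <- build_profile(h)
  expect_equal(mutant_profile_score(prof, 1, "L", "L"), 0)
  s_fwd <- mutant_profile_score(prof, 1, "L", "D")
  s_rev <- mutant_profile_score(prof, 1, "D", "L")
  expect_equal(s_fwd, -s_rev, tolerance = 1e-12)
  # two-site score is exactly the sum of the single-site scores
  s1 <- mutant_profile_score(prof, 1, "L", "A")
  s2 <- mutant_profile_score(prof, 2, "K", "E")
  expect_equal(mutant_profile_score(prof, c(1, 2), c("L", "K"),
                                    c("A", "E")), s1 + s2,
               tolerance = 1e-12)
  expect_error(mutant_profile_score(prof, 9, "L", "D"), "not in interface")
})

test_that("single-sequence all-L profile reproduces published BLOSUM entries", {
  h <- fake_hits(list(rep("L", 2)))
  prof <- build_profile(h)
  # M(L,L) = 4 and M(D,L) = -4 in BLOSUM62
  expect_equal(mutant_profile_score(prof, 1, "L", "D"), 4 - (-4))
})

test_that("uncovered positions fall back to the raw substitution difference", {
  h <- fake_hits(list(c("L", NA), c("I", NA)))
  prof <- build_profile(h)
  M <- substitution_matrix("BLOSUM62")
  expect_equal(prof$n_seq[2], 0L)
  expect_equal(mutant_profile_score(prof, 2, "K", "E"),
               M["K", "K"] - M["K", "E"])
})

test_that("adaptive template selection follows the strict/loose/n rule", {
  sims <- c(0.30, 0.26, 0.24, 0.22, 0.18)
  sel <- adaptive_select(sims, strict = 0.25, loose = 0.19, n = 2)
  expect_equal(sel, 1:4)
  # all hits above strict: n is irrelevant
  expect_equal(adaptive_select(c(0.9, 0.8, 0.7), 0.25, 0.19, 0), 1:3)
  # n = 0 keeps only the strict set
  expect_equal(adaptive_select(sims, 0.25, 0.19, 0), 1:2)
  expect_error(adaptive_select(c(0.1, 0.3), 0.25, 0.19, 2), "descending")
  # set algebra on random similarity lists
  set.seed(502)
  for (rep in 1:200) {
    s <- sort(runif(sample(3:30, 1)), decreasing = TRUE)
    n <- sample(0:10, 1)
    strict_set <- which(s >= 0.25)
    loose_set <- which(s >= 0.19)
    ad <- adaptive_select(s, 0.25, 0.19, n)
    expect_true(all(strict_set %in% ad))
    expect_true(all(ad %in% loose_set))
  }
})

test_that("adaptive profile selects hits and errors without usable templates", {
  seqs <- list(c("L", "K"), c("I", "K"), c("L", "R"), c("V", "K"),
               c("L", "E"))
  h <- fake_hits(seqs, sims = c(0.30, 0.26, 0.24, 0.22, 0.18))
  prof <- adaptive_profile(h, strict = 0.25, loose = 0.19, n = 2)
  expect_equal(prof$n_templates, 4L)
  h2 <- fake_hits(seqs[1:2], sims = c(0.15, 0.10))
  expect_error(adaptive_profile(h2, 0.25, 0.19, 2), "no usable templates")
})

test_that("template collection dedupes redundant interface sequences", {
  sp <- fixture_spec(seed = 31, interface_length = 8, flank = 2,
                     n_templates = 8, noise_max = 0.3, duplicate_rate = 1)
  base <- make_toy_dimer(sp)
  im <- extract_interface(base)
  fam <- make_template_family(base, sp)
  hits <- collect_templates(im, fam, metric = "iscore", cutoff = 0.19)
  seqs <- vapply(hits, function(h)
    paste(ifelse(is.na(h$aligned_seq), "-", h$aligned_seq), collapse = ""),
    character(1))
  expect_false(any(duplicated(seqs)))
  # duplicate_rate = 1 reuses the first template's sequence throughout
  expect_lt(length(hits), length(fam))
  # impossible threshold yields an empty hit list
  none <- collect_templates(im, fam, metric = "iscore", cutoff = 1.1)
  expect_length(none, 0L)
})

test_that("an exact copy of the query is a perfect hit", {
  sp <- fixture_spec(seed = 32, interface_length = 8, flank = 2)
  base <- make_toy_dimer(sp)
  im <- extract_interface(base)
  hits <- collect_templates(im, list(copy = base), metric = "iscore",
                            cutoff = 0.5)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$similarity, 1.0, tolerance = 1e-9)
  expect_equal(hits[[1]]$aligned_seq,
               base$residues$aa[im$interface])
})

test_that("Jensen-Shannon divergence matches its closed forms and oracle", {
  bg <- ddgprof:::BG_FREQ
  expect_equal(js_divergence(bg, bg), 0)
  # disjoint supports reach the 1-bit maximum
  p <- c(1, 0, 0, 0); q <- c(0, 0, 0.5, 0.5)
  expect_equal(js_divergence(p, q), 1)
  set.seed(503)
  for (rep in 1:30) {
    a <- runif(20); a <- a / sum(a)
    b <- runif(20); b <- b / sum(b)
    expect_equal(js_divergence(a, b), oracle_js(a, b), tolerance = 1e-12)
  }
})

test_that("profile quality features report coverage, divergence and Z-score", {
  h <- fake_hits(list(c("L", "K", NA), c("L", "R", NA), c("I", "K", NA)),
                 d = list(c(0.2, 0.4, NA), c(0.6, 0.8, NA),
                          c(1.0, 1.2, NA)),
                 f = list(c(1, 0.5, NA), c(0.8, 0.7, NA), c(0.6, 0.9, NA)))
  prof <- build_profile(h)
  q1 <- profile_quality_features(h, prof, 1)
  expect_equal(q1[["mean_rmsd_at_site"]], mean(c(0.2, 0.6, 1.0)))
  expect_equal(q1[["mean_preserved_contacts"]], mean(c(1, 0.8, 0.6)))
  expect_equal(q1[["n_seq_at_site"]], 3)
  expect_equal(q1[["js_divergence"]],
               js_divergence(prof$g[1, ], ddgprof:::BG_FREQ),
               tolerance = 1e-12)
  # uncovered site takes the documented sentinels
  q3 <- profile_quality_features(h, prof, 3)
  expect_equal(q3[["mean_rmsd_at_site"]], 10)
  expect_equal(q3[["n_seq_at_site"]], 0)
  expect_equal(q3[["js_zscore"]], 0)
  # one covered site only: across-site sd is NA -> Z = 0 by convention
  h1 <- fake_hits(list("L", "I"))
  prof1 <- build_profile(h1)
  expect_equal(profile_quality_features(h1, prof1, 1)[["js_zscore"]], 0)
})

test_that("the 13-feature profile set has the documented layout", {
  sp <- fixture_spec(seed = 33, interface_length = 8, flank = 2,
                     n_templates = 20, noise_max = 1)
  base <- make_toy_dimer(sp)
  im <- extract_interface(base)
  fam <- make_template_family(base, sp)
  hits <- collect_templates(im, fam, metric = "iscore", cutoff = 0.19)
  fs <- profile_feature_set(hits, site = 3, wt = base$residues$aa[
    im$interface][3], mut = "A")
  expect_length(fs, 13L)
  expect_named(fs, c("score_high", "score_low", "score_adaptive",
                     "mean_rmsd_at_site_high",
                     "mean_preserved_contacts_high", "n_seq_at_site_high",
                     "js_divergence_high", "js_zscore_high",
                     "mean_rmsd_at_site_low", "mean_preserved_contacts_low",
                     "n_seq_at_site_low", "js_divergence_low",
                     "js_zscore_low"))
  expect_true(all(is.finite(fs)))
})

test_that("profiles survive a TSV round-trip", {
  sp <- fixture_spec(seed = 34, interface_length = 6, flank = 1,
                     n_templates = 6, noise_max = 0.5)
  base <- make_toy_dimer(sp)
  im <- extract_interface(base)
  fam <- make_template_family(base, sp)
  hits <- collect_templates(im, fam, metric = "iscore", cutoff = 0.19)
  prof <- build_profile(hits)
  f <- tempfile(fileext = ".tsv")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$F, prof$F, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(back$n_seq, prof$n_seq)
  unlink(f)
})
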