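test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(401)
  A <- matrix(rnorm(30), 10, 3)
  # identity case
  fit <- kabsch_superpose(A, A)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$R, diag(3), tolerance = 1e-9)
  # exact rigid copy
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  B <- A %*% R + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  fit2 <- kabsch_superpose(A, B)
  expect_lt(fit2$rmsd, 1e-6)
  expect_equal(fit2$R, R, tolerance = 1e-6)
  expect_equal(det(fit2$R), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches a numerical rotation-search oracle", {
  set.seed(402)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.5), 12, 3)
  fit <- kabsch_superpose(A, B)
  # oracle: minimize RMSD over Euler angles + translation by BFGS from
  # several starts, entirely independent of the SVD path
  obj <- function(par) {
    c1 <- cos(par[1]); s1 <- sin(par[1])
    c2 <- cos(par[2]); s2 <- sin(par[2])
    c3 <- cos(par[3]); s3 <- sin(par[3])
    Rx <- matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3, 3, byrow = TRUE)
    Rz <- matrix(c(c3, -s3, 0, s3, c3, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    X <- A %*% (Rx %*% Ry %*% Rz)
    X <- sweep(X, 2, par[4:6], "+")
    sqrt(mean(rowSums((X - B)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    start <- c(runif(3, -pi, pi), rnorm(3))
    o <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-4)
})

test_that("d0 scaling floors at 0.5 and grows with interface length", {
  expect_equal(d0(1), 0.5)
  expect_equal(d0(15), 0.5)
  expect_equal(d0(142), 1.24 * 127^(1 / 3) - 1.8)
  v <- d0(1:500)
  expect_true(all(diff(v) >= -1e-12))
})

test_that("score formulas match brute-force summation on random fixtures", {
  set.seed(403)
  for (rep in 1:100) {
    L <- sample(5:40, 1)
    na <- sample(3:L, 1)
    d <- runif(na, 0, 8)
    f <- runif(na)
    I <- sample(0:1, na, replace = TRUE)
    fc <- runif(1)
    d0v <- d0(L)
    expect_equal(itm_score(d, L), oracle_itm(d, L, d0v), tolerance = 1e-10)
    expect_equal(i_score(d, f, L), oracle_iscore(d, f, L, d0v),
                 tolerance = 1e-10)
    expect_equal(pc_score(d, I, L, fc), oracle_pc(d, I, L, fc),
                 tolerance = 1e-10)
    expect_lte(i_score(d, f, L), itm_score(d, L) + 1e-12)
  }
})

test_that("closed-form single-term values are reproduced", {
  # one pair at d = d0 with L_Q = 1 contributes exactly 1/2
  expect_equal(itm_score(d0(1), 1), 0.5)
  # chemistry mismatch at zero distance scores 1/(1 + 0.25) = 0.8
  expect_equal(pc_score(0, 0, 1, 1), 0.8)
  expect_equal(pc_score(0, 1, 1, 1), 1.0)
  expect_error(itm_score(numeric(0), 0), "positive")
})

test_that("contact overlap reproduces the printed formula and an oracle", {
  # a = 4 template contacts, b = 2 query contacts, c = 2 preserved
  map <- c("1" = 11L, "2" = 12L, "3" = 13L)
  qc <- rbind(c(1L, 2L), c(1L, 3L))
  tc <- rbind(c(11L, 12L), c(11L, 13L), c(11L, 14L), c(11L, 15L))
  f <- contact_overlap(map, qc, tc)
  expect_equal(f[[1]], (2 / 4 + 2 / 2) / 2)
  # identity alignment on identical contact maps gives f = 1 everywhere
  f2 <- contact_overlap(setNames(1:4, 1:4), rbind(c(1L, 3L), c(2L, 4L)),
                        rbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(as.numeric(f2), rep(1, 4))
  # randomized maps vs exhaustive enumeration
  set.seed(404)
  for (rep in 1:20) {
    nq <- 8L
    qres <- 1:nq; tres <- 11:(10 + nq)
    map <- setNames(tres, qres)
    qc <- unique(t(replicate(10, sort(sample(qres, 2)))))
    tc <- unique(t(replicate(10, sort(sample(tres, 2)))))
    f <- contact_overlap(map, qc, tc)
    for (k in seq_len(nq)) {
      qr <- qres[k]; tr <- map[[k]]
      b <- sum(qc == qr); a <- sum(tc == tr)
      cc <- 0
      for (r in seq_len(nrow(qc))) {
        if (qc[r, 1] == qr || qc[r, 2] == qr) {
          partner <- if (qc[r, 1] == qr) qc[r, 2] else qc[r, 1]
          tp <- map[[as.character(partner)]]
          hit <- any((tc[, 1] == tr & tc[, 2] == tp) |
                       (tc[, 2] == tr & tc[, 1] == tp))
          if (hit) cc <- cc + 1
        }
      }
      want <- if (a == 0 || b == 0) 0 else (cc / a + cc / b) / 2
      expect_equal(f[[k]], want, tolerance = 1e-12)
    }
  }
})

test_that("chemical classes partition the 20 amino acids as printed", {
  expect_identical(chemical_class("K"), "pos")
  expect_identical(chemical_class("R"), "pos")
  expect_identical(chemical_class("E"), "neg")
  expect_identical(chemical_class("N"), "donor_acceptor")
  expect_identical(chemical_class("F"), "aromatic")
  expect_identical(chemical_class("G"), "hydrophobic")
  expect_identical(chemical_class("H"), "his_tyr")
  expect_identical(chemical_class("Y"), "his_tyr")
  all20 <- chemical_class(ddgprof::AA1)
  expect_equal(length(all20), 20L)
  expect_equal(sort(unique(all20)),
               sort(c("pos", "neg", "donor_acceptor", "aromatic",
                      "hydrophobic", "his_tyr")))
  expect_equal(as.numeric(table(all20)[c("pos", "neg", "donor_acceptor",
                                         "aromatic", "hydrophobic",
                                         "his_tyr")]),
               c(2, 2, 4, 2, 8, 2))
  expect_error(chemical_class("X"), "nonstandard")
})

test_that("self-alignment and rigid copies score exactly 1", {
  sp <- fixture_spec(seed = 21, interface_length = 10, flank = 2)
  cx <- make_toy_dimer(sp)
  im <- extract_interface(cx)
  self <- align_interfaces(im, im, metric = "iscore")
  expect_equal(self$itm, 1.0, tolerance = 1e-9)
  expect_equal(self$iscore, 1.0, tolerance = 1e-9)
  expect_equal(self$pcscore, 1.0, tolerance = 1e-9)
  expect_equal(self$alignment$N_a, im$L_Q)
  # rigidly moved copy: scores invariant
  moved <- perturb_complex(cx, sigma = 0, seed = 99)
  im2 <- extract_interface(moved)
  rep2 <- align_interfaces(im, im2, metric = "iscore")
  expect_equal(rep2$itm, 1.0, tolerance = 1e-6)
  expect_equal(rep2$iscore, 1.0, tolerance = 1e-6)
  expect_equal(rep2$pcscore, 1.0, tolerance = 1e-6)
})

test_that("returned scores equal formula re-evaluation and beat random maps", {
  sp <- fixture_spec(seed = 22, interface_length = 10, flank = 2)
  cx <- make_toy_dimer(sp)
  im <- extract_interface(cx)
  noisy <- perturb_complex(cx, sigma = 1, seed = 7)
  imn <- extract_interface(noisy)
  rep <- align_interfaces(im, imn, metric = "itm")
  al <- rep$alignment
  # formula oracle on the returned correspondence
  expect_equal(rep$itm, oracle_itm(al$d, im$L_Q, d0(im$L_Q)),
               tolerance = 1e-10)
  expect_equal(rep$iscore, oracle_iscore(al$d, al$f, im$L_Q, d0(im$L_Q)),
               tolerance = 1e-10)
  # optimality spot-check: better than random correspondences of equal size
  qd <- rbind(ddgprof:::interface_chain_data(im, "A")$ca,
              ddgprof:::interface_chain_data(im, "B")$ca)
  td <- rbind(ddgprof:::interface_chain_data(imn, "A")$ca,
              ddgprof:::interface_chain_data(imn, "B")$ca)
  set.seed(405)
  for (k in 1:50) {
    qi <- sort(sample(nrow(qd), al$N_a))
    ti <- sort(sample(nrow(td), al$N_a))
    fit <- kabsch_superpose(qd[qi, ], td[ti, ])
    dr <- sqrt(rowSums((sweep(qd[qi, ] %*% fit$R, 2, -fit$t) -
                          td[ti, ])^2))
    expect_lte(oracle_itm(dr, im$L_Q, d0(im$L_Q)), rep$itm + 1e-9)
  }
})

test_that("median iTM-score degrades monotonically with coordinate noise", {
  sp <- fixture_spec(seed = 23, interface_length = 10, flank = 2)
  cx <- make_toy_dimer(sp)
  im <- extract_interface(cx)
  sigmas <- c(0, 0.5, 1, 2, 4)
  med <- vapply(sigmas, function(sg) {
    vals <- vapply(1:20, function(s) {
      pert <- perturb_complex(cx, sigma = sg, seed = 1000 + s)
      imp <- tryCatch(extract_interface(pert), error = function(e) NULL)
      if (is.null(imp)) return(0)
      align_interfaces(im, imp, metric = "itm")$itm
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
  expect_equal(med[1], 1.0, tolerance = 1e-9)
})
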