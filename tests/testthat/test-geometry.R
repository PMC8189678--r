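test_that("dihedral reproduces constructed torsions and planar cases", {
  # trans zig-zag in a plane
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, -1, 0)), 180)
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 0)
  # p4 rotated by t about the p2->p3 axis must give angle t
  for (t in c(30, 90, 275)) {
    p2 <- c(0, 0, 0); p3 <- c(0, 0, 1)
    p1 <- p2 + c(1, 0, 0)
    p4 <- p3 + c(cos(t * pi / 180), sin(t * pi / 180), 0)
    expect_equal(dihedral(p1, p2, p3, p4), t, tolerance = 1e-12)
  }
})

test_that("dihedral degenerate geometry yields NA, not an exception", {
  # collinear triple
  expect_true(is.na(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))))
  # coincident consecutive points
  expect_true(is.na(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))))
  expect_true(is.na(dihedral(NULL, c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))))
})

test_that("dihedral agrees with an independent formulation and is rigid-motion invariant", {
  set.seed(42)
  worst_oracle <- 0
  worst_rigid <- 0
  for (k in 1:500) {
    pts <- matrix(rnorm(12), 4, 3)
    a <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    if (is.na(a)) next
    b <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    worst_oracle <- max(worst_oracle, abs(((a - b + 180) %% 360) - 180))
    m <- random_rigid_motion()
    tp <- pts %*% t(m$R) + matrix(m$t, 4, 3, byrow = TRUE)
    a2 <- dihedral(tp[1, ], tp[2, ], tp[3, ], tp[4, ])
    worst_rigid <- max(worst_rigid, abs(((a - a2 + 180) %% 360) - 180))
  }
  expect_lt(worst_oracle, 1e-9)
  expect_lt(worst_rigid, 1e-9)
})

test_that("pseudorotation round-trips phase, amplitude and bin label", {
  set.seed(11)
  for (k in 1:200) {
    P <- runif(1, 0, 360)
    amp <- runif(1, 5, 60)
    nu <- amp * cos((P + 144 * (0:4 - 2)) * pi / 180)
    sp <- sugar_pucker(nu)
    expect_equal(sp$phase, P, tolerance = 1e-9)
    expect_equal(sp$amplitude, amp, tolerance = 1e-9)
    expect_identical(sp$pucker_label,
                     rnaforge:::.PUCKER_LABELS[[floor(P / 36) + 1]])
  }
  # worked bins
  nu18 <- 40 * cos((18 + 144 * (0:4 - 2)) * pi / 180)
  expect_identical(sugar_pucker(nu18)$pucker_label, "C3'-endo")
  nu162 <- 38 * cos((162 + 144 * (0:4 - 2)) * pi / 180)
  expect_identical(sugar_pucker(nu162)$pucker_label, "C2'-endo")
})

test_that("planar ring gives amplitude zero and undefined label", {
  sp <- sugar_pucker(rep(0, 5))
  expect_equal(sp$amplitude, 0)
  expect_true(is.na(sp$phase))
  expect_true(is.na(sp$pucker_label))
  # nu2 ~ 0 but puckered: phase must still be quadrant-correct (P ~ 90)
  nu90 <- 40 * cos((90 + 144 * (0:4 - 2)) * pi / 180)
  expect_equal(sugar_pucker(nu90)$phase, 90, tolerance = 1e-9)
})

test_that("periodic helix interiors share identical torsion vectors", {
  # a homogeneous sequence: base-centre pseudotorsions depend on the base
  ch <- make_test_helix(n = 7, sequence = "GGGGGGG")
  ann <- annotate_chain(ch)
  interior <- 3:5  # unaffected by either terminus
  for (col in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi",
                "eta", "theta", "eta_prime", "theta_prime",
                "eta_pprime", "theta_pprime")) {
    v <- ann[[col]][interior]
    expect_false(anyNA(v), info = col)
    expect_lt(max(v) - min(v), 1e-6)
  }
})

test_that("terminal and missing-P undefined bookkeeping is exact", {
  ch <- make_test_helix(n = 6)
  ann <- annotate_chain(ch)
  # 5'-terminal residue has no P atom: alpha and beta undefined there
  expect_true(is.na(ann$alpha[1]))
  expect_true(is.na(ann$beta[1]))
  expect_false(anyNA(ann$alpha[2:6]))
  expect_false(anyNA(ann$beta[2:6]))
  # epsilon/zeta need P(i+1): undefined at the 3' terminus only
  expect_identical(which(is.na(ann$epsilon)), 6L)
  expect_identical(which(is.na(ann$zeta)), 6L)
  # eta family needs residue i-1 and P(i); theta family needs P(i+1)
  for (col in c("eta", "eta_prime", "eta_pprime",
                "theta", "theta_prime", "theta_pprime")) {
    expect_identical(which(is.na(ann[[col]])), c(1L, 6L), info = col)
  }
  # ribose and pucker are intra-residue: always defined here
  expect_false(anyNA(ann$phase))
  expect_false(anyNA(ann$nu0))
})

test_that("an unresolved residue propagates undefined angles to its neighbours", {
  ch <- make_test_helix(n = 4)
  ch$residues[[2]]$atoms <- NULL
  ch$residues[[2]]$resolved <- FALSE
  ch$residues[[2]]$nt_code <- "-"
  ann <- annotate_chain(ch)
  expect_true(all(is.na(ann[2, c("alpha", "beta", "gamma", "delta",
                                 "epsilon", "zeta", "chi", "eta", "theta",
                                 "nu0", "phase")])))
  expect_true(is.na(ann$epsilon[1]))  # needs P(2)
  expect_true(is.na(ann$zeta[1]))
  expect_true(is.na(ann$alpha[3]))    # needs O3'(2)
  expect_true(is.na(ann$eta[3]))      # needs C4'(2)
  expect_false(is.na(ann$theta[3]))   # only forward-looking
  expect_false(is.na(ann$gamma[3]))
})

test_that("single-residue chain defines only intra-residue descriptors", {
  ch <- make_test_helix(n = 1)
  ann <- annotate_chain(ch)
  expect_true(all(is.na(ann[1, c("alpha", "beta", "epsilon", "zeta",
                                 "eta", "theta", "eta_prime", "theta_prime",
                                 "eta_pprime", "theta_pprime")])))
  expect_false(is.na(ann$phase[1]))
  expect_false(is.na(ann$chi[1]))
})

test_that("chi window classifies syn and anti", {
  syn_ch <- make_test_helix(n = 2, chi_deg = 10)
  expect_identical(annotate_chain(syn_ch)$chi_class, c("syn", "syn"))
  anti_ch <- make_test_helix(n = 2, chi_deg = 200)
  expect_identical(annotate_chain(anti_ch)$chi_class, c("anti", "anti"))
  edge <- make_test_helix(n = 1, chi_deg = 270)
  expect_identical(annotate_chain(edge)$chi_class, "syn")
})

test_that("eta-prime equals eta when C1' coordinates are copied onto C4'", {
  ch <- make_test_helix(n = 4)
  for (i in seq_along(ch$residues)) {
    at <- ch$residues[[i]]$atoms
    at["C1'", ] <- at["C4'", ]
    ch$residues[[i]]$atoms <- at
  }
  ann <- annotate_chain(ch)
  expect_identical(ann$eta_prime, ann$eta)
  expect_identical(ann$theta_prime, ann$theta)
})

test_that("all chain descriptors are rigid-motion invariant", {
  set.seed(5)
  ch <- make_test_helix(n = 5, noise = 0.1, seed = 3L)
  ann <- annotate_chain(ch)
  num_cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi",
                "nu0", "nu1", "nu2", "nu3", "nu4", "eta", "theta",
                "eta_prime", "theta_prime", "eta_pprime", "theta_pprime",
                "phase", "amplitude")
  for (k in 1:3) {
    ann2 <- annotate_chain(apply_rigid_motion_chain(ch, random_rigid_motion()))
    for (col in num_cols) {
      d <- abs(((ann[[col]] - ann2[[col]] + 180) %% 360) - 180)
      expect_lt(max(d, na.rm = TRUE), 1e-9)
      expect_identical(is.na(ann[[col]]), is.na(ann2[[col]]))
    }
    expect_identical(ann$pucker_label, ann2$pucker_label)
    expect_identical(ann$chi_class, ann2$chi_class)
  }
})
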