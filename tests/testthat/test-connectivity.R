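test_that("PLV anchors: identical, phase-shifted and independent signals", {
  t_ax <- seq(0, 1, length.out = 200)
  x <- sin(2 * pi * 10 * t_ax)
  expect_equal(plv(x, x), 1, tolerance = 1e-12)
  # constant pi/2 phase offset still locks perfectly
  expect_equal(plv(x, cos(2 * pi * 10 * t_ax)), 1, tolerance = 1e-3)
  expect_error(plv(x, rep(1, 200)), "zero variance")
  set.seed(1)
  expect_lt(plv(rnorm(400), rnorm(400)), 0.3)
})

test_that("pairwise estimators match independently coded brute-force oracles", {
  set.seed(42)
  for (rep in 1:12) {
    x <- rnorm(200)
    y <- rnorm(200)
    expect_equal(plv(x, y), oracle_plv(x, y), tolerance = 1e-10)
    expect_equal(pcc(x, y), oracle_pcc(x, y), tolerance = 1e-10)
    expect_equal(coh(x, y, fs = 200), oracle_coh(x, y, fs = 200),
                 tolerance = 1e-8)
    expect_equal(mi(x, y), oracle_mi(x, y), tolerance = 1e-10)
  }
})

test_that("PCC analytic anchors and error cases", {
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pcc(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(pcc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("coherence is 1 for identical signals and scale-invariant", {
  set.seed(7)
  x <- rnorm(200)
  expect_equal(coh(x, x, fs = 200), 1, tolerance = 1e-10)
  expect_equal(coh(x, 3 * x, fs = 200), 1, tolerance = 1e-10)
  y <- rnorm(200)
  expect_equal(coh(x, y, fs = 200), coh(5 * x, y, fs = 200),
               tolerance = 1e-10)
  expect_error(coh(x, y, fs = 200, band = c(1, 150)), "fs/2")
})

test_that("MI anchors: independence, identity, and a hand-computed table", {
  # independent 2x2 table: joint equals product of marginals
  expect_equal(spdconn:::mi_from_joint(matrix(0.25, 2, 2)), 0)
  # identical uniform 4-level signal: MI = H = log2 4
  x <- rep(c(0, 1, 2, 3), 25)
  expect_equal(mi(x, x, n_bins = 4), 2, tolerance = 1e-12)
  # direct evaluation over the 2x2 table [[.25,.25],[0,.5]]
  expect_equal(spdconn:::mi_from_joint(matrix(c(0.25, 0, 0.25, 0.5), 2)),
               0.25 * log2(2) + 0.25 * log2(2 / 3) + 0.5 * log2(4 / 3),
               tolerance = 1e-12)
  expect_equal(spdconn:::mi_from_joint(matrix(c(0.25, 0, 0.25, 0.5), 2)),
               0.3112781, tolerance = 1e-6)
  expect_error(mi(1, 1), "at least 2")
})

test_that("range, symmetry and scaling invariances hold on random pairs", {
  set.seed(99)
  for (rep in 1:40) {
    x <- rnorm(120)
    y <- rnorm(120)
    v_plv <- plv(x, y); v_pcc <- pcc(x, y)
    v_coh <- coh(x, y, fs = 120); v_mi <- mi(x, y)
    expect_gte(v_plv, 0); expect_lte(v_plv, 1)
    expect_gte(v_pcc, -1); expect_lte(v_pcc, 1)
    expect_gte(v_coh, 0); expect_lte(v_coh, 1 + 1e-12)
    expect_gte(v_mi, 0)
    # symmetry in the arguments
    expect_equal(v_plv, plv(y, x), tolerance = 1e-12)
    expect_equal(v_pcc, pcc(y, x), tolerance = 1e-12)
    expect_equal(v_coh, coh(y, x, fs = 120), tolerance = 1e-12)
    expect_equal(v_mi, mi(y, x), tolerance = 1e-12)
    # amplitude scaling leaves PLV/COH untouched; positive affine
    # rescaling leaves PCC untouched
    expect_equal(v_plv, plv(2.5 * x, y), tolerance = 1e-10)
    expect_equal(v_coh, coh(x, 0.3 * y, fs = 120), tolerance = 1e-10)
    expect_equal(v_pcc, pcc(2 * x + 1, y), tolerance = 1e-12)
    # self-MI dominates cross-MI under the same binning
    expect_gte(mi(x, x) + 1e-12, v_mi)
  }
})

test_that("connectivity_matrix mirrors the pairwise estimators", {
  set.seed(5)
  X <- matrix(rnorm(4 * 200), 4, 200)
  for (kind in c("plv", "pcc", "coh", "mi")) {
    M <- connectivity_matrix(X, kind, fs = 200, n_bins = 16L)
    expect_identical(bare(M), t(bare(M)))
    fun <- switch(kind,
      plv = function(a, b) plv(a, b),
      pcc = function(a, b) pcc(a, b),
      coh = function(a, b) coh(a, b, fs = 200),
      mi  = function(a, b) mi(a, b, n_bins = 16L))
    for (m in 1:3) {
      for (n in (m + 1):4) {
        expect_equal(M[m, n], fun(X[m, ], X[n, ]), tolerance = 1e-10)
      }
    }
    if (kind != "mi") expect_equal(diag(bare(M)), rep(1, 4))
  }
  # identical channels: PLV matrix of all ones
  Xi <- matrix(rep(sin(2 * pi * 9 * seq(0, 1, length.out = 200)), 3),
               3, byrow = TRUE)
  expect_equal(bare(connectivity_matrix(Xi, "plv")),
               matrix(1, 3, 3), tolerance = 1e-9)
  # MI diagonal holds each channel's self-MI
  Mmi <- connectivity_matrix(X, "mi", n_bins = 16L)
  expect_equal(Mmi[2, 2], mi(X[2, ], X[2, ], 16L), tolerance = 1e-12)
})
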