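test_that("thresholding keeps supra-threshold magnitudes off the diagonal", {
  M <- matrix(0.9, 3, 3); diag(M) <- 1
  attr(M, "kind") <- "plv"
  A <- threshold_to_adjacency(M, 0.5)
  expect_equal(bare(A), matrix(0.9, 3, 3) - diag(0.9, 3))
  expect_equal(diag(bare(A)), rep(0, 3))

  M2 <- matrix(0.2, 3, 3); diag(M2) <- 1
  expect_equal(bare(threshold_to_adjacency(M2, 0.5)), matrix(0, 3, 3))

  # negative PCC entries count by magnitude
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- -0.8
  P[1, 3] <- P[3, 1] <- 0.5
  attr(P, "kind") <- "pcc"
  A2 <- threshold_to_adjacency(P, 0.7)
  expect_equal(A2[1, 2], 0.8)
  expect_equal(A2[1, 3], 0)

  # binary mode
  expect_equal(bare(threshold_to_adjacency(M, 0.5, binary = TRUE)),
               matrix(1, 3, 3) - diag(3))
})

test_that("raising the threshold never adds an edge", {
  set.seed(21)
  for (rep in 1:20) {
    M <- matrix(runif(36), 6)
    M <- (M + t(M)) / 2
    th <- sort(runif(2))
    e_lo <- bare(threshold_to_adjacency(M, th[1])) > 0
    e_hi <- bare(threshold_to_adjacency(M, th[2])) > 0
    expect_true(all(e_lo | !e_hi)) # edges at high threshold subset of low
  }
})

test_that("Laplacian matches the hand-derived path-graph case", {
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  L <- graph_laplacian(A)
  expect_equal(L, rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 1, 3),
               tolerance = 1e-12)
  expect_equal(graph_laplacian(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("Laplacians are PSD with the constant vector in the null space", {
  set.seed(31)
  for (rep in 1:30) {
    A <- matrix(runif(49), 7) * (matrix(runif(49), 7) > 0.5)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    L <- graph_laplacian(A)
    expect_equal(max(abs(L %*% rep(1, 7))), 0, tolerance = 1e-12)
    for (j in 1:30) {
      x <- rnorm(7)
      expect_gte(drop(t(x) %*% L %*% x), -1e-10)
    }
  }
})

test_that("rectification clamps the spectrum from below at epsilon", {
  expect_equal(bare(rectify_spd(matrix(0, 3, 3), 1e-4)),
               diag(1e-4, 3))
  S <- diag(c(2, 3))
  expect_equal(bare(rectify_spd(S, 1e-4)), S, tolerance = 1e-10)
  L <- rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1))
  R <- rectify_spd(L, 1e-4)
  expect_equal(sort(eigen(R, symmetric = TRUE)$values), c(1e-4, 1, 3),
               tolerance = 1e-10)
  expect_error(rectify_spd(matrix(c(1, NA, NA, 1), 2)), "non-finite")
  expect_error(rectify_spd(diag(2), epsilon = 0), "positive")
})

test_that("every rectified Laplacian passes the SPD check", {
  set.seed(41)
  for (rep in 1:50) {
    A <- matrix(runif(64), 8) * (matrix(runif(64), 8) > 0.6)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    R <- rectify_spd(graph_laplacian(A), 1e-4)
    expect_true(is_spd(R))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
               1e-4 - 1e-12)
  }
})

test_that("mean-PLV thresholding recovers the planted graph support", {
  ds <- bench_dataset()
  spec <- bench_spec()
  for (cls in 0:2) {
    idx <- which(ds$labels == cls)
    M <- matrix(0, 8, 8)
    for (i in idx) {
      M <- M + bare(connectivity_matrix(ds$data[i, , ], "plv"))
    }
    M <- M / length(idx)
    A_true <- planted_adjacency(spec, cls)
    off <- row(M) != col(M)
    midpoint <- (mean(M[A_true == 1]) + mean(M[A_true == 0 & off])) / 2
    A_rec <- (M >= midpoint & off) * 1
    expect_equal(A_rec, A_true, label = paste("class", cls))
  }
})

test_that("epochs_to_spd produces SPD inputs aligned with labels", {
  ds <- subset_epochs(bench_dataset(), 1:10)
  out <- epochs_to_spd(ds, "plv", threshold = 0.6, epsilon = 1e-4)
  expect_equal(dim(out$spd), c(10, 8, 8))
  expect_identical(out$labels, ds$labels)
  for (i in 1:10) expect_true(is_spd(out$spd[i, , ]))
})
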