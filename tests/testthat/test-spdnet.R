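test_that("BiMap layer contracts: dimensions, SPD preservation, orthonormal identity", {
  set.seed(61)
  p <- spdnet_params(62)
  # dimension chain 62 -> 31 -> 20 -> 16 -> 12
  expect_equal(p$dims, c(62, 31, 20, 16, 12))
  expect_equal(dim(p$W[[1]]), c(31, 62))
  S <- random_spd(62)
  out <- bimap_forward(S, p$W[[1]])
  expect_equal(dim(out), c(31, 31))
  # orthonormal rows map the identity to the smaller identity
  expect_equal(bimap_forward(diag(62), p$W[[1]]), diag(31),
               tolerance = 1e-10)
  expect_error(bimap_forward(diag(10), p$W[[1]]), "mismatch")
  # congruence with full-row-rank W preserves positive definiteness
  for (rep in 1:50) {
    W <- matrix(rnorm(4 * 7), 4, 7)
    ev <- eigen(bimap_forward(random_spd(7), W), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("ReEig clamps, is idempotent, and preserves SPD with BiMap", {
  expect_equal(reeig_forward(diag(c(1, 1e-8)), 1e-4), diag(c(1, 1e-4)),
               tolerance = 1e-12)
  S <- random_spd(5)
  expect_equal(reeig_forward(S, 1e-4), S, tolerance = 1e-10)
  set.seed(71)
  p <- spdnet_params(8, c(5, 3))
  for (rep in 1:200) {
    S <- random_spd(8, jitter = stats::runif(1, 0, 0.3))
    h <- reeig_forward(bimap_forward(S, p$W[[1]]), 1e-4)
    expect_true(is_spd(h))
    expect_equal(reeig_forward(h, 1e-4), h, tolerance = 1e-10)
    h2 <- reeig_forward(bimap_forward(h, p$W[[2]]), 1e-4)
    expect_true(is_spd(h2))
  }
})

test_that("LogEig agrees with the geometry module's matrix log", {
  set.seed(81)
  for (rep in 1:10) {
    S <- random_spd(6)
    expect_equal(logeig_forward(S), matrix_log(S), tolerance = 1e-10)
  }
  expect_equal(logeig_forward(diag(3)), matrix(0, 3, 3))
  expect_equal(logeig_forward(diag(c(exp(1), 1))), diag(c(1, 0)),
               tolerance = 1e-12)
})

test_that("forward pass yields a proper probability simplex", {
  set.seed(91)
  p <- spdnet_params(6, c(4, 3))
  S <- random_spd(6)
  out <- spdconn:::spdnet_forward(S, p)
  expect_equal(sum(out$probs), 1, tolerance = 1e-10)
  expect_true(all(out$probs > 0))
  # inference is deterministic (no dropout outside training)
  out2 <- spdconn:::spdnet_forward(S, p)
  expect_identical(out$probs, out2$probs)
  # zero head weights give uniform class probabilities
  p0 <- p; p0$A[] <- 0; p0$b[] <- 0
  expect_equal(spdconn:::spdnet_forward(S, p0)$probs, rep(1 / 3, 3),
               tolerance = 1e-12)
})

test_that("analytic gradients match central differences on a toy network", {
  set.seed(13)
  params <- spdnet_params(4, c(3, 2), n_classes = 3)
  S <- random_spd(4)
  y <- 2L
  lossfun <- function(pp) {
    -log(spdconn:::spdnet_forward(S, pp)$probs[y])
  }
  fwd <- spdconn:::spdnet_forward(S, params, keep_cache = TRUE)
  bwd <- spdconn:::spdnet_backward(fwd, y, params)
  h <- 1e-5
  relerr <- function(a, num) {
    keep <- abs(num) > 1e-6
    if (!any(keep)) return(0)
    max(abs(a - num)[keep] / pmax(abs(a) + abs(num), 1e-8)[keep])
  }
  for (k in 1:2) {
    num <- array(0, dim(params$W[[k]]))
    for (i in seq_along(num)) {
      p1 <- params; p1$W[[k]][i] <- p1$W[[k]][i] + h
      p2 <- params; p2$W[[k]][i] <- p2$W[[k]][i] - h
      num[i] <- (lossfun(p1) - lossfun(p2)) / (2 * h)
    }
    expect_lt(relerr(bwd$dW[[k]], num), 1e-4)
  }
  numA <- array(0, dim(params$A))
  for (i in seq_along(numA)) {
    p1 <- params; p1$A[i] <- p1$A[i] + h
    p2 <- params; p2$A[i] <- p2$A[i] - h
    numA[i] <- (lossfun(p1) - lossfun(p2)) / (2 * h)
  }
  expect_lt(relerr(bwd$dA, numA), 1e-4)
  numb <- numeric(length(params$b))
  for (i in seq_along(numb)) {
    p1 <- params; p1$b[i] <- p1$b[i] + h
    p2 <- params; p2$b[i] <- p2$b[i] - h
    numb[i] <- (lossfun(p1) - lossfun(p2)) / (2 * h)
  }
  expect_lt(relerr(bwd$db, numb), 1e-4)
})

test_that("training keeps BiMap weights orthonormal and is deterministic", {
  set.seed(15)
  n <- 64
  spd <- array(0, dim = c(n, 6, 6))
  labels <- rep(0:2, length.out = n)
  for (i in seq_len(n)) {
    spd[i, , ] <- random_spd(6) + diag(6) * labels[i]
  }
  cfg <- train_config(batch_size = 16, max_epochs = 4, seed = 99)
  fit1 <- spdnet_train(spd, labels, c(4, 3), cfg)
  fit2 <- spdnet_train(spd, labels, c(4, 3), cfg)
  expect_identical(fit1$params, fit2$params)
  for (W in fit1$params$W) {
    expect_lt(max(abs(W %*% t(W) - diag(nrow(W)))), 1e-6)
  }
  expect_true(all(is.finite(fit1$log$loss)))
  # non-SPD input is refused up front
  bad <- spd
  bad[3, , ] <- diag(c(1, -1, 1, 1, 1, 1))
  expect_error(spdnet_train(bad, labels, c(4, 3), cfg), "not SPD")
})

test_that("an easily separable planted dataset is fit to high accuracy", {
  ds <- bench_dataset()
  sub <- subset_epochs(ds, 1:200) # 200 epochs of data, all classes present
  feats <- epochs_to_spd(sub, "plv")
  fit <- spdnet_train(feats$spd, feats$labels, c(6, 4),
                      bench_train_config(max_epochs = 40))
  expect_gte(dplyr::last(fit$log$train_accuracy), 0.95)
  # broom-style accessors stay consistent with the log
  expect_equal(nrow(tidy(fit)), 40)
  expect_equal(glance(fit)$train_accuracy,
               dplyr::last(fit$log$train_accuracy))
})
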