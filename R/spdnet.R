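# SPD matrix network: stacked BiMap (bilinear congruence) -> ReEig
# (eigenvalue clamp) pairs, a LogEig layer into flat space, and a dense
# softmax head. Trained by SGD; BiMap weights live on the manifold of
# row-orthonormal matrices and are updated by tangent projection plus a
# QR retraction. Backprop through the eigendecomposition layers uses the
# Daleckii-Krein divided-difference (Loewner) form of the derivative of a
# spectral function, which stays finite for arbitrarily close eigenvalues.

#' BiMap layer: bilinear congruence transform
#'
#' `W S W^t`, reducing an SPD matrix from `d_in x d_in` to
#' `d_out x d_out`. With full-row-rank `W` the output remains SPD.
#'
#' @param S SPD matrix, `d_in x d_in`.
#' @param W transformation matrix, `d_out x d_in`, orthonormal rows.
#' @return `d_out x d_out` matrix.
#' @export
bimap_forward <- function(S, W) {
  if (ncol(W) != nrow(S)) {
    stop(sprintf("BiMap dimension mismatch: W is %dx%d, S is %dx%d",
                 nrow(W), ncol(W), nrow(S), ncol(S)), call. = FALSE)
  }
  W %*% S %*% t(W)
}

#' ReEig layer: eigenvalue rectification
#'
#' Clamps eigenvalues below `epsilon` up to `epsilon`, guaranteeing an
#' SPD output; idempotent.
#'
#' @param S symmetric matrix.
#' @param epsilon eigenvalue floor.
#' @return SPD matrix with smallest eigenvalue `>= epsilon`.
#' @export
reeig_forward <- function(S, epsilon = 1e-4) {
  e <- eig_sym(S, "ReEig input")
  sym_part(e$vectors %*% (pmax(e$values, epsilon) * t(e$vectors)))
}

#' LogEig layer: matrix logarithm into flat space
#'
#' Identical to [matrix_log()]; maps the final SPD representation into
#' the tangent space at the identity so it can be flattened for a dense
#' classifier.
#'
#' @param S SPD matrix.
#' @return symmetric matrix.
#' @export
logeig_forward <- function(S) matrix_log(S)

#' Training configuration for the SPD network
#'
#' Defaults follow the reference hyperparameters: learning rate 0.001,
#' batch size 64, at most 200 epochs, weight decay 1e-4 (dense head
#' only), dropout 0.2 on the flattened LogEig output.
#'
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size.
#' @param max_epochs training epochs.
#' @param weight_decay L2 penalty on the dense head.
#' @param dropout dropout probability on the flattened feature vector.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         max_epochs = 200, weight_decay = 1e-4,
                         dropout = 0.2, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            weight_decay >= 0, dropout >= 0, dropout < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize SPD network parameters
#'
#' BiMap weights are rows of seeded random orthogonal matrices (QR of a
#' Gaussian), so `W_k W_k^t = I` from the start; the dense head is a
#' small-Gaussian affine map from the flattened LogEig output to the
#' class logits.
#'
#' @param input_dim input SPD matrix dimension (62 for a dense EEG
#'   montage).
#' @param hidden_dims output dimension of each BiMap layer, strictly
#'   decreasing (default `c(31, 20, 16, 12)`).
#' @param n_classes number of classes.
#' @param reeig_epsilon ReEig clamp floor.
#' @return a `spdnet_params` list with elements `W` (list of matrices),
#'   `A`, `b`, `dims`, `reeig_epsilon`.
#' @export
spdnet_params <- function(input_dim, hidden_dims = c(31, 20, 16, 12),
                          n_classes = 3, reeig_epsilon = 1e-4) {
  dims <- c(input_dim, hidden_dims)
  if (any(diff(dims) >= 0)) {
    stop("BiMap dimensions must be strictly decreasing", call. = FALSE)
  }
  W <- vector("list", length(hidden_dims))
  for (k in seq_along(hidden_dims)) {
    G <- matrix(stats::rnorm(dims[k] * dims[k + 1]), dims[k], dims[k + 1])
    W[[k]] <- t(qr.Q(qr(G)))
  }
  d_out <- dims[length(dims)]
  structure(list(
    W = W,
    A = matrix(stats::rnorm(n_classes * d_out^2, sd = 0.01),
               n_classes, d_out^2),
    b = numeric(n_classes),
    dims = dims, reeig_epsilon = reeig_epsilon
  ), class = "spdnet_params")
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Forward pass for one SPD matrix. Returns probabilities and, when
# keep_cache, the per-layer eigendecompositions needed for backprop.
spdnet_forward <- function(S, params, training = FALSE, drop_mask = NULL,
                           keep_cache = FALSE) {
  K <- length(params$W)
  cache <- if (keep_cache) vector("list", K) else NULL
  for (k in seq_len(K)) {
    S_in <- S
    M <- bimap_forward(S, params$W[[k]])
    e <- eig_sym(M, "BiMap output")
    v_cl <- pmax(e$values, params$reeig_epsilon)
    S <- sym_part(e$vectors %*% (v_cl * t(e$vectors)))
    if (keep_cache) cache[[k]] <- list(S_in = S_in, U = e$vectors,
                                       v = e$values)
  }
  e_log <- eig_sym(S, "LogEig input")
  Fm <- sym_part(e_log$vectors %*% (log(pmax(e_log$values, 1e-300)) *
                                      t(e_log$vectors)))
  f <- as.vector(Fm)
  if (training && !is.null(drop_mask)) f <- f * drop_mask
  z <- drop(params$A %*% f + params$b)
  list(probs = softmax(z), f = f, cache = cache,
       logeig = list(U = e_log$vectors, v = e_log$values))
}

# Loewner (divided-difference) matrix for a spectral function.
loewner_matrix <- function(v, fv, fpv) {
  n <- length(v)
  dv <- outer(v, v, "-")
  df <- outer(fv, fv, "-")
  Lw <- matrix(0, n, n)
  close_ev <- abs(dv) < 1e-12
  Lw[!close_ev] <- df[!close_ev] / dv[!close_ev]
  fp_mid <- (outer(fpv, fpv, "+")) / 2
  Lw[close_ev] <- fp_mid[close_ev]
  Lw
}

# dL/dS for F = U f(V) U^t given symmetric upstream gradient G.
spectral_backward <- function(U, v, G, fv, fpv) {
  Lw <- loewner_matrix(v, fv, fpv)
  sym_part(U %*% (Lw * (t(U) %*% G %*% U)) %*% t(U))
}

# Backward pass for one sample; fwd is spdnet_forward(keep_cache = TRUE)
# output, y the 1-based class index. Returns per-parameter gradients
# (Euclidean; Stiefel projection happens at update time) and the loss.
spdnet_backward <- function(fwd, y, params, drop_mask = NULL) {
  n_cls <- length(params$b)
  dz <- fwd$probs
  dz[y] <- dz[y] - 1
  dA <- dz %o% fwd$f
  db <- dz
  df <- drop(crossprod(params$A, dz))
  if (!is.null(drop_mask)) df <- df * drop_mask
  d_out <- params$dims[length(params$dims)]
  G <- sym_part(matrix(df, d_out, d_out))
  # through LogEig
  v <- pmax(fwd$logeig$v, 1e-300)
  G <- spectral_backward(fwd$logeig$U, v, G, log(v), 1 / v)
  dW <- vector("list", length(params$W))
  eps <- params$reeig_epsilon
  for (k in rev(seq_along(params$W))) {
    ck <- fwd$cache[[k]]
    # through ReEig (clamp)
    G <- spectral_backward(ck$U, ck$v, G, pmax(ck$v, eps),
                           as.numeric(ck$v > eps))
    # through BiMap
    dW[[k]] <- 2 * G %*% params$W[[k]] %*% ck$S_in
    G <- t(params$W[[k]]) %*% G %*% params$W[[k]]
  }
  loss <- -log(max(fwd$probs[y], 1e-300))
  list(dW = dW, dA = dA, db = db, loss = loss)
}

# Project a Euclidean gradient onto the tangent space of the Stiefel
# manifold at X (orthonormal columns) and retract by sign-fixed QR.
stiefel_step <- function(X, GX, lr) {
  PG <- GX - X %*% sym_part(crossprod(X, GX))
  qr_d <- qr(X - lr * PG)
  Q <- qr.Q(qr_d)
  s <- sign(diag(qr.R(qr_d)))
  s[s == 0] <- 1
  Q %*% diag(s, ncol(Q))
}

as_spd_array <- function(x) {
  if (is.list(x)) {
    C <- nrow(x[[1]])
    a <- array(0, dim = c(length(x), C, C))
    for (i in seq_along(x)) a[i, , ] <- x[[i]]
    a
  } else {
    stopifnot(length(dim(x)) == 3)
    x
  }
}

#' Train an SPD network
#'
#' Minimizes softmax cross-entropy (plus weight decay on the dense head)
#' by minibatch SGD. BiMap weights are kept row-orthonormal throughout:
#' each step projects the Euclidean gradient onto the Stiefel tangent
#' space and retracts with a sign-fixed QR decomposition. All randomness
#' (initialization, shuffling, dropout) flows from `config$seed`, so a
#' fixed seed gives identical parameters across runs on one thread.
#'
#' @param spd `n x C x C` array (or list of matrices) of SPD inputs.
#' @param labels class label per example (any atomic type).
#' @param hidden_dims BiMap output dimensions.
#' @param config a [train_config()].
#' @param reeig_epsilon ReEig clamp floor.
#' @param check_inputs verify every training matrix is SPD before
#'   training starts.
#' @param verbose print the loss every 10 epochs.
#' @return an object of class `spdnet_fit`: `params`, `classes`,
#'   `config`, and `log` (tibble with per-epoch loss and training
#'   accuracy).
#' @export
spdnet_train <- function(spd, labels, hidden_dims = c(31, 20, 16, 12),
                         config = train_config(), reeig_epsilon = 1e-4,
                         check_inputs = TRUE, verbose = FALSE) {
  spd <- as_spd_array(spd)
  n <- dim(spd)[1]
  C <- dim(spd)[2]
  if (length(labels) != n) stop("one label per example", call. = FALSE)
  if (n < config$batch_size) {
    stop("need at least batch_size training examples", call. = FALSE)
  }
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  if (check_inputs) {
    for (i in seq_len(n)) {
      if (!is_spd(spd[i, , ], tol = 1e-8)) {
        stop("training example ", i, " is not SPD", call. = FALSE)
      }
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  params <- spdnet_params(C, hidden_dims, n_classes = length(classes),
                          reeig_epsilon = reeig_epsilon)
  d_flat <- params$dims[length(params$dims)]^2
  p_drop <- config$dropout
  lr <- config$learning_rate
  log_rows <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      m <- length(idx)
      gW <- lapply(params$W, function(w) array(0, dim(w)))
      gA <- array(0, dim(params$A))
      gb <- numeric(length(params$b))
      for (i in idx) {
        mask <- if (p_drop > 0) {
          (stats::runif(d_flat) >= p_drop) / (1 - p_drop)
        } else NULL
        fwd <- spdnet_forward(spd[i, , ], params, training = TRUE,
                              drop_mask = mask, keep_cache = TRUE)
        bwd <- spdnet_backward(fwd, y[i], params, drop_mask = mask)
        for (k in seq_along(gW)) gW[[k]] <- gW[[k]] + bwd$dW[[k]]
        gA <- gA + bwd$dA
        gb <- gb + bwd$db
        ep_loss <- ep_loss + bwd$loss
        ep_correct <- ep_correct + (which.max(fwd$probs) == y[i])
      }
      # dense head: SGD with weight decay
      params$A <- params$A - lr * (gA / m + config$weight_decay * params$A)
      params$b <- params$b - lr * gb / m
      # BiMap weights: Riemannian SGD on the Stiefel manifold
      for (k in seq_along(params$W)) {
        X <- t(params$W[[k]])
        params$W[[k]] <- t(stiefel_step(X, t(gW[[k]]) / m, lr))
      }
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / n, train_accuracy = ep_correct / n)
    if (verbose && epoch %% 10 == 0) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                      epoch, ep_loss / n, ep_correct / n))
    }
  }

  structure(list(params = params, classes = classes, config = config,
                 log = dplyr::bind_rows(log_rows)),
            class = "spdnet_fit")
}

#' Predict from a fitted SPD network
#'
#' @param object an `spdnet_fit`.
#' @param newdata `n x C x C` array or list of SPD matrices.
#' @param type `"prob"` for an `n x n_classes` probability matrix,
#'   `"class"` for predicted labels (probability ties broken toward the
#'   lowest class index).
#' @param ... unused.
#' @return matrix of probabilities or vector of labels.
#' @export
predict.spdnet_fit <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  spd <- as_spd_array(newdata)
  n <- dim(spd)[1]
  P <- matrix(0, n, length(object$classes),
              dimnames = list(NULL, as.character(object$classes)))
  for (i in seq_len(n)) {
    P[i, ] <- spdnet_forward(spd[i, , ], object$params)$probs
  }
  if (type == "prob") P else object$classes[max.col(P, ties.method = "first")]
}

#' @export
print.spdnet_fit <- function(x, ...) {
  cat(sprintf("<spdnet_fit> dims %s, %d classes\n",
              paste(x$params$dims, collapse = " -> "),
              length(x$classes)))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  %d epochs, final loss %.4f, train accuracy %.3f\n",
              nrow(x$log), last$loss, last$train_accuracy))
  invisible(x)
}

#' Tidy the training log of an SPD network fit
#' @param x an `spdnet_fit`.
#' @param ... unused.
#' @return tibble with `epoch`, `loss`, `train_accuracy`.
#' @method tidy spdnet_fit
#' @export
tidy.spdnet_fit <- function(x, ...) x$log

#' One-row summary of an SPD network fit
#' @param x an `spdnet_fit`.
#' @param ... unused.
#' @return one-row tibble: epochs trained, final loss, final training
#'   accuracy, parameter dimensions.
#' @method glance spdnet_fit
#' @export
glance.spdnet_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(n_epochs = nrow(x$log), loss = last$loss,
                 train_accuracy = last$train_accuracy,
                 dims = paste(x$params$dims, collapse = "-"))
}
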