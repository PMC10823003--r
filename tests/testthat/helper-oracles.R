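# Independent brute-force oracles for the pairwise connectivity
# estimators. These deliberately avoid the package's vectorized code
# paths: DFTs are explicit O(n^2) sums, averages are explicit loops.

# explicit DFT (no fft())
dft_naive <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 2i else -2i
  vapply(0:(n - 1), function(k) {
    sum(x * exp(sgn * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

# analytic signal by the textbook DFT multiplier, using dft_naive
analytic_naive <- function(x) {
  n <- length(x)
  X <- dft_naive(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  dft_naive(X * h, inverse = TRUE) / n
}

# PLV: phases elementwise, complex mean by explicit accumulation.
# The 5% edge trim is part of the estimator's definition.
oracle_plv <- function(x, y) {
  n <- length(x)
  k <- floor(n * 0.05)
  idx <- (k + 1):(n - k)
  phx <- atan2(Im(analytic_naive(x)), Re(analytic_naive(x)))
  phy <- atan2(Im(analytic_naive(y)), Re(analytic_naive(y)))
  acc <- 0 + 0i
  for (t in idx) acc <- acc + exp(1i * (phx[t] - phy[t]))
  Mod(acc / length(idx))
}

# Pearson correlation from explicit sums
oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_len(n)) {
    num <- num + (x[t] - mx) * (y[t] - my)
    dx <- dx + (x[t] - mx)^2
    dy <- dy + (y[t] - my)^2
  }
  num / sqrt(dx * dy)
}

# band-averaged magnitude-squared coherence by an independent Welch
# implementation (explicit segments, naive DFT)
oracle_coh <- function(x, y, fs, band = c(1, 47)) {
  n <- length(x)
  seg_len <- min(n, max(8L, round(fs / 2)))
  step <- max(1L, floor(seg_len * 0.5))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nf <- floor(seg_len / 2) + 1L
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1)]; xs <- (xs - mean(xs)) * w
    ys <- y[s:(s + seg_len - 1)]; ys <- (ys - mean(ys)) * w
    Fx <- dft_naive(xs)[seq_len(nf)]
    Fy <- dft_naive(ys)[seq_len(nf)]
    pxx <- pxx + Mod(Fx)^2
    pyy <- pyy + Mod(Fy)^2
    pxy <- pxy + Fx * Conj(Fy)
  }
  freqs <- (seq_len(nf) - 1) * fs / seg_len
  sel <- freqs >= band[1] & freqs <= band[2]
  m <- length(starts)
  mean(Mod(pxy[sel] / m)^2 / ((pxx[sel] / m) * (pyy[sel] / m)))
}

# mutual information by explicit summation over the joint table
oracle_mi <- function(x, y, n_bins = 16L) {
  bin1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  bx <- bin1(x); by <- bin1(y)
  joint <- matrix(0, n_bins, n_bins)
  for (t in seq_along(x)) {
    joint[bx[t], by[t]] <- joint[bx[t], by[t]] + 1
  }
  joint <- joint / sum(joint)
  out <- 0
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      p <- joint[i, j]
      if (p > 0) out <- out + p * log2(p / (sum(joint[i, ]) * sum(joint[, j])))
    }
  }
  out
}

# random SPD matrix with eigenvalues bounded away from zero
random_spd <- function(n, jitter = 0.5) {
  G <- matrix(stats::rnorm(n * n), n)
  crossprod(G) / n + jitter * diag(n)
}

# drop class and bookkeeping attributes for plain-matrix comparisons
bare <- function(M) matrix(as.numeric(M), nrow(M), ncol(M))
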