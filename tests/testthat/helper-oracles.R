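# Brute-force discretized Bayesian filters used as independent oracles for
# the Kalman recursion and the point-process filter. Both assume diagonal A
# and W so the 2-D transition kernel factorizes into per-dimension kernels
# (the toy instances are built that way); the observation step is applied
# pointwise on the full 2-D grid, so the posterior itself is fully 2-D.

makeGrid <- function(lim = 1.6, step = 0.05) seq(-lim, lim, by = step)

# per-dimension transition kernel K[i, j] = p(x' = g[i] | x = g[j])
dimKernel <- function(g, a, w) {
  K <- outer(g, g, function(xp, x) stats::dnorm(xp, a * x, sqrt(w)))
  sweep(K, 2, colSums(K), "/")
}

# generic separable grid filter; loglikFun(t) returns a matrix over the grid
gridFilter <- function(g, A, W, T, loglikFun) {
  K1 <- dimKernel(g, A[1, 1], W[1, 1])
  K2 <- dimKernel(g, A[2, 2], W[2, 2])
  # initial predictive matches the package filters: x0 = 0, P0 = W
  p <- outer(stats::dnorm(g, 0, sqrt(A[1, 1]^2 * W[1, 1] + W[1, 1])),
             stats::dnorm(g, 0, sqrt(A[2, 2]^2 * W[2, 2] + W[2, 2])))
  p <- p / sum(p)
  means <- matrix(0, T, 2)
  for (t in seq_len(T)) {
    if (t > 1) {
      p <- K1 %*% p %*% t(K2)
      p <- p / sum(p)
    }
    ll <- loglikFun(t)
    ll <- ll - max(ll)
    p <- p * exp(ll)
    p <- p / sum(p)
    means[t, ] <- c(sum(rowSums(p) * g), sum(colSums(p) * g))
  }
  means
}

# linear-Gaussian observations y_t = H x + N(0, Q)
kfGridFilter <- function(g, A, W, H, Q, Y) {
  Qi <- solve(Q)
  X1 <- matrix(rep(g, length(g)), length(g))      # rows vary dim 1
  X2 <- t(X1)
  gridFilter(g, A, W, nrow(Y), function(t) {
    ll <- 0
    for (c in seq_len(nrow(H))) {    # toy instances use diagonal Q
      r <- Y[t, c] - (H[c, 1] * X1 + H[c, 2] * X2)
      ll <- ll - 0.5 * Qi[c, c] * r^2
    }
    ll
  })
}

# Poisson observations y_tc ~ Pois(exp(mu_c + a_c . x))
ppfGridFilter <- function(g, A, W, mu, a, Y) {
  X1 <- matrix(rep(g, length(g)), length(g))
  X2 <- t(X1)
  gridFilter(g, A, W, nrow(Y), function(t) {
    ll <- 0
    for (c in seq_along(mu)) {
      eta <- mu[c] + a[c, 1] * X1 + a[c, 2] * X2
      ll <- ll + Y[t, c] * eta - exp(eta)
    }
    ll
  })
}

# simulate from the linear-Gaussian state-space model
simulateLG <- function(A, W, H, Q, T, seed = 1) {
  set.seed(seed)
  d <- nrow(A); C <- nrow(H)
  X <- matrix(0, T, d); Y <- matrix(0, T, C)
  x <- c(0, 0)
  cw <- chol(W); cq <- chol(Q)
  for (t in seq_len(T)) {
    x <- as.vector(A %*% x) + as.vector(rnorm(d) %*% cw)
    X[t, ] <- x
    Y[t, ] <- as.vector(H %*% x) + as.vector(rnorm(C) %*% cq)
  }
  list(X = X, Y = Y)
}

# wrap a raw count matrix as a BinnedHD with the given headings
binnedFromCounts <- function(Y, hd_deg = rep(0, nrow(Y)), bin_width_s = 0.2) {
  ids <- sprintf("c%02d", seq_len(ncol(Y)))
  colnames(Y) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(Y)),
    rowData = S4Vectors::DataFrame(cell_id = ids, row.names = ids),
    colData = S4Vectors::DataFrame(
      bin_center_s = (seq_len(nrow(Y)) - 0.5) * bin_width_s,
      hd_deg = hd_deg, valid = rep(TRUE, nrow(Y))))
  new("BinnedHD", se, bin_width_s = bin_width_s)
}
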