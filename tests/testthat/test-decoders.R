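test_that("Kalman MLE recovers generating parameters and degenerates sensibly", {
  ds <- generateDataset(trajectoryConfig(duration_s = 4000, seed = 6),
                        populationConfig(n_cells = 4, seed = 7), "kfrec")
  b <- binDataset(ds@tracking, ds@spikes, 0.2)   # 20,000 bins
  m <- fitDecoder("KF", b)
  # oracle: closed-form least squares computed independently on the same data
  ok <- validBins(b)
  X <- cbind(cos(headingDeg(b)[ok] * pi / 180), sin(headingDeg(b)[ok] * pi / 180))
  X <- sweep(X, 2, colMeans(X))
  A_hat <- t(solve(crossprod(X[-nrow(X), ]), crossprod(X[-nrow(X), ], X[-1, ])))
  expect_equal(unname(m@A), unname(A_hat), tolerance = 1e-8)
  Y <- spikeCounts(b)[ok, ]
  Yc <- sweep(Y, 2, colMeans(Y))
  H_hat <- t(solve(crossprod(X), crossprod(X, Yc)))
  expect_equal(unname(m@H), unname(H_hat), tolerance = 1e-8)
  expect_true(all(eigen(m@W, only.values = TRUE)$values > -1e-12))
  expect_true(all(eigen(m@Q, only.values = TRUE)$values > -1e-10))

  # noiseless integer-linear observations: residual covariance collapses
  hd4 <- rep(c(0, 90, 180, 270), 100)
  cnt <- cbind(a = 5 + 3 * round(cos(hd4 * pi / 180)),
               b = 5 + 2 * round(sin(hd4 * pi / 180)))
  b4 <- binnedFromCounts(cnt, hd4)
  m4 <- fitDecoder("KF", b4)
  expect_lt(max(abs(m4@Q)), 1e-8)

  # constant heading: singular design must error with advice
  cds <- trackFromHeadings(rep(10, 3000), 30)
  csp <- SpikeTrains(list(a = seq(1, 99, by = 0.5)))
  cb <- binDataset(cds, csp, 0.2)
  expect_error(fitDecoder("KF", cb), "coverage")

  # single cell: H is 1 x 2 and the pipeline still runs
  one <- subsetBins(b, cells = 1)
  m1 <- fitDecoder("KF", subsetBins(one, bins = 1:1000))
  expect_equal(dim(m1@H), c(1L, 2L))
  expect_length(predictHeading(m1, subsetBins(one, bins = 1001:1100)), 100L)
})

test_that("Kalman recursion matches a brute-force Bayesian grid filter", {
  A <- diag(c(0.9, 0.85)); W <- diag(c(0.02, 0.03))
  H <- matrix(c(1.0, -0.6, 0.4, 0.9), 2, 2)
  Q <- diag(c(0.2, 0.25))
  sim <- simulateLG(A, W, H, Q, T = 50, seed = 9)
  # integerize the observations (both filter and oracle see the same data;
  # the non-negativity shift is undone by the model's y_mean)
  Yobs <- round(sim$Y)
  model <- new("KFModel", method = "KF", cell_ids = sprintf("c%02d", 1:2),
               x_mean = c(0, 0), y_mean = c(10, 10), A = A, W = W, H = H, Q = Q)
  kf <- predictHeading(model, binnedFromCounts(Yobs + 10L), details = TRUE)
  grid_means <- kfGridFilter(makeGrid(1.6, 0.05), A, W, H, Q, Yobs)
  expect_lt(max(abs(kf$states - grid_means)), 1e-2)
})

test_that("KF posterior collapses onto a constant state under precise observations", {
  x_true <- c(0.6, -0.3)
  H <- diag(100, 2); T <- 40
  set.seed(8)
  Y <- round(matrix(rep(100 * x_true, each = T), T, 2) +
               matrix(rnorm(2 * T, sd = 1), T, 2)) + 200L
  model <- new("KFModel", method = "KF", cell_ids = c("c01", "c02"),
               x_mean = c(0, 0), y_mean = c(200, 200),
               A = diag(2), W = diag(0.01, 2), H = H, Q = diag(1, 2))
  kf <- predictHeading(model, binnedFromCounts(Y), details = TRUE)
  expect_lt(max(abs(kf$states[T, ] - x_true)), 0.01)
})

test_that("Poisson GLM fit recovers intercepts, gains and preferred directions", {
  ds <- benchDataset(n_cells = 6, duration_s = 600, kappa = 4, baseline = 0, seed = 61)
  b <- binDataset(ds@tracking, ds@spikes, 0.2)
  sp <- utLtSplit(ncol(b))
  m <- fitDecoder("GLM", subsetBins(b, bins = sp$UT$train))
  pd_hat <- wrapDeg(atan2(m@gains[, 2], m@gains[, 1]) * 180 / pi)
  err <- abs(rescaleAngle(pd_hat - ds@truth$pd_deg))
  expect_true(all(err < 5))

  # flat cell: gains shrink to 0, intercept to log mean count
  flat <- generateDataset(trajectoryConfig(duration_s = 300, seed = 62),
                          populationConfig(n_cells = 1, kappa_range = c(0, 0),
                                           rate_range = c(10, 10),
                                           baseline_hz = 10, seed = 63), "flat")
  fb <- binDataset(flat@tracking, flat@spikes, 0.2)
  fm <- fitDecoder("GLM", fb)
  expect_lt(sqrt(sum(fm@gains^2)), 0.1)
  expect_equal(fm@mu[1], log(mean(spikeCounts(fb))), tolerance = 0.05)

  # zero-spike cell is refused by name
  z <- flat
  z@spikes <- SpikeTrains(list(hd01 = flat@spikes@spikes[[1]], dead = numeric(0)))
  zb <- binDataset(z@tracking, z@spikes, 0.2)
  expect_error(fitDecoder("GLM", zb), "dead")
})

test_that("GLM coefficients match exact Poisson regression at scale", {
  # counts generated exactly from the log-linear model on a simulated heading
  trk <- simulateTrajectory(trajectoryConfig(duration_s = 4000, seed = 64))
  b <- binDataset(trk, SpikeTrains(list(a = numeric(0))), 0.2)
  ok <- validBins(b)
  hd <- headingDeg(b)[ok]
  X <- cbind(cos(hd * pi / 180), sin(hd * pi / 180))
  Xc <- sweep(X, 2, colMeans(X))
  mu_true <- log(2); a_true <- c(1.1, -0.7)
  set.seed(65)
  Ycounts <- matrix(rpois(nrow(Xc), exp(mu_true + Xc %*% a_true)), ncol = 1)
  bhd <- binnedFromCounts(Ycounts, hd)
  m <- fitDecoder("GLM", bhd)
  expect_lt(abs(m@mu[1] - mu_true) / abs(mu_true), 0.05)
  expect_lt(max(abs(m@gains[1, ] - a_true) / abs(a_true)), 0.05)
})

test_that("point-process filter matches a brute-force grid filter on a toy instance", {
  # random-walk state near the unit circle with informative counts, so the
  # posterior is concentrated and an angle comparison is meaningful
  A <- diag(2); W <- diag(0.002, 2)
  th <- c(20, 110) * pi / 180
  a <- 2.2 * cbind(cos(th), sin(th))
  mu <- c(1.5, 1.2)
  T <- 30
  set.seed(71)
  x <- c(0.8, 0.3); Y <- matrix(0, T, 2)
  for (t in 1:T) {
    x <- as.vector(A %*% x) + rnorm(2, sd = sqrt(diag(W)))
    Y[t, ] <- rpois(2, exp(mu + as.vector(a %*% x)))
  }
  model <- new("GLMModel", method = "GLM", cell_ids = c("c01", "c02"),
               x_mean = c(0, 0), y_mean = c(0, 0), A = A, W = W,
               mu = mu, gains = a)
  ppf <- predictHeading(model, binnedFromCounts(Y), details = TRUE)
  grid_means <- ppfGridFilter(makeGrid(2.0, 0.04), A, W, mu, a, Y)
  hd_ppf <- atan2(ppf$states[, 2], ppf$states[, 1]) * 180 / pi
  hd_grid <- atan2(grid_means[, 2], grid_means[, 1]) * 180 / pi
  expect_lt(max(abs(rescaleAngle(hd_ppf - hd_grid))), 3)

  # zero-gain cells contribute no information: prediction follows the prior
  m0 <- new("GLMModel", method = "GLM", cell_ids = c("c01", "c02"),
            x_mean = c(0.2, 0.1), y_mean = c(0, 0), A = A, W = W,
            mu = mu, gains = matrix(0, 2, 2))
  p0 <- predictHeading(m0, binnedFromCounts(Y), details = TRUE)
  expect_lt(max(abs(p0$states)), 1e-9)  # prior mean is the origin
})

test_that("model tuning curves: GLM log-cosine peaks at the gain direction", {
  m <- new("GLMModel", method = "GLM", cell_ids = "c01",
           x_mean = c(0, 0), y_mean = 0, A = diag(2), W = diag(2),
           mu = 0.5, gains = matrix(c(cos(50 * pi / 180), sin(50 * pi / 180)), 1, 2))
  curve <- modelTuningCurve(m, 1, bin_width_s = 0.2)
  grid <- seq(3, 357, by = 6)
  expect_equal(grid[which.max(curve)], 51)  # nearest bin center to 50 degrees
  # flat cell: constant curve
  mf <- new("GLMModel", method = "GLM", cell_ids = "c01",
            x_mean = c(0, 0), y_mean = 0, A = diag(2), W = diag(2),
            mu = 1, gains = matrix(0, 1, 2))
  expect_equal(diff(range(modelTuningCurve(mf, 1, 0.2))), 0)
})

test_that("GLM model curves beat KF linear curves on Poisson cells", {
  ds <- generateDataset(trajectoryConfig(duration_s = 600, seed = 31),
                        populationConfig(n_cells = 10, seed = 17), "f5")
  st <- trainTestSplit(ds)
  gm <- fitDecoder("GLM", st$train); km <- fitDecoder("KF", st$train)
  grid <- seq(3, 357, by = 6)
  wins <- vapply(seq_len(10), function(c) {
    p <- with(ds@truth[c, ], cellTuningParams(pd_deg, peak_hz, kappa, baseline_hz))
    truth <- tuningRate(p, grid)
    rg <- sqrt(mean((modelTuningCurve(gm, c, 0.2) - truth)^2))
    rk <- sqrt(mean((modelTuningCurve(km, c, 0.2) - truth)^2))
    rg < rk
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("vector reconstruction estimates phases and respects its conic hull", {
  # pure cosine tuning: exact phase recovery through the binned pipeline
  ds <- benchDataset(n_cells = 6, duration_s = 600, kappa = 4, seed = 81)
  st <- trainTestSplit(ds)
  m <- fitDecoder("VR", st$train)
  pd_hat <- wrapDeg(atan2(m@vectors[, 2], m@vectors[, 1]) * 180 / pi)
  err <- abs(rescaleAngle(pd_hat - ds@truth$pd_deg))
  expect_true(all(err < 2))  # cosine fit preserves the phase of a symmetric peak
  expect_equal(unname(sqrt(rowSums(m@vectors^2))), rep(1, 6), tolerance = 1e-12)

  # analytic two-cell toy: single active cell and equal orthogonal firing
  toy <- new("PopVectorModel", method = "VR", cell_ids = c("c01", "c02"),
             x_mean = c(0, 0), y_mean = c(0, 0),
             vectors = rbind(c(1, 0), c(0, 1)), L = matrix(0, 0, 2),
             Qmat = matrix(0, 0, 0))
  R <- rbind(c(5, 0), c(0, 5), c(3, 3), c(0, 0)) / 0.2
  tb <- binnedFromCounts(rbind(c(5, 0), c(0, 5), c(3, 3), c(0, 0)))
  pred <- predictHeading(toy, tb)
  expect_equal(pred[1], 0)
  expect_equal(pred[2], 90)
  expect_equal(pred[3], 45)
  expect_equal(pred[4], 45)            # hold-last on the silent bin
  expect_equal(attr(pred, "held"), 4L)

  # an exactly flat curve (b_c = b_s = 0) is rejected
  hd_sweep <- wrapDeg(seq(0, 719, length.out = 400))
  flatb <- binnedFromCounts(matrix(3L, 400, 1), hd_sweep)
  expect_error(fitDecoder("VR", flatb), "directional modulation")
})

test_that("OLE reduces to scaled center-of-mass vectors in the uncorrelated case", {
  ds <- benchDataset(n_cells = 5, duration_s = 600, seed = 91)
  st <- trainTestSplit(ds)
  m <- fitDecoder("OLE", st$train)
  expect_equal(dim(m@vectors), c(5L, 2L))
  # training-set optimality: OLE squared trig error <= VR's (same linear family)
  vr <- fitDecoder("VR", st$train)
  R <- firingRates(st$train)[validBins(st$train), ]
  hd <- headingDeg(st$train)[validBins(st$train)]
  U <- cbind(cos(hd * pi / 180), sin(hd * pi / 180))
  sse <- function(V) sum((R %*% V - U)^2)
  expect_lte(sse(m@vectors), sse(vr@vectors) + 1e-8)

  # diagonal-Q limit: D parallel to L (single cell)
  one <- subsetBins(st$train, cells = 1)
  m1 <- fitDecoder("OLE", one)
  cosang <- sum(m1@vectors * m1@L) / sqrt(sum(m1@vectors^2) * sum(m1@L^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
})

test_that("Wiener filter and cascade fit, predict, and nest correctly", {
  # rates exactly linear in [cos, sin]: zero training error
  hd <- rep(c(0, 90, 180, 270), 100)
  U <- cbind(cos(hd * pi / 180), sin(hd * pi / 180))
  Yl <- round(U %*% t(matrix(c(2, 1, -1, 3), 2, 2))) + 4L
  bl <- binnedFromCounts(Yl, hd)
  m <- wfFit(bl)
  pred <- predictHeading(m, bl)
  expect_lt(maeDeg(hd, pred), 1e-6)

  # cascade with p = 1 reproduces the filter on linear data
  ds <- benchDataset(n_cells = 8, duration_s = 480, seed = 101)
  st <- trainTestSplit(ds)
  wf <- fitDecoder("WF", st$train)
  wc <- fitDecoder("WC", st$train, max_order = 5)
  expect_true(wc@order %in% 1:5)
  mae_wf <- maeDeg(headingDeg(st$test), predictHeading(wf, st$test))
  mae_wc <- maeDeg(headingDeg(st$test), predictHeading(wc, st$test))
  # the linear model is in the cascade's search space
  expect_lt(mae_wc, mae_wf + 2)
})

test_that("all decoders share the fit/predict contract and are deterministic", {
  ds <- benchDataset(n_cells = 5, duration_s = 300, seed = 111)
  st <- trainTestSplit(ds)
  for (method in modelBasedMethods()) {
    m1 <- fitDecoder(method, st$train)
    m2 <- fitDecoder(method, st$train)
    p1 <- as.numeric(predictHeading(m1, st$test))
    p2 <- as.numeric(predictHeading(m2, st$test))
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 < 360))
    expect_length(p1, ncol(st$test))
  }
  expect_error(fitDecoder("NOPE", st$train), "registry")
})

test_that("VR and OLE predictions rotate with a global heading rotation", {
  ds <- benchDataset(n_cells = 6, duration_s = 300, seed = 121)
  rot <- 90
  ds_rot <- ds
  ds_rot@tracking <- HDTracking(ds@tracking@timestamps,
                                wrapDeg(ds@tracking@hd_deg + rot))
  for (method in c("VR", "OLE")) {
    p0 <- predictHeading(fitDecoder(method, trainTestSplit(ds)$train),
                         trainTestSplit(ds)$test)
    p1 <- predictHeading(fitDecoder(method, trainTestSplit(ds_rot)$train),
                         trainTestSplit(ds_rot)$test)
    expect_lt(stats::median(abs(rescaleAngle(p1 - p0 - rot))), 1.5)
  }
})

test_that("fitted models serialize to JSON and round-trip", {
  ds <- benchDataset(n_cells = 4, duration_s = 300, seed = 131)
  st <- trainTestSplit(ds)
  for (method in c("KF", "GLM", "OLE", "WC")) {
    m <- fitDecoder(method, st$train)
    f <- tempfile(fileext = ".json")
    writeDecoderModel(m, f)
    back <- readDecoderModel(f)
    expect_equal(as.numeric(predictHeading(back, st$test)),
                 as.numeric(predictHeading(m, st$test)), tolerance = 1e-10)
    unlink(f)
  }
})
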