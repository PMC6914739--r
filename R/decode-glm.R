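#' @describeIn fitDecoder Poisson generalized linear model: the same trig
#'   AR(1) state as the Kalman filter, with per-cell counts
#'   \eqn{Y_{t,c} \sim \mathrm{Poisson}(\exp(\mu_c + a_c^T X_t))}
#'   conditionally independent given the state. \eqn{(\mu_c, a_c)} are the
#'   Poisson log-linear maximum-likelihood estimates, obtained per cell by
#'   iteratively reweighted least squares run to convergence (relative
#'   log-likelihood change below 1e-8, at most 100 iterations).
#' @export
glmFit <- function(train, ...) {
  m <- trainMatrices(train)
  st <- fitStateAR(m$X)
  zero <- colSums(m$Y) == 0
  if (any(zero))
    stop("input error: zero-spike cell(s) in training: ",
         paste(colnames(m$Y)[zero], collapse = ", "), call. = FALSE)
  C <- ncol(m$Y)
  mu <- numeric(C); gains <- matrix(0, C, 2)
  D <- cbind(1, m$X)
  for (c in seq_len(C)) {
    fit <- tryCatch(
      stats::glm.fit(D, m$Y[, c], family = stats::poisson(),
                     control = list(epsilon = 1e-8, maxit = 100)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      stop("fit error: Poisson IRLS did not converge for cell ",
           colnames(m$Y)[c], call. = FALSE)
    mu[c] <- fit$coefficients[1]
    gains[c, ] <- fit$coefficients[2:3]
  }
  new("GLMModel", method = "GLM", cell_ids = colnames(m$Y),
      x_mean = m$x_mean, y_mean = m$y_mean,
      A = st$A, W = st$W, mu = mu, gains = gains)
}

#' Model-implied tuning curves of the likelihood-based decoders
#'
#' Evaluates a fitted model's expected spike count as a function of heading
#' on the 60-bin grid, for visual or quantitative comparison with the true
#' tuning function. For the Poisson GLM the curve is
#' \eqn{\hat\lambda(\theta) = \exp(\hat\mu_c + \hat a_c^T X(\theta))}; for
#' the Kalman filter it is the linear observation \eqn{H X(\theta)} plus the
#' mean count, floored at zero (a Gaussian model has no positivity
#' constraint of its own). Counts are divided by the bin width to give Hz.
#'
#' @param model a fitted \linkS4class{GLMModel} or \linkS4class{KFModel}.
#' @param cell cell index or id.
#' @param bin_width_s bin width used to convert counts/bin to spikes/s.
#' @param hd_grid_deg headings at which to evaluate (default the 60 bin
#'   centers).
#' @return numeric vector of model rates (Hz) on the grid.
#' @export
modelTuningCurve <- function(model, cell, bin_width_s,
                             hd_grid_deg = seq(3, 357, by = 6)) {
  if (is.character(cell)) cell <- match(cell, model@cell_ids)
  stopIfNot(is.finite(cell) && cell >= 1 && cell <= length(model@cell_ids),
            "input error: unknown cell")
  X <- sweep(cbind(cos(hd_grid_deg * DEG2RAD), sin(hd_grid_deg * DEG2RAD)),
             2, model@x_mean)
  if (is(model, "GLMModel")) {
    lam <- exp(pmin(model@mu[cell] + X %*% model@gains[cell, ], 30))
  } else if (is(model, "KFModel")) {
    lam <- pmax(X %*% model@H[cell, ] + model@y_mean[cell], 0)
  } else stop("input error: model tuning curves exist for GLM and KF models only")
  as.numeric(lam) / bin_width_s
}

#' @describeIn predictHeading Point-process filter: a recursive Gaussian
#'   approximation to the Bayesian posterior under the Poisson GLM. Predict
#'   as in the Kalman filter; the information update is
#'   \eqn{P^{-1} = \bar P^{-1} + \sum_c \bar\lambda_c a_c a_c^T} with mean
#'   update \eqn{x = \bar x + P \sum_c a_c (y_c - \bar\lambda_c)}, rates
#'   evaluated at the predicted state. Log-rates are clipped to ±30 and the
#'   covariance symmetrized each step.
#' @export
setMethod("predictHeading", signature(model = "GLMModel", test = "BinnedHD"),
  function(model, test, details = FALSE, ...) {
    checkRoster(model, test)
    Y <- spikeCounts(test)
    T <- nrow(Y)
    A <- model@A; W <- model@W; a <- model@gains; mu <- model@mu
    x <- c(0, 0); P <- W
    Xhat <- matrix(0, T, 2)
    for (t in seq_len(T)) {
      xp <- as.vector(A %*% x)
      Pp <- A %*% P %*% t(A) + W
      lam <- exp(pmin(pmax(mu + as.vector(a %*% xp), -30), 30))
      Pinv <- solve(Pp) + crossprod(a * sqrt(lam))
      P <- solve(Pinv)
      P <- (P + t(P)) / 2
      x <- xp + as.vector(P %*% crossprod(a, Y[t, ] - lam))
      if (!all(is.finite(x)))
        stop("fit error: point-process filter diverged at bin ", t, call. = FALSE)
      Xhat[t, ] <- x
    }
    hd <- as.numeric(trigToHeading(Xhat, model@x_mean))
    if (details) list(heading_deg = hd, states = Xhat) else hd
  })
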