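# Shared decoder plumbing ----------------------------------------------------

# Centralized trig-heading design from the valid bins of a BinnedHD:
# X is T x 2 of [cos, sin] minus the training mean ("directional cosines").
trigState <- function(hd_deg, x_mean = NULL) {
  X <- cbind(cos(hd_deg * DEG2RAD), sin(hd_deg * DEG2RAD))
  if (is.null(x_mean)) x_mean <- colMeans(X)
  list(X = sweep(X, 2, x_mean), x_mean = x_mean)
}

# Heading from a de-centralized trig series; zero vectors hold the last
# defined value (flagged via the "held" attribute).
trigToHeading <- function(Xhat, x_mean) {
  V <- sweep(Xhat, 2, x_mean, "+")
  nrm <- sqrt(rowSums(V^2))
  hd <- wrapDeg(atan2(V[, 2], V[, 1]) * RAD2DEG)
  zero <- nrm < 1e-12
  if (any(zero)) {
    last <- wrapDeg(atan2(x_mean[2], x_mean[1]) * RAD2DEG)
    for (i in seq_along(hd)) {
      if (zero[i]) hd[i] <- last else last <- hd[i]
    }
  }
  structure(hd, held = which(zero))
}

trainMatrices <- function(train) {
  ok <- validBins(train)
  stopIfNot(sum(ok) >= 3, "input error: need at least 3 valid training bins")
  Y <- spikeCounts(train)[ok, , drop = FALSE]
  hd <- headingDeg(train)[ok]
  ts <- trigState(hd)
  y_mean <- colMeans(Y)
  list(X = ts$X, x_mean = ts$x_mean, Yc = sweep(Y, 2, y_mean), y_mean = y_mean,
       hd = hd, Y = Y)
}

# state AR(1) closed-form Gaussian MLE shared by the KF and GLM decoders:
# A regresses X_{t+1} on X_t (no intercept; X is centralized), W is the
# residual covariance (MLE denominator n).
fitStateAR <- function(X) {
  T <- nrow(X)
  X1 <- X[-T, , drop = FALSE]
  X2 <- X[-1, , drop = FALSE]
  G <- crossprod(X1)
  if (rcond(G) < 1e-12)
    stop("input error: heading covers too little of the circle to fit the state model; collect more coverage",
         call. = FALSE)
  A <- t(solve(G, crossprod(X1, X2)))
  R <- X2 - X1 %*% t(A)
  W <- crossprod(R) / nrow(R)
  list(A = A, W = W)
}

#' @describeIn fitDecoder Kalman filter: latent centralized trig-heading
#'   AR(1) with linear-Gaussian count observations. The closed-form Gaussian
#'   maximum-likelihood estimates are used: \code{A} regresses the next state
#'   on the current one with residual covariance \code{W}; \code{H}
#'   regresses centralized counts on the state with residual covariance
#'   \code{Q}. No intercepts — both series are centralized.
#' @export
setMethod("fitDecoder", signature(method = "character", train = "BinnedHD"),
  function(method, train, ...) {
    method <- toupper(method)
    fitters <- decoderRegistry()
    stopIfNot(method %in% names(fitters),
              paste0("unknown decoder '", method, "'; registry: ",
                     paste(names(fitters), collapse = ", ")))
    fitters[[method]](train, ...)
  })

kfFit <- function(train, ...) {
  m <- trainMatrices(train)
  st <- fitStateAR(m$X)
  G <- crossprod(m$X)
  H <- t(solve(G, crossprod(m$X, m$Yc)))
  R <- m$Yc - m$X %*% t(H)
  Q <- crossprod(R) / nrow(R)
  new("KFModel", method = "KF", cell_ids = colnames(m$Y),
      x_mean = m$x_mean, y_mean = m$y_mean,
      A = st$A, W = st$W, H = H, Q = Q)
}

checkRoster <- function(model, test) {
  stopIfNot(identical(model@cell_ids, rownames(test)),
            "input error: test cell roster does not match the fitted model")
}

#' @describeIn predictHeading Kalman recursion on centralized test counts:
#'   predict \eqn{\bar x = A x}, \eqn{\bar P = A P A^T + W}; update with gain
#'   \eqn{K = \bar P H^T (H \bar P H^T + Q)^{-1}}. The filter starts at the
#'   centralized mean (\eqn{x_0 = 0}) with \eqn{P_0 = W}; heading is the
#'   two-argument arctangent of the de-centralized state.
#' @export
setMethod("predictHeading", signature(model = "KFModel", test = "BinnedHD"),
  function(model, test, details = FALSE, ...) {
    checkRoster(model, test)
    Y <- sweep(spikeCounts(test), 2, model@y_mean)
    T <- nrow(Y)
    x <- c(0, 0); P <- model@W
    H <- model@H; Q <- model@Q; A <- model@A; W <- model@W
    Xhat <- matrix(0, T, 2)
    for (t in seq_len(T)) {
      xp <- as.vector(A %*% x)
      Pp <- A %*% P %*% t(A) + W
      S <- H %*% Pp %*% t(H) + Q
      K <- Pp %*% t(H) %*% solve(S)
      x <- xp + as.vector(K %*% (Y[t, ] - as.vector(H %*% xp)))
      P <- (diag(2) - K %*% H) %*% Pp
      P <- (P + t(P)) / 2
      Xhat[t, ] <- x
    }
    hd <- as.numeric(trigToHeading(Xhat, model@x_mean))
    if (details) list(heading_deg = hd, states = Xhat) else hd
  })
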