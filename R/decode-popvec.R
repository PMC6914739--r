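# 60-bin tuning summary computed from the training bins themselves (the
# population-vector methods are defined on the binned training data)
binnedTuning <- function(train) {
  ok <- validBins(train)
  hd <- headingDeg(train)[ok]
  R <- firingRates(train)[ok, , drop = FALSE]
  bi <- hdBinIndex(hd)
  dwell <- tabulate(bi, nbins = 60L) * binWidth(train)
  rate <- apply(R, 2, function(r)
    vapply(1:60, function(b) if (dwell[b] > 0) mean(r[bi == b]) else NA_real_,
           numeric(1)))
  list(rate = rate, dwell = dwell, centers = seq(3, 357, by = 6))
}

#' @describeIn fitDecoder Vector reconstruction: per cell a cosine curve
#'   \eqn{b_0 + b_c\cos\theta + b_s\sin\theta} is least-squares fitted to the
#'   binned firing-rate-by-heading curve of the training data; the phase
#'   \eqn{\hat\theta = \mathrm{atan2}(b_s, b_c)} gives the unit
#'   preferred-direction vector. All-flat cells (no directional modulation)
#'   are an error.
#' @export
vrFit <- function(train, ...) {
  bt <- binnedTuning(train)
  ids <- rownames(train)
  vecs <- t(vapply(seq_along(ids), function(c) {
    ok <- is.finite(bt$rate[, c])
    th <- bt$centers[ok] * DEG2RAD
    fit <- stats::lm.fit(cbind(1, cos(th), sin(th)), bt$rate[ok, c])
    b <- fit$coefficients[2:3]
    if (!all(is.finite(b)) || sqrt(sum(b^2)) < 1e-10)
      stop("fit error: cell ", ids[c],
           " has no directional modulation; exclude it before fitting VR",
           call. = FALSE)
    b / sqrt(sum(b^2))
  }, numeric(2)))
  rownames(vecs) <- ids
  m <- trainMatrices(train)
  new("PopVectorModel", method = "VR", cell_ids = ids,
      x_mean = m$x_mean, y_mean = m$y_mean,
      vectors = vecs, L = matrix(0, 0, 2), Qmat = matrix(0, 0, 0))
}

#' @describeIn fitDecoder Optimal linear estimator: per cell the
#'   center-of-mass vector \eqn{L_c = \mathrm{mean}_t\, r_c(t)\,[\cos\phi_t,
#'   \sin\phi_t]} over training bins (the occupancy-weighted center of mass
#'   of the tuning curve), and the uncentered second-moment matrix
#'   \eqn{Q_{ij} = \mathrm{mean}_t\, r_i(t) r_j(t)}, ridge-regularized by
#'   \eqn{10^{-6}\,\mathrm{tr}(Q)/C}. The decoding vectors are
#'   \eqn{D = Q^{-1} L}, the least-squares-optimal linear readout.
#'   \code{use_pearson = TRUE} swaps in the Pearson correlation matrix for
#'   sensitivity analysis.
#' @export
oleFit <- function(train, use_pearson = FALSE, ...) {
  ok <- validBins(train)
  hd <- headingDeg(train)[ok]
  R <- firingRates(train)[ok, , drop = FALSE]
  U <- cbind(cos(hd * DEG2RAD), sin(hd * DEG2RAD))
  L <- crossprod(R, U) / nrow(R)
  Q <- if (use_pearson) stats::cor(R) else crossprod(R) / nrow(R)
  if (any(!is.finite(Q)))
    stop("fit error: degenerate rate matrix (constant cell?) in OLE", call. = FALSE)
  eps <- 1e-6 * sum(diag(Q)) / ncol(Q)
  Qr <- Q + diag(eps, ncol(Q))
  if (rcond(Qr) < 1e-14)
    stop("fit error: rate second-moment matrix singular after regularization",
         call. = FALSE)
  D <- solve(Qr, L)
  ids <- rownames(train)
  rownames(D) <- ids
  m <- trainMatrices(train)
  new("PopVectorModel", method = "OLE", cell_ids = ids,
      x_mean = m$x_mean, y_mean = m$y_mean,
      vectors = D, L = L, Qmat = Qr)
}

#' @describeIn predictHeading Population-vector readout shared by VR and
#'   OLE: \eqn{\phi_{est}(t) = \mathrm{angle}[\sum_c r_c(t) \hat v_c]} with
#'   non-negative rate weights. Bins in which no cell fires give a zero
#'   vector; the prediction holds the last defined value (the equal-weight
#'   population vector direction if it happens at the first bin) and such
#'   bins are flagged in the \code{"held"} attribute.
#' @export
setMethod("predictHeading", signature(model = "PopVectorModel", test = "BinnedHD"),
  function(model, test, ...) {
    checkRoster(model, test)
    R <- firingRates(test)
    V <- R %*% model@vectors
    nrm <- sqrt(rowSums(V^2))
    hd <- wrapDeg(atan2(V[, 2], V[, 1]) * RAD2DEG)
    zero <- nrm < 1e-12
    if (any(zero)) {
      v0 <- colSums(model@vectors)
      last <- wrapDeg(atan2(v0[2], v0[1]) * RAD2DEG)
      for (i in seq_along(hd)) {
        if (zero[i]) hd[i] <- last else last <- hd[i]
      }
    }
    structure(hd, held = which(zero))
  })
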