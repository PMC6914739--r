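lagDesign <- function(R, n_lags) {
  if (n_lags == 0) return(R)
  T <- nrow(R)
  cols <- lapply(0:n_lags, function(l) {
    idx <- pmax(seq_len(T) - l, 1L)   # edge rows repeat the first bin
    R[idx, , drop = FALSE]
  })
  do.call(cbind, cols)
}

wienerLinearFit <- function(D, Yt) {
  fit <- stats::lm.fit(D, Yt)
  B <- fit$coefficients
  if (anyNA(B)) {
    warning("rank-deficient Wiener design; using ridge fallback", call. = FALSE)
    lam <- 1e-6 * sum(diag(crossprod(D))) / ncol(D)
    B <- solve(crossprod(D) + diag(lam, ncol(D)), crossprod(D, Yt))
  }
  B
}

polyApply <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

#' @describeIn fitDecoder Wiener filter: ordinary multiple linear regression
#'   from the per-bin firing-rate vector (optionally augmented with
#'   \code{n_lags} preceding bins) to the centralized trig-heading 2-vector.
#'   The default \code{n_lags = 0} regresses on the same-bin rates only.
#' @export
wfFit <- function(train, n_lags = 0, ...) {
  ok <- validBins(train)
  R <- firingRates(train)[ok, , drop = FALSE]
  stopIfNot(nrow(R) > ncol(R) * (n_lags + 1) + 1,
            "input error: too few training bins for the Wiener design")
  m <- trainMatrices(train)
  D <- cbind(1, lagDesign(R, n_lags))
  B <- wienerLinearFit(D, m$X)
  new("WienerModel", method = "WF", cell_ids = rownames(train),
      x_mean = m$x_mean, y_mean = m$y_mean,
      coef = B, n_lags = n_lags, poly = list(), order = 1)
}

wcValMae <- function(B, polys, Dval, hd_val, x_mean) {
  F <- Dval %*% B
  if (length(polys))
    F <- cbind(polyApply(polys[[1]], F[, 1]), polyApply(polys[[2]], F[, 2]))
  pred <- as.numeric(trigToHeading(F, x_mean))
  maeDeg(hd_val, pred)
}

fitPolyStage <- function(F, Yt, p) {
  lapply(1:2, function(j) {
    D <- vapply(0:p, function(k) F[, j]^k, numeric(nrow(F)))
    b <- stats::lm.fit(D, Yt[, j])$coefficients
    b[is.na(b)] <- 0
    b
  })
}

#' @describeIn fitDecoder Wiener cascade: the Wiener filter followed by a
#'   per-output polynomial of order \code{p} fitted by least squares on the
#'   linear stage's fitted values. \code{p} is selected over
#'   \code{1..max_order} by minimum validation MAE on an inner split (the
#'   last quarter of the training bins); with only five candidates an
#'   exhaustive search replaces surrogate-based optimization. Both stages
#'   are refitted on the full training set at the selected order.
#' @export
wcFit <- function(train, max_order = 5, n_lags = 0, ...) {
  ok <- validBins(train)
  R <- firingRates(train)[ok, , drop = FALSE]
  hd <- headingDeg(train)[ok]
  Tn <- nrow(R)
  stopIfNot(Tn > ncol(R) * (n_lags + 1) + max_order + 2,
            "input error: too few training bins for the cascade design")
  n_tr <- max(ceiling(0.75 * Tn), ncol(R) * (n_lags + 1) + 2)
  idx_tr <- seq_len(n_tr); idx_va <- setdiff(seq_len(Tn), idx_tr)
  if (!length(idx_va)) { idx_va <- idx_tr }  # degenerate tiny input

  tsAll <- trigState(hd)
  ts_tr <- trigState(hd[idx_tr])
  D_tr <- cbind(1, lagDesign(R[idx_tr, , drop = FALSE], n_lags))
  D_va <- cbind(1, lagDesign(R, n_lags))[idx_va, , drop = FALSE]
  Yt_tr <- ts_tr$X
  B1 <- wienerLinearFit(D_tr, Yt_tr)
  F_tr <- D_tr %*% B1

  val_mae <- vapply(1:max_order, function(p) {
    polys <- fitPolyStage(F_tr, Yt_tr, p)
    wcValMae(B1, polys, D_va, hd[idx_va], ts_tr$x_mean)
  }, numeric(1))
  p_best <- which.min(val_mae)

  # refit both stages on the full training data at the selected order
  D <- cbind(1, lagDesign(R, n_lags))
  B <- wienerLinearFit(D, tsAll$X)
  polys <- fitPolyStage(D %*% B, tsAll$X, p_best)
  m <- trainMatrices(train)
  new("WienerModel", method = "WC", cell_ids = rownames(train),
      x_mean = m$x_mean, y_mean = m$y_mean,
      coef = B, n_lags = n_lags, poly = polys, order = p_best)
}

#' @describeIn predictHeading Wiener filter/cascade: apply the linear map
#'   (and, for the cascade, the per-output polynomial) to the test rate
#'   vectors, de-centralize by the training trig mean, and take the
#'   two-argument arctangent.
#' @export
setMethod("predictHeading", signature(model = "WienerModel", test = "BinnedHD"),
  function(model, test, ...) {
    checkRoster(model, test)
    R <- firingRates(test)
    D <- cbind(1, lagDesign(R, model@n_lags))
    F <- D %*% model@coef
    if (length(model@poly))
      F <- cbind(polyApply(model@poly[[1]], F[, 1]),
                 polyApply(model@poly[[2]], F[, 2]))
    as.numeric(trigToHeading(F, model@x_mean))
  })
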