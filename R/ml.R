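#' Machine-learning decoder adapters
#'
#' Thin wrappers giving machine-learning regressors the same contract as the
#' model-based decoders: train on the centralized trig-heading targets, pick
#' hyperparameters on an inner validation split (the last quarter of the
#' training bins) by random search over a small space, predict the test
#' bins and convert back through the two-argument arctangent. Backends:
#' \code{SVR} uses \pkg{e1071} (radial-basis kernel), \code{XGB} uses
#' \pkg{xgboost} (trees, depth and learning rate searched), \code{FFNN}
#' uses \pkg{nnet} (a single hidden layer — the only feedforward network
#' available here — with weight decay in place of dropout). The recurrent
#' methods \code{RNN}, \code{GRU} and \code{LSTM} have no installed R
#' backend and raise a capability error naming the missing engine. No part
#' of the core pipeline depends on these adapters.
#'
#' @param method one of \code{mlMethods()}.
#' @param train,test \linkS4class{BinnedHD} objects sharing a cell roster.
#' @param search_budget candidate configurations to evaluate (>= 1; 1 means
#'   no search).
#' @param seed integer seed; fixes the search trajectory.
#' @return a list: \code{predicted_deg} on the test bins, \code{method},
#'   \code{hyperparameters} chosen, \code{val_mae_deg}.
#' @export
mlFitPredict <- function(method, train, test, search_budget = 10, seed = 1L) {
  method <- toupper(method)
  stopIfNot(method %in% mlMethods(), "input error: unknown ML method")
  stopIfNot(search_budget >= 1, "input error: search_budget must be >= 1")
  if (method %in% c("RNN", "GRU", "LSTM"))
    stop("capability error: ", method,
         " needs a recurrent-network backend (keras/torch), which is not installed",
         call. = FALSE)
  pkg <- c(SVR = "e1071", XGB = "xgboost", FFNN = "nnet")[[method]]
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("capability error: method ", method, " requires the optional package '",
         pkg, "'", call. = FALSE)

  ok <- validBins(train)
  R <- firingRates(train)[ok, , drop = FALSE]
  hd <- headingDeg(train)[ok]
  ts <- trigState(hd)
  Tn <- nrow(R)
  n_tr <- ceiling(0.75 * Tn)
  i_tr <- seq_len(n_tr); i_va <- setdiff(seq_len(Tn), i_tr)
  if (!length(i_va)) i_va <- i_tr

  space <- mlSearchSpace(method)
  withSeed(seed, {
    cands <- lapply(seq_len(search_budget), function(i)
      lapply(space, function(rng) {
        if (is.list(rng)) sample(rng, 1)[[1]]
        else if (is.integer(rng)) sample(seq(rng[1], rng[2]), 1)
        else stats::runif(1, rng[1], rng[2])
      }))
    val <- vapply(cands, function(hp) {
      fit <- mlTrain(method, R[i_tr, , drop = FALSE], ts$X[i_tr, , drop = FALSE], hp)
      pv <- mlPredictTrig(method, fit, R[i_va, , drop = FALSE])
      maeDeg(hd[i_va], as.numeric(trigToHeading(pv, ts$x_mean)))
    }, numeric(1))
    best <- cands[[which.min(val)]]
    fit <- mlTrain(method, R, ts$X, best)
    Rtest <- firingRates(test)
    pred <- as.numeric(trigToHeading(mlPredictTrig(method, fit, Rtest), ts$x_mean))
  })
  list(predicted_deg = pred, method = method, hyperparameters = best,
       val_mae_deg = min(val))
}

#' @rdname mlFitPredict
#' @export
mlMethods <- function() c("SVR", "XGB", "FFNN", "RNN", "GRU", "LSTM")

mlSearchSpace <- function(method) {
  switch(method,
    SVR = list(cost = c(0.1, 30), gamma_scale = c(0.2, 3)),
    XGB = list(nrounds = as.integer(c(20L, 150L)), max_depth = as.integer(c(2L, 6L)),
               eta = c(0.03, 0.4)),
    FFNN = list(size = as.integer(c(4L, 32L)), decay = c(1e-4, 0.3),
                maxit = as.integer(c(100L, 400L))))
}

mlTrain <- function(method, R, Yt, hp) {
  switch(method,
    SVR = lapply(1:2, function(j)
      e1071::svm(R, Yt[, j], kernel = "radial", cost = hp$cost,
                 gamma = hp$gamma_scale / ncol(R))),
    XGB = lapply(1:2, function(j)
      xgboost::xgboost(R, Yt[, j], nrounds = hp$nrounds,
                       max_depth = hp$max_depth, learning_rate = hp$eta,
                       objective = "reg:squarederror", verbosity = 0,
                       nthreads = 1)),
    FFNN = lapply(1:2, function(j)
      nnet::nnet(R, Yt[, j], size = hp$size, decay = hp$decay,
                 maxit = hp$maxit, linout = TRUE, trace = FALSE)))
}

mlPredictTrig <- function(method, fit, R) {
  cbind(as.numeric(stats::predict(fit[[1]], R)),
        as.numeric(stats::predict(fit[[2]], R)))
}
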