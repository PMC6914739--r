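#' Circular decoding error metrics
#'
#' Per-bin errors are the absolute value of the angle difference after
#' rescaling to \code{[-180, 180]} degrees (\code{\link{rescaleAngle}}); the
#' median absolute error (MAE) is robust to the occasional large flip,
#' while the average absolute error (AAE) is sensitive to outliers — the
#' reason MAE is the headline accuracy measure. Bins with \code{NA} in
#' either series are excluded.
#'
#' @param true_deg,pred_deg equal-length heading series, degrees.
#' @return error in degrees, in \code{[0, 180]}.
#' @examples
#' maeDeg(10, 350)  # 20
#' @export
maeDeg <- function(true_deg, pred_deg) {
  stats::median(absErrDeg(true_deg, pred_deg), na.rm = TRUE)
}

#' @rdname maeDeg
#' @export
aaeDeg <- function(true_deg, pred_deg) {
  mean(absErrDeg(true_deg, pred_deg), na.rm = TRUE)
}

absErrDeg <- function(true_deg, pred_deg) {
  stopIfNot(length(true_deg) == length(pred_deg),
            "input error: series lengths differ")
  e <- abs(rescaleAngle(true_deg - pred_deg))
  if (all(is.na(e))) stop("input error: no overlapping valid bins", call. = FALSE)
  e
}

#' Contiguous upper/lower train-test splits
#'
#' The session's bins are split contiguously: \code{UT} trains on the first
#' \eqn{\lceil 3T/4 \rceil} bins and tests on the remainder; \code{LT}
#' trains on the last \eqn{\lceil 3T/4 \rceil} and tests on the first
#' remainder. Contiguity matters because both the data and the state-space
#' models are time series — a held-out middle block would break the training
#' sequence.
#'
#' @param n_bins total number of bins \code{T}.
#' @return a list with elements \code{UT} and \code{LT}, each a list of
#'   integer vectors \code{train} and \code{test}.
#' @export
utLtSplit <- function(n_bins) {
  stopIfNot(n_bins >= 2, "input error: need at least 2 bins to split")
  k <- ceiling(3 * n_bins / 4)
  test_ut <- if (k < n_bins) seq.int(k + 1L, n_bins) else integer(0)
  list(UT = list(train = seq_len(k), test = test_ut),
       LT = list(train = seq.int(n_bins - k + 1L, n_bins),
                 test = seq_len(n_bins - k)))
}

#' Decode one dataset with one method and score the result
#'
#' The full pipeline for a single (dataset, method, split) cell of the
#' benchmark: bin the session, restrict to the decoding roster (classified
#' HD cells by default, or all cells), split contiguously, fit on the
#' training bins only — all centering statistics and tuning summaries come
#' from the training span, never the test span — predict the test bins and
#' score MAE/AAE over the valid ones.
#'
#' @param dataset an \linkS4class{HDDataset}.
#' @param method a registry tag (see \code{\link{decoderRegistry}}).
#' @param split \code{"UT"} or \code{"LT"}.
#' @param bin_width_s decoding bin width, seconds (default 0.2).
#' @param cells \code{"hd"} to decode with classified HD cells only
#'   (classification scores are taken from \code{scores}, or the ground
#'   truth for synthetic data, or computed), \code{"all"} for every cell, or
#'   a character vector of cell ids.
#' @param scores optional precomputed \code{\link{classifyHDCells}} table.
#' @param ... extra arguments to the decoder's fitting function.
#' @return a \linkS4class{DecodeResult}.
#' @export
runDecoding <- function(dataset, method, split = "UT", bin_width_s = 0.2,
                        cells = "hd", scores = NULL, ...) {
  stopIfNot(split %in% c("UT", "LT"), "input error: split must be 'UT' or 'LT'")
  roster <- decodingRoster(dataset, cells, scores)
  stopIfNot(length(roster) >= 1, "input error: no cells left to decode with")
  binned <- binDataset(dataset@tracking, dataset@spikes, bin_width_s)
  binned <- subsetBins(binned, cells = roster)
  sp <- utLtSplit(ncol(binned))[[split]]
  train <- subsetBins(binned, bins = sp$train)
  test <- subsetBins(binned, bins = sp$test)
  model <- withCallingHandlers(
    fitDecoder(method, train, ...),
    error = function(e) stop(sprintf("[%s/%s/%s] %s", dataset@dataset_id,
                                     method, split, conditionMessage(e)),
                             call. = FALSE))
  pred <- predictHeading(model, test)
  truth <- headingDeg(test)
  ok <- validBins(test) & is.finite(truth)
  err <- rep(NA_real_, length(truth))
  err[ok] <- abs(rescaleAngle(truth[ok] - pred[ok]))
  new("DecodeResult", dataset_id = dataset@dataset_id, method = toupper(method),
      split = split, predicted_deg = pred,
      true_deg = as.numeric(truth), abs_err_deg = err,
      mae_deg = stats::median(err[ok]), aae_deg = mean(err[ok]),
      n_test_bins = sum(ok), n_excluded = sum(!ok),
      n_cells = length(roster))
}

decodingRoster <- function(dataset, cells, scores) {
  if (is.character(cells) && length(cells) > 1) return(cells)
  if (identical(cells, "all")) return(cellIds(dataset@spikes))
  stopIfNot(identical(cells, "hd"), "input error: cells must be 'hd', 'all' or ids")
  if (!is.null(scores)) return(scores$cell_id[scores$is_hd])
  if (!is.null(dataset@truth)) return(dataset@truth$cell_id[dataset@truth$is_hd])
  sc <- classifyHDCells(dataset)
  sc$cell_id[sc$is_hd]
}
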