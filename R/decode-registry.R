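#' Decoder registry
#'
#' Maps method tags to fitting functions. The six statistical model-based
#' decoders are always available: \code{KF} (Kalman filter), \code{GLM}
#' (Poisson GLM + point-process filter), \code{VR} (vector reconstruction),
#' \code{OLE} (optimal linear estimator), \code{WF} (Wiener filter) and
#' \code{WC} (Wiener cascade). Machine-learning adapters (\code{SVR},
#' \code{XGB}, \code{FFNN}, \code{RNN}, \code{GRU}, \code{LSTM}) are listed
#' by \code{mlMethods()} and dispatched through \code{\link{mlFitPredict}};
#' they require optional packages.
#'
#' @return named list of fitting functions, each taking
#'   \code{(train, ...)} and returning an \linkS4class{HDDecoderModel}.
#' @export
decoderRegistry <- function() {
  list(KF = kfFit, GLM = glmFit, VR = vrFit, OLE = oleFit,
       WF = wfFit, WC = wcFit)
}

#' @rdname decoderRegistry
#' @export
modelBasedMethods <- function() names(decoderRegistry())

#' Serialize / restore a fitted decoder as JSON
#'
#' Matrices are stored row-major with explicit dimensions, so models
#' round-trip losslessly across sessions.
#'
#' @param model a fitted \linkS4class{HDDecoderModel}.
#' @param path output path.
#' @return \code{writeDecoderModel} returns \code{path} invisibly;
#'   \code{readDecoderModel} the restored model.
#' @export
writeDecoderModel <- function(model, path) {
  mat <- function(M) list(dim = dim(M), data = as.vector(t(M)))
  sl <- setdiff(slotNames(class(model)), c("method", "cell_ids", "x_mean", "y_mean"))
  payload <- list(class = as.character(class(model)), method = model@method,
                  cell_ids = model@cell_ids, x_mean = model@x_mean,
                  y_mean = model@y_mean)
  for (s in sl) {
    v <- slot(model, s)
    payload[[s]] <- if (is.matrix(v)) mat(v) else v
  }
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeDecoderModel
#' @export
readDecoderModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  unmat <- function(m) matrix(m$data, nrow = m$dim[1], ncol = m$dim[2], byrow = TRUE)
  cls <- p$class
  args <- list(Class = cls, method = p$method, cell_ids = as.character(p$cell_ids),
               x_mean = as.numeric(p$x_mean), y_mean = as.numeric(p$y_mean))
  for (s in setdiff(slotNames(cls), names(args)[-1])) {
    v <- p[[s]]
    args[[s]] <- if (is.list(v) && !is.null(v$dim)) unmat(v)
      else if (s == "poly") {
        # jsonlite may simplify the per-output coefficient lists to a matrix
        if (is.matrix(v)) lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
        else lapply(v, as.numeric)
      }
      else if (s %in% c("n_lags", "order")) as.numeric(v)
      else v
  }
  if (!is.null(args$vectors)) rownames(args$vectors) <- args$cell_ids
  do.call(new, args)
}
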