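#' Fit a heading decoder to a training dataset
#'
#' Every decoder in the registry obeys one contract: \code{fitDecoder} takes a
#' method tag and a training \linkS4class{BinnedHD} and returns a fitted model
#' object; \code{\link{predictHeading}} maps a fitted model and a test
#' \linkS4class{BinnedHD} to a heading series in degrees in \code{[0, 360)}.
#' The model-based decoders are deterministic given the data.
#'
#' @param method a method tag (see \code{\link{decoderRegistry}}) or a
#'   \linkS4class{DecoderSpec}.
#' @param train a \linkS4class{BinnedHD} of training bins.
#' @param ... method-specific options (e.g. \code{n_lags} for the Wiener
#'   filter, \code{max_order} for the Wiener cascade).
#' @return a fitted decoder object (subclass of \linkS4class{HDDecoderModel}).
#' @seealso \code{\link{predictHeading}}, \code{\link{runDecoding}}
#' @export
setGeneric("fitDecoder", function(method, train, ...) standardGeneric("fitDecoder"))

#' Predict a heading series from a fitted decoder
#'
#' @param model a fitted decoder returned by \code{\link{fitDecoder}}.
#' @param test a \linkS4class{BinnedHD} with the same cell roster as the
#'   training data.
#' @param ... unused.
#' @return numeric vector of predicted headings in degrees in \code{[0, 360)},
#'   one per test bin.
#' @export
setGeneric("predictHeading", function(model, test, ...) standardGeneric("predictHeading"))

#' @rdname BinnedHD-class
#' @param x a \code{BinnedHD}.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedHD-class
#' @export
setGeneric("headingDeg", function(x) standardGeneric("headingDeg"))

#' @rdname BinnedHD-class
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname BinnedHD-class
#' @export
setGeneric("firingRates", function(x) standardGeneric("firingRates"))

#' @rdname BinnedHD-class
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))
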