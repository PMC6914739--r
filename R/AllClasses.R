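#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Head-direction tracking series
#'
#' Timestamped heading at video frame rate (30--60 Hz), optionally carrying
#' the raw two-LED pixel coordinates the heading was derived from. Frames in
#' which the tracker lost the animal carry \code{NA} heading and are excluded
#' from occupancy, tuning curves and decoder training.
#'
#' @slot timestamps numeric, strictly increasing, seconds.
#' @slot hd_deg numeric, heading per frame in degrees in \code{[0, 360)};
#'   \code{NA} marks a lost frame.
#' @slot red_xy,green_xy optional per-frame LED pixel coordinates (n x 2
#'   matrices) or \code{NULL}.
#' @seealso \code{\link{simulateTrajectory}}, \code{\link{readTracking}},
#'   \code{\link{hdFromLeds}}
#' @export
setClass("HDTracking",
  representation(timestamps = "numeric", hd_deg = "numeric",
                 red_xy = "matrixOrNULL", green_xy = "matrixOrNULL"),
  prototype(red_xy = NULL, green_xy = NULL))

setValidity("HDTracking", function(object) {
  msgs <- character()
  n <- length(object@timestamps)
  if (length(object@hd_deg) != n)
    msgs <- c(msgs, "hd_deg and timestamps must have equal length")
  if (n > 1 && any(diff(object@timestamps) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  hd <- object@hd_deg[is.finite(object@hd_deg)]
  if (length(hd) && (any(hd < 0) || any(hd >= 360)))
    msgs <- c(msgs, "hd_deg must lie in [0, 360)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an HDTracking object
#'
#' @param timestamps numeric seconds, strictly increasing.
#' @param hd_deg headings in degrees; wrapped to \code{[0, 360)}.
#' @param red_xy,green_xy optional n x 2 LED coordinate matrices.
#' @return an \linkS4class{HDTracking}.
#' @export
HDTracking <- function(timestamps, hd_deg, red_xy = NULL, green_xy = NULL) {
  new("HDTracking", timestamps = as.numeric(timestamps),
      hd_deg = wrapDeg(as.numeric(hd_deg)), red_xy = red_xy, green_xy = green_xy)
}

setMethod("show", "HDTracking", function(object) {
  n <- length(object@timestamps)
  dur <- if (n) diff(range(object@timestamps)) else 0
  cat(sprintf("HDTracking: %d frames over %.1f s (%.1f Hz nominal), %d lost\n",
              n, dur, if (n > 1) (n - 1) / dur else NA_real_,
              sum(!is.finite(object@hd_deg))))
})

#' Spike trains for a recorded population
#'
#' Per-cell sorted spike timestamps (seconds) within the session bounds.
#'
#' @slot spikes named list of sorted numeric vectors, one per cell.
#' @export
setClass("SpikeTrains", representation(spikes = "list"))

setValidity("SpikeTrains", function(object) {
  msgs <- character()
  if (is.null(names(object@spikes)) && length(object@spikes))
    msgs <- c(msgs, "spike trains must be named by cell id")
  for (nm in names(object@spikes)) {
    s <- object@spikes[[nm]]
    if (!is.numeric(s)) msgs <- c(msgs, paste0(nm, ": not numeric"))
    else {
      if (is.unsorted(s)) msgs <- c(msgs, paste0(nm, ": spike times not sorted"))
      if (length(s) && any(s < 0)) msgs <- c(msgs, paste0(nm, ": negative spike times"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @param spikes named list of numeric spike-time vectors (seconds).
#' @return a \linkS4class{SpikeTrains}.
#' @rdname SpikeTrains-class
#' @export
SpikeTrains <- function(spikes) {
  spikes <- lapply(spikes, function(s) sort(as.numeric(s)))
  if (is.null(names(spikes)))
    names(spikes) <- sprintf("cell%02d", seq_along(spikes))
  new("SpikeTrains", spikes = spikes)
}

#' @rdname SpikeTrains-class
#' @param x a \code{SpikeTrains}.
#' @export
cellIds <- function(x) names(x@spikes)

#' @rdname SpikeTrains-class
#' @export
nCells <- function(x) length(x@spikes)

setMethod("show", "SpikeTrains", function(object) {
  ns <- vapply(object@spikes, length, integer(1))
  cat(sprintf("SpikeTrains: %d cells, %d spikes total\n", length(ns), sum(ns)))
})

#' Occupancy-normalized directional tuning curve
#'
#' Firing rate as a function of heading in sixty 6-degree bins: the rate in a
#' bin is the spike count divided by the dwell time. Bins the animal never
#' occupied have undefined rate (\code{NA}), never silently zero.
#'
#' @slot cell_id character.
#' @slot bin_centers_deg the 60 bin centers (3, 9, ..., 357 degrees).
#' @slot rate_hz spikes/s per bin; \code{NA} where dwell is 0.
#' @slot dwell_s seconds of occupancy per bin.
#' @slot spike_count spikes per bin.
#' @seealso \code{\link{tuningCurve}}, \code{\link{meanVectorLength}}
#' @export
setClass("TuningCurve",
  representation(cell_id = "character", bin_centers_deg = "numeric",
                 rate_hz = "numeric", dwell_s = "numeric", spike_count = "numeric"))

setValidity("TuningCurve", function(object) {
  msgs <- character()
  if (length(object@bin_centers_deg) != 60L)
    msgs <- c(msgs, "a tuning curve has exactly 60 bins")
  for (sl in c("rate_hz", "dwell_s", "spike_count"))
    if (length(slot(object, sl)) != 60L) msgs <- c(msgs, paste0(sl, " must have 60 bins"))
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TuningCurve", function(object) {
  cat(sprintf("TuningCurve [%s]: peak %.2f Hz at %g deg, %d spikes, %d unoccupied bins\n",
              object@cell_id,
              suppressWarnings(max(object@rate_hz, na.rm = TRUE)),
              object@bin_centers_deg[which.max(object@rate_hz)],
              as.integer(sum(object@spike_count)),
              sum(object@dwell_s == 0)))
})

#' Time-binned population dataset
#'
#' A \linkS4class{SummarizedExperiment} with cells as rows and time bins as
#' columns. The \code{"counts"} assay holds non-negative integer spike counts;
#' \code{colData} carries the bin centers (s), the per-bin heading (circular
#' mean of member frames, degrees) and a validity mask (bins with more than
#' half their frames lost are invalid and excluded from fitting and scoring).
#'
#' Accessors: \code{binWidth} (s), \code{headingDeg} (per-bin heading),
#' \code{spikeCounts} (bins x cells matrix), \code{firingRates}
#' (counts / bin width, Hz) and \code{validBins} (logical mask).
#'
#' @seealso \code{\link{binDataset}}
#' @aliases binWidth headingDeg spikeCounts firingRates validBins
#' @export
setClass("BinnedHD", contains = "SummarizedExperiment",
         representation(bin_width_s = "numeric"))

setValidity("BinnedHD", function(object) {
  msgs <- character()
  cts <- assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    msgs <- c(msgs, "counts must be non-negative integers")
  need <- c("bin_center_s", "hd_deg", "valid")
  if (!all(need %in% colnames(colData(object))))
    msgs <- c(msgs, "colData must have bin_center_s, hd_deg, valid")
  if (length(object@bin_width_s) != 1L || object@bin_width_s <= 0)
    msgs <- c(msgs, "bin_width_s must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' @rdname BinnedHD-class
#' @export
setMethod("binWidth", "BinnedHD", function(x) x@bin_width_s)

#' @rdname BinnedHD-class
#' @export
setMethod("headingDeg", "BinnedHD", function(x) colData(x)$hd_deg)

#' @rdname BinnedHD-class
#' @export
setMethod("spikeCounts", "BinnedHD", function(x) t(assay(x, "counts")))

#' @rdname BinnedHD-class
#' @export
setMethod("firingRates", "BinnedHD", function(x) t(assay(x, "counts")) / x@bin_width_s)

#' @rdname BinnedHD-class
#' @export
setMethod("validBins", "BinnedHD", function(x) colData(x)$valid)

setMethod("show", "BinnedHD", function(object) {
  cat(sprintf("BinnedHD: %d cells x %d bins of %.3g s (%d invalid bins)\n",
              nrow(object), ncol(object), object@bin_width_s,
              sum(!colData(object)$valid)))
})

#' A simulated or loaded HD-cell dataset
#'
#' Bundles a tracking series and spike trains; for synthetic data the
#' generating per-cell tuning parameters are retained as ground truth for
#' parameter-recovery tests.
#'
#' @slot dataset_id character label.
#' @slot tracking an \linkS4class{HDTracking}.
#' @slot spikes a \linkS4class{SpikeTrains}.
#' @slot truth \code{data.frame} of generating parameters (one row per cell:
#'   \code{cell_id}, \code{pd_deg}, \code{peak_hz}, \code{baseline_hz},
#'   \code{kappa}, \code{is_hd}) or \code{NULL} for real data.
#' @slot config list echoing the generating configuration (seeds included).
#' @seealso \code{\link{generateDataset}}
#' @export
setClass("HDDataset",
  representation(dataset_id = "character", tracking = "HDTracking",
                 spikes = "SpikeTrains", truth = "dfOrNULL", config = "list"),
  prototype(truth = NULL, config = list()))

setMethod("show", "HDDataset", function(object) {
  cat(sprintf("HDDataset '%s': %d cells, %.1f min session%s\n",
              object@dataset_id, nCells(object@spikes),
              diff(range(object@tracking@timestamps)) / 60,
              if (is.null(object@truth)) "" else " (ground truth retained)"))
})

#' Fitted decoder models
#'
#' \code{HDDecoderModel} is the virtual parent of all fitted decoders. Each
#' subclass stores the parameters its method needs plus the training-set
#' centering statistics (trig-heading mean and per-cell mean counts) so that
#' prediction never touches test-set statistics.
#'
#' @slot method registry tag (\code{"KF"}, \code{"GLM"}, \code{"VR"},
#'   \code{"OLE"}, \code{"WF"}, \code{"WC"}).
#' @slot cell_ids training cell roster, enforced at prediction time.
#' @slot x_mean length-2 mean of the training \code{[cos, sin]} vectors.
#' @slot y_mean per-cell mean training counts.
#' @export
setClass("HDDecoderModel", representation("VIRTUAL",
  method = "character", cell_ids = "character",
  x_mean = "numeric", y_mean = "numeric"))

#' @rdname HDDecoderModel-class
#' @slot A 2x2 state-transition matrix of the latent trig-heading AR(1).
#' @slot W 2x2 state-noise covariance.
#' @slot H cells x 2 observation matrix (Kalman filter only).
#' @slot Q cells x cells observation-noise covariance (Kalman filter only).
#' @export
setClass("KFModel", contains = "HDDecoderModel",
  representation(A = "matrix", W = "matrix", H = "matrix", Q = "matrix"))

#' @rdname HDDecoderModel-class
#' @slot mu per-cell log-rate intercepts (Poisson GLM).
#' @slot gains cells x 2 matrix of trig-heading gain vectors (Poisson GLM).
#' @export
setClass("GLMModel", contains = "HDDecoderModel",
  representation(A = "matrix", W = "matrix", mu = "numeric", gains = "matrix"))

#' @rdname HDDecoderModel-class
#' @slot vectors cells x 2 decoding vectors: unit preferred-direction vectors
#'   for vector reconstruction, optimal vectors for the OLE.
#' @slot L cells x 2 center-of-mass vectors (OLE only).
#' @slot Qmat cells x cells rate second-moment matrix (OLE only).
#' @export
setClass("PopVectorModel", contains = "HDDecoderModel",
  representation(vectors = "matrix", L = "matrix", Qmat = "matrix"))

#' @rdname HDDecoderModel-class
#' @slot coef regression coefficients (intercept + lagged rates) x 2 outputs.
#' @slot n_lags number of preceding bins appended to the rate vector.
#' @slot poly list of per-output polynomial coefficients (Wiener cascade).
#' @slot order selected polynomial order (1 for the plain Wiener filter).
#' @export
setClass("WienerModel", contains = "HDDecoderModel",
  representation(coef = "matrix", n_lags = "numeric", poly = "list",
                 order = "numeric"))

setMethod("show", "HDDecoderModel", function(object) {
  cat(sprintf("<%s> fitted %s decoder, %d cells\n", class(object)[1],
              object@method, length(object@cell_ids)))
})

#' Result of one decode-and-score run
#'
#' @slot dataset_id,method,split identifying metadata (split is \code{"UT"}
#'   or \code{"LT"}).
#' @slot predicted_deg,true_deg heading series on the test span, degrees.
#' @slot abs_err_deg per-bin absolute rescaled error, degrees in
#'   \code{[0, 180]}; \code{NA} on invalid bins.
#' @slot mae_deg median of the valid errors; \code{aae_deg} their mean.
#' @slot n_test_bins valid test bins scored; \code{n_excluded} dropped.
#' @slot n_cells cells used by the decoder.
#' @seealso \code{\link{runDecoding}}, \code{\link{resultsTable}}
#' @export
setClass("DecodeResult",
  representation(dataset_id = "character", method = "character",
                 split = "character", predicted_deg = "numeric",
                 true_deg = "numeric", abs_err_deg = "numeric",
                 mae_deg = "numeric", aae_deg = "numeric",
                 n_test_bins = "integer", n_excluded = "integer",
                 n_cells = "integer"))

setMethod("show", "DecodeResult", function(object) {
  cat(sprintf("DecodeResult %s/%s/%s: MAE %.1f deg, AAE %.1f deg (%d test bins)\n",
              object@dataset_id, object@method, object@split,
              object@mae_deg, object@aae_deg, object@n_test_bins))
})

#' Collapse decode results into a results table
#'
#' @param results a list of \linkS4class{DecodeResult} objects.
#' @return a \code{data.frame} with one row per result: dataset, method,
#'   split, cell count, MAE, AAE, test-bin count.
#' @export
resultsTable <- function(results) {
  if (is(results, "DecodeResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(dataset_id = r@dataset_id, method = r@method, split = r@split,
               n_cells = r@n_cells, mae_deg = r@mae_deg, aae_deg = r@aae_deg,
               n_test_bins = r@n_test_bins, stringsAsFactors = FALSE)
  }))
}
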