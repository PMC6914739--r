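#' Bin a tracking + spikes session into a population count matrix
#'
#' Time is divided into half-open bins \code{[t, t + bin_width_s)} starting
#' at the first video frame and covering the whole session (a spike exactly
#' on a boundary goes to the later bin). Each bin's heading is the circular
#' mean of its member frames; bins with more than half their frames lost to
#' tracking (or with no frames) are masked invalid. Binning conserves spikes:
#' the count matrix total over valid plus invalid bins equals the number of
#' session spikes.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param spikes a \linkS4class{SpikeTrains}.
#' @param bin_width_s bin width in seconds, at least one frame interval.
#'   The default 0.2 s matches the angular-velocity analysis bin.
#' @return a \linkS4class{BinnedHD}.
#' @export
binDataset <- function(track, spikes, bin_width_s = 0.2) {
  ts <- track@timestamps
  stopIfNot(length(ts) > 0, "input error: empty tracking")
  dts <- diff(ts)
  dt_med <- if (length(dts)) stats::median(dts) else bin_width_s
  stopIfNot(bin_width_s >= dt_med - 1e-9,
            "input error: bin_width_s must be at least one frame interval")
  t0 <- ts[1]
  t_end <- ts[length(ts)] + dt_med        # session runs through the last frame
  n_bins <- max(1L, ceiling((t_end - t0) / bin_width_s - 1e-9))
  edges <- t0 + (0:n_bins) * bin_width_s

  frame_bin <- findInterval(ts, edges, rightmost.closed = FALSE)
  hd_bin <- vapply(seq_len(n_bins), function(b) {
    circMeanDeg(track@hd_deg[frame_bin == b])
  }, numeric(1))
  valid <- vapply(seq_len(n_bins), function(b) {
    h <- track@hd_deg[frame_bin == b]
    length(h) > 0 && mean(!is.finite(h)) <= 0.5
  }, logical(1))
  valid <- valid & is.finite(hd_bin)

  ids <- cellIds(spikes)
  counts <- vapply(ids, function(id) {
    s <- spikes@spikes[[id]]
    s <- s[s >= t0 & s < edges[n_bins + 1L]]
    tabulate(findInterval(s, edges, rightmost.closed = FALSE), nbins = n_bins)
  }, integer(n_bins))
  counts <- matrix(as.integer(counts), nrow = n_bins,
                   dimnames = list(NULL, ids))

  se <- SummarizedExperiment(
    assays = list(counts = t(counts)),
    rowData = DataFrame(cell_id = ids, row.names = ids),
    colData = DataFrame(bin_center_s = edges[-(n_bins + 1L)] + bin_width_s / 2,
                        hd_deg = hd_bin, valid = valid))
  new("BinnedHD", se, bin_width_s = bin_width_s)
}

#' Subset a binned dataset to a bin range or cell set
#'
#' @param x a \linkS4class{BinnedHD}.
#' @param bins integer or logical index over time bins.
#' @param cells character, integer or logical index over cells.
#' @return a \linkS4class{BinnedHD}.
#' @export
subsetBins <- function(x, bins = NULL, cells = NULL) {
  if (is.null(bins)) bins <- seq_len(ncol(x))
  if (is.null(cells)) cells <- seq_len(nrow(x))
  new("BinnedHD", as(x, "SummarizedExperiment")[cells, bins],
      bin_width_s = x@bin_width_s)
}

# per-frame dwell intervals (last frame gets the typical interval) and the
# heading-bin index (1..60) of each frame; NA for lost frames
frameDwell <- function(track) {
  ts <- track@timestamps
  dts <- diff(ts)
  c(dts, if (length(dts)) stats::median(dts) else 0)
}

hdBinIndex <- function(hd_deg) {
  idx <- floor(wrapDeg(hd_deg) / 6) + 1L
  idx[idx == 61L] <- 60L  # guard against wrapDeg returning 360 - eps
  idx
}

#' Build a 60-bin occupancy-normalized tuning curve
#'
#' Dwell time per 6-degree heading bin is the sum of frame intervals of
#' frames whose heading falls in the bin; spikes are assigned the heading of
#' their containing video frame; rate = spikes / dwell. Lost frames (and
#' their spikes) are excluded. Bins never occupied have \code{NA} rate.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param spike_times_s numeric vector of one cell's spike times, or a
#'   \linkS4class{SpikeTrains} of length one.
#' @param cell_id label for the curve.
#' @return a \linkS4class{TuningCurve}.
#' @export
tuningCurve <- function(track, spike_times_s, cell_id = "cell") {
  if (is(spike_times_s, "SpikeTrains")) {
    stopIfNot(nCells(spike_times_s) == 1L,
              "input error: pass a single cell's spikes")
    cell_id <- cellIds(spike_times_s)
    spike_times_s <- spike_times_s@spikes[[1]]
  }
  ts <- track@timestamps
  stopIfNot(length(ts) > 0, "input error: empty tracking")
  dwell_frame <- frameDwell(track)
  hd <- track@hd_deg
  ok <- is.finite(hd)
  fb <- hdBinIndex(hd[ok])
  dwell <- vapply(1:60, function(b) sum(dwell_frame[ok][fb == b]), numeric(1))

  # spike -> containing frame (frame i spans [t_i, t_i + dwell_i))
  fi <- findInterval(spike_times_s, ts, rightmost.closed = FALSE)
  keep <- fi >= 1L & spike_times_s < ts[length(ts)] + dwell_frame[length(ts)]
  fi <- fi[keep]
  fi <- fi[is.finite(hd[fi])]
  sb <- hdBinIndex(hd[fi])
  cnt <- tabulate(sb, nbins = 60L)

  rate <- ifelse(dwell > 0, cnt / dwell, NA_real_)
  new("TuningCurve", cell_id = cell_id, bin_centers_deg = seq(3, 357, by = 6),
      rate_hz = rate, dwell_s = dwell, spike_count = as.numeric(cnt))
}

#' Circularly smooth a tuning curve with a Gaussian kernel
#'
#' Display and diagnostics helper: the 60-bin rate vector is circularly
#' convolved with a unit-mass Gaussian kernel, which preserves the mean rate
#' exactly. A zero-width kernel is the identity. Unoccupied (\code{NA}) bins
#' are left \code{NA} and excluded from the convolution mass.
#'
#' @param tc a \linkS4class{TuningCurve}.
#' @param kernel_sd_bins kernel standard deviation in 6-degree bins.
#' @return a smoothed \linkS4class{TuningCurve} (dwell and counts untouched).
#' @export
smoothTuning <- function(tc, kernel_sd_bins = 1) {
  if (kernel_sd_bins <= 0) return(tc)
  n <- 60L
  lags <- 0:(n - 1)
  d <- pmin(lags, n - lags)                      # circular lag distance
  k <- exp(-0.5 * (d / kernel_sd_bins)^2)
  k <- k / sum(k)
  r <- tc@rate_hz
  na <- !is.finite(r)
  r0 <- ifelse(na, 0, r)
  m0 <- as.numeric(!na)
  sm <- function(v) vapply(seq_len(n), function(i)
    sum(v * k[((seq_len(n) - i) %% n) + 1L]), numeric(1))
  num <- sm(r0); den <- sm(m0)
  out <- ifelse(den > 0, num / den, NA_real_)
  out[na & den == 0] <- NA_real_
  tc2 <- tc
  tc2@rate_hz <- out
  tc2
}
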