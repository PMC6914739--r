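#' Mean vector length (Rayleigh r) of a tuning curve
#'
#' Magnitude of the firing-rate-weighted circular resultant over the 60-bin
#' curve: \eqn{r = |\sum_b w_b e^{i\theta_b}| / \sum_b w_b} with bin centers
#' \eqn{\theta_b} and per-bin rates \eqn{w_b}. Ranges from 0 (uniform) to 1
#' (all rate in one bin); unoccupied bins are excluded. An all-zero curve has
#' no direction: the value 0 is returned with attribute
#' \code{undefined = TRUE}.
#'
#' @param tc a \linkS4class{TuningCurve}.
#' @return the mean vector length in \code{[0, 1]}.
#' @export
meanVectorLength <- function(tc) {
  ok <- tc@dwell_s > 0 & is.finite(tc@rate_hz)
  stopIfNot(any(ok), "input error: tuning curve has no occupied bins")
  w <- tc@rate_hz[ok]
  th <- tc@bin_centers_deg[ok] * DEG2RAD
  tot <- sum(w)
  if (tot <= 0) return(structure(0, undefined = TRUE))
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / tot
}

# internal: fast 60-bin curve from precomputed per-frame quantities
curveFromCounts <- function(cnt, dwell) ifelse(dwell > 0, cnt / dwell, NA_real_)

# Pearson correlation over bins occupied in both quarters; NA when degenerate
quarterPairCor <- function(r1, r2, d1, d2) {
  ok <- d1 > 0 & d2 > 0
  if (sum(ok) < 3) return(NA_real_)
  a <- r1[ok]; b <- r2[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# Shared precomputation for stability/shuffle loops: per-frame heading-bin
# index, dwell, quarter id, and per-quarter dwell histograms.
sessionGeometry <- function(track) {
  ts <- track@timestamps
  dwell_frame <- frameDwell(track)
  t0 <- ts[1]
  t_end <- ts[length(ts)] + dwell_frame[length(ts)]
  Tdur <- t_end - t0
  q_edges <- t0 + (0:4) * Tdur / 4
  quarter <- pmin(findInterval(ts, q_edges, rightmost.closed = FALSE), 4L)
  ok <- is.finite(track@hd_deg)
  fb <- ifelse(ok, hdBinIndex(track@hd_deg), NA_integer_)
  dwell_q <- vapply(1:4, function(q) {
    sel <- ok & quarter == q
    vapply(1:60, function(b) sum(dwell_frame[sel & fb == b]), numeric(1))
  }, numeric(60))
  dwell_all <- rowSums(dwell_q)
  list(ts = ts, t0 = t0, t_end = t_end, Tdur = Tdur, dwell_frame = dwell_frame,
       ok = ok, fb = fb, quarter = quarter, dwell_q = dwell_q,
       dwell_all = dwell_all)
}

# spike -> containing-frame index; drops spikes outside the session or on
# lost frames
spikeFrames <- function(geom, s) {
  fi <- findInterval(s, geom$ts, rightmost.closed = FALSE)
  fi <- fi[fi >= 1L & s < geom$t_end]
  fi[geom$ok[fi]]
}

# mvl and stability from spike frame indices, given precomputed geometry
scoresFromFrames <- function(geom, fi) {
  bq <- (geom$quarter[fi] - 1L) * 60L + geom$fb[fi]
  cnt_q <- matrix(tabulate(bq, nbins = 240L), nrow = 60L)
  cnt <- rowSums(cnt_q)
  rate <- curveFromCounts(cnt, geom$dwell_all)
  okb <- geom$dwell_all > 0
  th <- (seq(3, 357, by = 6) * DEG2RAD)[okb]
  w <- rate[okb]
  tot <- sum(w)
  mvl <- if (tot > 0) sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / tot else 0
  rq <- lapply(1:4, function(q) curveFromCounts(cnt_q[, q], geom$dwell_q[, q]))
  pairs <- utils::combn(4, 2)
  cs <- apply(pairs, 2, function(p)
    quarterPairCor(rq[[p[1]]], rq[[p[2]]], geom$dwell_q[, p[1]], geom$dwell_q[, p[2]]))
  stab <- if (all(is.na(cs))) NA_real_ else mean(cs, na.rm = TRUE)
  c(mvl = mvl, stability = stab)
}

#' Four-quarter directional stability score
#'
#' The session is divided into four equal time quarters; a 60-bin tuning
#' curve is built for each, and the score is the mean of the six pairwise
#' Pearson correlations (Q1:Q2, Q1:Q3, Q1:Q4, Q2:Q3, Q2:Q4, Q3:Q4), each
#' computed over bins occupied in both quarters. Pairs with a degenerate
#' (zero-variance or near-empty) curve are undefined and excluded; if all
#' six are undefined the score is \code{NA} — a flat cell is never awarded a
#' spurious 1.0.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param spike_times_s one cell's spike times (seconds).
#' @return mean pairwise correlation in \code{[-1, 1]}, or \code{NA}.
#' @export
stabilityScore <- function(track, spike_times_s) {
  geom <- sessionGeometry(track)
  unname(scoresFromFrames(geom, spikeFrames(geom, spike_times_s))["stability"])
}

#' Shuffle null distribution for directionality and stability
#'
#' Each of \code{n_iter} iterations circularly time-shifts the whole spike
#' train relative to the tracked heading by a uniform random offset in
#' \code{[min_shift_s, T - min_shift_s]} (wrapping at the session end), then
#' recomputes the mean vector length and stability score. Shifting preserves
#' the spike count and inter-spike structure; only the alignment to heading
#' is destroyed. The 95th percentiles of the two null distributions are the
#' classification cutoffs. A minimum shift keeps near-zero offsets from
#' leaking genuine tuning into the null.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param spike_times_s one cell's spike times.
#' @param n_iter shuffle iterations (default 400).
#' @param min_shift_s minimum shift in seconds (default 20).
#' @param percentile cutoff percentile (default 0.95).
#' @param seed integer seed; the null is reproducible.
#' @return a list with \code{mvl_threshold}, \code{stability_threshold} and
#'   the full null vectors \code{mvl_null}, \code{stability_null}.
#' @export
shuffleNull <- function(track, spike_times_s, n_iter = 400, min_shift_s = 20,
                        percentile = 0.95, seed = 1L) {
  geom <- sessionGeometry(track)
  stopIfNot(geom$Tdur > 2 * min_shift_s,
            "input error: session too short for the requested minimum shift")
  s0 <- spike_times_s - geom$t0
  withSeed(seed, {
    shifts <- stats::runif(n_iter, min_shift_s, geom$Tdur - min_shift_s)
    nulls <- vapply(shifts, function(dx) {
      s <- ((s0 + dx) %% geom$Tdur) + geom$t0
      scoresFromFrames(geom, spikeFrames(geom, s))
    }, c(mvl = 0, stability = 0))
  })
  list(mvl_threshold = unname(stats::quantile(nulls["mvl", ], percentile, na.rm = TRUE)),
       stability_threshold = unname(stats::quantile(nulls["stability", ], percentile, na.rm = TRUE)),
       mvl_null = unname(nulls["mvl", ]),
       stability_null = unname(nulls["stability", ]))
}

#' Classify HD cells by the shuffle criterion
#'
#' A cell is an HD cell when both its mean vector length and its stability
#' score exceed the 95th-percentile cutoffs of its shuffle null. By default
#' the null distributions of all cells in the dataset are pooled and one
#' cutoff pair is applied to every cell (the per-region pooling used with
#' real recordings); \code{pooled = FALSE} applies each cell its own
#' cutoffs. One time shift per iteration feeds both statistics jointly.
#'
#' @param dataset an \linkS4class{HDDataset}.
#' @param n_iter,min_shift_s,percentile,seed passed to
#'   \code{\link{shuffleNull}} (per-cell seeds are derived from \code{seed}).
#' @param pooled pool null distributions across cells (default \code{TRUE}).
#' @return a \code{data.frame} with one row per cell: \code{cell_id},
#'   \code{mvl}, \code{stability}, \code{mvl_threshold},
#'   \code{stability_threshold}, \code{n_spikes}, \code{is_hd}.
#' @export
classifyHDCells <- function(dataset, n_iter = 400, min_shift_s = 20,
                            percentile = 0.95, pooled = TRUE, seed = 1L) {
  track <- dataset@tracking
  geom <- sessionGeometry(track)
  ids <- cellIds(dataset@spikes)
  obs <- t(vapply(ids, function(id)
    scoresFromFrames(geom, spikeFrames(geom, dataset@spikes@spikes[[id]])),
    c(mvl = 0, stability = 0)))
  nulls <- lapply(seq_along(ids), function(i)
    shuffleNull(track, dataset@spikes@spikes[[ids[i]]], n_iter = n_iter,
                min_shift_s = min_shift_s, percentile = percentile,
                seed = seed + i - 1L))
  if (pooled) {
    mt <- stats::quantile(unlist(lapply(nulls, `[[`, "mvl_null")), percentile,
                          na.rm = TRUE)
    st <- stats::quantile(unlist(lapply(nulls, `[[`, "stability_null")), percentile,
                          na.rm = TRUE)
    mvl_thr <- rep(unname(mt), length(ids))
    stab_thr <- rep(unname(st), length(ids))
  } else {
    mvl_thr <- vapply(nulls, `[[`, numeric(1), "mvl_threshold")
    stab_thr <- vapply(nulls, `[[`, numeric(1), "stability_threshold")
  }
  n_sp <- vapply(ids, function(id) length(dataset@spikes@spikes[[id]]), integer(1))
  data.frame(cell_id = ids, mvl = obs[, "mvl"], stability = obs[, "stability"],
             mvl_threshold = mvl_thr, stability_threshold = stab_thr,
             n_spikes = n_sp,
             is_hd = n_sp > 0 & obs[, "mvl"] > mvl_thr &
               !is.na(obs[, "stability"]) & obs[, "stability"] > stab_thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rayleigh test for grouped (binned) angular data
#'
#' Rayleigh test of unimodal deviation from uniformity on a 60-bin rate
#' distribution, with the standard correction for grouped angular data
#' (resultant inflated by \eqn{(\delta/2)/\sin(\delta/2)} for bin width
#' \eqn{\delta}). The effective sample size is the spike count.
#'
#' @param rate_hz per-bin rates (length 60; \code{NA} = unoccupied).
#' @param n effective sample size (total spikes).
#' @param bin_width_deg angular bin width (default 6).
#' @return a list with corrected \code{r}, \code{z} and \code{p}.
#' @export
rayleighTestBinned <- function(rate_hz, n, bin_width_deg = 6) {
  th <- (seq(3, 357, by = 6)) * DEG2RAD
  ok <- is.finite(rate_hz)
  w <- rate_hz[ok]
  tot <- sum(w)
  r <- if (tot > 0) sqrt(sum(w * cos(th[ok]))^2 + sum(w * sin(th[ok]))^2) / tot else 0
  delta <- bin_width_deg * DEG2RAD
  r <- min(1, r * (delta / 2) / sin(delta / 2))
  R <- n * r
  z <- n * r^2
  # Zar's approximation to the Rayleigh p-value
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r = r, z = z, p = min(1, max(0, p)))
}

peakBin <- function(rate_hz) {
  if (all(!is.finite(rate_hz))) return(NA_integer_)
  which.max(ifelse(is.finite(rate_hz), rate_hz, -Inf))
}

#' Classify HD cells with the sparse-firing (parietal-style) criteria
#'
#' For sparsely firing cortical cells the shuffle criterion is replaced by:
#' at least 250 spikes per session, a significant Rayleigh test (p <= 0.05,
#' corrected for 6-degree binning) on the pooled tuning curve, and a stable
#' peak direction — circular shift of the peak-rate bin between the two
#' sessions (or split halves of a single session) of fewer than 7 bins
#' (42 degrees).
#'
#' @param dataset an \linkS4class{HDDataset}, or a list of two
#'   \code{HDDataset}s holding consecutive sessions. A single dataset is
#'   split in half with a message (the documented fallback).
#' @param min_spikes hard spike-count floor (default 250).
#' @param alpha Rayleigh significance level (default 0.05).
#' @param max_shift_bins peak-shift stability bound, exclusive (default 7).
#' @return a \code{data.frame}: \code{cell_id}, \code{rayleigh_r},
#'   \code{rayleigh_p}, \code{peak_shift_bins}, \code{n_spikes},
#'   \code{is_hd}.
#' @export
classifyPCStyle <- function(dataset, min_spikes = 250, alpha = 0.05,
                            max_shift_bins = 7) {
  if (is(dataset, "HDDataset")) {
    message("single session supplied; using split halves for peak stability")
    geom <- sessionGeometry(dataset@tracking)
    mid <- geom$t0 + geom$Tdur / 2
    splitTrack <- function(sel) HDTracking(dataset@tracking@timestamps[sel],
                                           dataset@tracking@hd_deg[sel])
    sel1 <- dataset@tracking@timestamps < mid
    halves <- list(
      list(track = splitTrack(sel1),
           sub = function(s) s[s < mid]),
      list(track = splitTrack(!sel1),
           sub = function(s) s[s >= mid]))
    sessions <- lapply(halves, function(h)
      list(track = h$track,
           spikes = lapply(dataset@spikes@spikes, h$sub)))
    ids <- cellIds(dataset@spikes)
    pooled_track <- dataset@tracking
    pooled_spikes <- dataset@spikes@spikes
  } else {
    stopIfNot(is.list(dataset) && length(dataset) == 2L,
              "input error: supply one HDDataset or a list of two")
    ids <- cellIds(dataset[[1]]@spikes)
    stopIfNot(identical(ids, cellIds(dataset[[2]]@spikes)),
              "input error: the two sessions must share a cell roster")
    sessions <- lapply(dataset, function(d)
      list(track = d@tracking, spikes = d@spikes@spikes))
    # pool by concatenating session two after session one on the time axis
    off <- max(dataset[[1]]@tracking@timestamps) + 1
    pooled_track <- HDTracking(
      c(dataset[[1]]@tracking@timestamps, dataset[[2]]@tracking@timestamps + off),
      c(dataset[[1]]@tracking@hd_deg, dataset[[2]]@tracking@hd_deg))
    pooled_spikes <- stats::setNames(lapply(ids, function(id)
      c(dataset[[1]]@spikes@spikes[[id]], dataset[[2]]@spikes@spikes[[id]] + off)), ids)
  }
  rows <- lapply(ids, function(id) {
    tc <- tuningCurve(pooled_track, pooled_spikes[[id]], id)
    n_sp <- sum(tc@spike_count)
    rt <- rayleighTestBinned(tc@rate_hz, n_sp)
    pk <- vapply(sessions, function(s)
      peakBin(tuningCurve(s$track, s$spikes[[id]], id)@rate_hz), integer(1))
    shift <- if (anyNA(pk)) NA_integer_ else {
      d <- abs(pk[1] - pk[2]); as.integer(min(d, 60L - d))
    }
    data.frame(cell_id = id, rayleigh_r = rt$r, rayleigh_p = rt$p,
               peak_shift_bins = shift, n_spikes = n_sp,
               is_hd = n_sp >= min_spikes && rt$p <= alpha &&
                 !is.na(shift) && shift < max_shift_bins,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
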