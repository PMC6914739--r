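#' Trajectory generator configuration
#'
#' The heading trajectory is a wrapped random walk driven by an
#' Ornstein--Uhlenbeck angular-velocity process: velocity relaxes toward 0
#' with time constant \code{ang_vel_tau_s} and is kicked by Gaussian noise so
#' its stationary standard deviation is \code{ang_vel_sd_degps}. The defaults
#' (80 deg/s SD, 1 s time constant) give a mean absolute angular velocity of
#' roughly 60 deg/s in 0.2-s bins — within the range foraging rodents show —
#' and full coverage of all sixty 6-degree heading bins within a 10-minute
#' session.
#'
#' @param duration_s session length in seconds (> 0).
#' @param frame_rate_hz video frame rate, samples/s; typical trackers run at
#'   30--60 Hz.
#' @param ang_vel_sd_degps stationary SD of angular velocity, deg/s (>= 0);
#'   0 freezes the heading.
#' @param ang_vel_tau_s velocity autocorrelation time constant, seconds.
#' @param start_deg initial heading, degrees.
#' @param seed integer seed; identical seed gives identical output.
#' @return a \code{trajectoryConfig} list.
#' @export
trajectoryConfig <- function(duration_s = 600, frame_rate_hz = 30,
                             ang_vel_sd_degps = 80, ang_vel_tau_s = 1,
                             start_deg = 0, seed = 1L) {
  stopIfNot(is.numeric(duration_s) && duration_s > 0,
            "configuration error: duration_s must be > 0")
  stopIfNot(is.numeric(frame_rate_hz) && frame_rate_hz > 0,
            "configuration error: frame_rate_hz must be > 0")
  stopIfNot(is.numeric(ang_vel_sd_degps) && ang_vel_sd_degps >= 0,
            "configuration error: ang_vel_sd_degps must be >= 0")
  stopIfNot(is.numeric(ang_vel_tau_s) && ang_vel_tau_s > 0,
            "configuration error: ang_vel_tau_s must be > 0")
  structure(list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 ang_vel_sd_degps = ang_vel_sd_degps,
                 ang_vel_tau_s = ang_vel_tau_s, start_deg = start_deg,
                 seed = as.integer(seed)),
            class = "trajectoryConfig")
}

#' Simulate a heading trajectory
#'
#' Draws a heading series of length \code{round(duration_s * frame_rate_hz)}
#' from the smoothed angular-velocity model in
#' \code{\link{trajectoryConfig}}; headings are wrapped to \code{[0, 360)}.
#'
#' @param cfg a \code{\link{trajectoryConfig}}.
#' @return an \linkS4class{HDTracking} with no lost frames.
#' @examples
#' trk <- simulateTrajectory(trajectoryConfig(duration_s = 60, seed = 7))
#' range(trk@hd_deg)
#' @export
simulateTrajectory <- function(cfg) {
  stopIfNot(inherits(cfg, "trajectoryConfig"), "configuration error: need a trajectoryConfig")
  n <- round(cfg$duration_s * cfg$frame_rate_hz)
  dt <- 1 / cfg$frame_rate_hz
  ts <- (seq_len(n) - 1L) * dt
  withSeed(cfg$seed, {
    if (cfg$ang_vel_sd_degps == 0) {
      hd <- rep(wrapDeg(cfg$start_deg), n)
    } else {
      a <- exp(-dt / cfg$ang_vel_tau_s)
      kick <- cfg$ang_vel_sd_degps * sqrt(1 - a^2)
      z <- rnorm(n)
      v <- numeric(n)
      v[1] <- cfg$ang_vel_sd_degps * z[1]
      for (i in seq_len(n - 1L)) v[i + 1L] <- a * v[i] + kick * z[i + 1L]
      hd <- wrapDeg(cfg$start_deg + cumsum(c(0, v[-n] * dt)))
    }
    HDTracking(timestamps = ts, hd_deg = hd)
  })
}

#' Von Mises-exponential directional tuning function
#'
#' Firing rate of an HD cell as a function of heading:
#' \deqn{r(\theta) = b + (p - b)\, e^{\kappa(\cos(\theta - \theta_0) - 1)}}
#' with baseline \eqn{b}, peak \eqn{p}, concentration \eqn{\kappa} and
#' preferred direction \eqn{\theta_0}. The rate is continuous, 360-periodic,
#' never negative, peaks exactly at the preferred direction, and with
#' \eqn{\kappa = 0} is flat at the peak rate (a non-directional cell). With
#' zero baseline the log-rate is exactly linear in \code{[cos, sin]}, the
#' observation model of the Poisson GLM decoder.
#'
#' @param params a \code{\link{cellTuningParams}}.
#' @param hd_deg heading(s), degrees.
#' @return firing rate(s), spikes/s.
#' @examples
#' p <- cellTuningParams(pd_deg = 0, peak_hz = 20, kappa = 4)
#' tuningRate(p, c(0, 90, 180))
#' @export
tuningRate <- function(params, hd_deg) {
  with(params, baseline_hz + (peak_hz - baseline_hz) *
         exp(kappa * (cos((hd_deg - pd_deg) * DEG2RAD) - 1)))
}

#' Per-cell tuning parameters
#'
#' @param pd_deg preferred direction, degrees in \code{[0, 360)}.
#' @param peak_hz peak firing rate, spikes/s; HD cells across thalamo-cortical
#'   regions span roughly 2--120 spikes/s.
#' @param kappa von Mises concentration (>= 0); 0 gives a flat cell.
#' @param baseline_hz background rate, spikes/s, \code{0 <= baseline <= peak}.
#' @return a \code{cellTuningParams} list.
#' @export
cellTuningParams <- function(pd_deg, peak_hz, kappa, baseline_hz = 0) {
  stopIfNot(peak_hz >= baseline_hz && baseline_hz >= 0,
            "configuration error: need peak_hz >= baseline_hz >= 0")
  stopIfNot(kappa >= 0, "configuration error: kappa must be >= 0")
  structure(list(pd_deg = wrapDeg(pd_deg), peak_hz = peak_hz, kappa = kappa,
                 baseline_hz = baseline_hz),
            class = "cellTuningParams")
}

#' Simulate inhomogeneous-Poisson spike trains from a trajectory
#'
#' For each cell the spike train is an inhomogeneous Poisson process with
#' intensity \code{tuningRate(params, hd(t))}: per video frame a Poisson
#' count with mean rate x frame interval is drawn and the spikes are placed
#' uniformly at random within the frame. At frame rates of 30--60 Hz and
#' rates up to 120 spikes/s the within-frame rate variation is negligible,
#' so this frame-wise emission is an accurate realization of the process.
#' Frames with lost tracking emit no spikes.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param cells a list of \code{\link{cellTuningParams}} (named, optionally).
#' @param seed integer seed.
#' @return a \linkS4class{SpikeTrains}.
#' @export
simulateSpikes <- function(track, cells, seed = 1L) {
  stopIfNot(length(track@timestamps) > 0, "input error: empty trajectory")
  ts <- track@timestamps
  n <- length(ts)
  dts <- diff(ts)
  dt <- c(dts, stats::median(dts))  # last frame gets the typical interval
  hd <- track@hd_deg
  ok <- is.finite(hd)
  if (is.null(names(cells)))
    names(cells) <- sprintf("cell%02d", seq_along(cells))
  withSeed(seed, {
    trains <- lapply(cells, function(p) {
      lam <- numeric(n)
      lam[ok] <- tuningRate(p, hd[ok]) * dt[ok]
      k <- stats::rpois(n, lam)
      idx <- rep.int(seq_len(n), k)
      if (!length(idx)) return(numeric(0))
      sort(ts[idx] + stats::runif(length(idx)) * dt[idx])
    })
    SpikeTrains(trains)
  })
}

#' Population configuration for synthetic datasets
#'
#' @param n_cells number of HD cells (>= 1).
#' @param pd_coverage either \code{"uniform"} (preferred directions evenly
#'   spread over the full circle with a random rotation) or a length-2
#'   numeric \code{c(lo, hi)} arc in degrees restricting preferred
#'   directions — the manipulation behind the vector-method coverage failure.
#' @param rate_range \code{c(min, max)} peak rates, spikes/s.
#' @param kappa_range \code{c(min, max)} von Mises concentrations.
#' @param baseline_hz background rate for every cell, spikes/s.
#' @param n_nonhd_cells flat (kappa = 0) distractor cells appended to the
#'   roster, for testing classifier false positives.
#' @param seed integer seed.
#' @return a \code{populationConfig} list.
#' @export
populationConfig <- function(n_cells = 5, pd_coverage = "uniform",
                             rate_range = c(10, 40), kappa_range = c(2, 6),
                             baseline_hz = 0.5, n_nonhd_cells = 0, seed = 1L) {
  stopIfNot(n_cells >= 1, "configuration error: n_cells must be >= 1")
  if (!identical(pd_coverage, "uniform")) {
    stopIfNot(is.numeric(pd_coverage) && length(pd_coverage) == 2L,
              "configuration error: pd_coverage must be 'uniform' or c(lo, hi)")
    stopIfNot(pd_coverage[2] > pd_coverage[1] &&
                (pd_coverage[2] - pd_coverage[1]) <= 360,
              "configuration error: pd_coverage arc must be a valid sub-arc")
  }
  structure(list(n_cells = as.integer(n_cells), pd_coverage = pd_coverage,
                 rate_range = rate_range, kappa_range = kappa_range,
                 baseline_hz = baseline_hz,
                 n_nonhd_cells = as.integer(n_nonhd_cells),
                 seed = as.integer(seed)),
            class = "populationConfig")
}

# Draw per-cell ground-truth parameters from a populationConfig.
drawPopulation <- function(pop_cfg) {
  withSeed(pop_cfg$seed, {
    nc <- pop_cfg$n_cells
    if (identical(pop_cfg$pd_coverage, "uniform")) {
      pds <- wrapDeg(stats::runif(1, 0, 360) + (seq_len(nc) - 1L) * 360 / nc +
                       stats::runif(nc, -180 / nc, 180 / nc))
    } else {
      arc <- pop_cfg$pd_coverage
      pds <- wrapDeg(sort(stats::runif(nc, arc[1], arc[2])))
    }
    peaks <- stats::runif(nc, pop_cfg$rate_range[1], pop_cfg$rate_range[2])
    kappas <- stats::runif(nc, pop_cfg$kappa_range[1], pop_cfg$kappa_range[2])
    cells <- lapply(seq_len(nc), function(i)
      cellTuningParams(pds[i], peaks[i], kappas[i], pop_cfg$baseline_hz))
    names(cells) <- sprintf("hd%02d", seq_len(nc))
    if (pop_cfg$n_nonhd_cells > 0) {
      flat_rates <- stats::runif(pop_cfg$n_nonhd_cells,
                                 pop_cfg$rate_range[1], pop_cfg$rate_range[2]) / 4
      flats <- lapply(flat_rates, function(r)
        cellTuningParams(0, r, 0, r))
      names(flats) <- sprintf("flat%02d", seq_len(pop_cfg$n_nonhd_cells))
      cells <- c(cells, flats)
    }
    cells
  })
}

#' Generate a complete synthetic HD-cell dataset
#'
#' Simulates a trajectory, draws a population of tuned cells (plus optional
#' flat distractors) and emits their Poisson spike trains. The generating
#' parameters are retained in the \code{truth} slot so parameter recovery and
#' classifier calibration are directly testable.
#'
#' @param traj_cfg a \code{\link{trajectoryConfig}}.
#' @param pop_cfg a \code{\link{populationConfig}}.
#' @param dataset_id character label.
#' @return an \linkS4class{HDDataset}.
#' @examples
#' ds <- generateDataset(trajectoryConfig(duration_s = 60, seed = 2),
#'                       populationConfig(n_cells = 4, seed = 3))
#' ds
#' @export
generateDataset <- function(traj_cfg, pop_cfg, dataset_id = "synthetic") {
  track <- simulateTrajectory(traj_cfg)
  cells <- drawPopulation(pop_cfg)
  # spike seed derived deterministically from the two config seeds
  spikes <- simulateSpikes(track, cells,
                           seed = (traj_cfg$seed * 1009L + pop_cfg$seed) %% .Machine$integer.max)
  truth <- data.frame(
    cell_id = names(cells),
    pd_deg = vapply(cells, `[[`, numeric(1), "pd_deg"),
    peak_hz = vapply(cells, `[[`, numeric(1), "peak_hz"),
    baseline_hz = vapply(cells, `[[`, numeric(1), "baseline_hz"),
    kappa = vapply(cells, `[[`, numeric(1), "kappa"),
    is_hd = vapply(cells, function(p) p$kappa > 0, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  new("HDDataset", dataset_id = dataset_id, tracking = track,
      spikes = spikes, truth = truth,
      config = list(trajectory = unclass(traj_cfg), population = unclass(pop_cfg)))
}
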