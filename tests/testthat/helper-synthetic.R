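# Shared fixtures, built in code.

# a small, well-covered benchmark dataset used by several decoder tests
benchDataset <- function(n_cells = 10, duration_s = 600, kappa = 4,
                         peak = 20, baseline = 0.5, seed = 11,
                         pd_coverage = "uniform") {
  generateDataset(
    trajectoryConfig(duration_s = duration_s, seed = seed),
    populationConfig(n_cells = n_cells, pd_coverage = pd_coverage,
                     rate_range = c(peak, peak), kappa_range = c(kappa, kappa),
                     baseline_hz = baseline, seed = seed + 100L),
    dataset_id = sprintf("bench_s%d", seed))
}

# a hand-built tracking series: constant frame rate, specified headings
trackFromHeadings <- function(hd_deg, frame_rate_hz = 30) {
  HDTracking(timestamps = (seq_along(hd_deg) - 1) / frame_rate_hz,
             hd_deg = hd_deg)
}

# a tuning curve object with specified per-bin rates and uniform dwell
curveWithRates <- function(rate_hz, dwell_s = rep(1, 60)) {
  new("TuningCurve", cell_id = "toy", bin_centers_deg = seq(3, 357, by = 6),
      rate_hz = rate_hz, dwell_s = dwell_s,
      spike_count = ifelse(dwell_s > 0 & is.finite(rate_hz), rate_hz * dwell_s, 0))
}

trainTestSplit <- function(ds, split = "UT", bin_width_s = 0.2, cells = NULL) {
  b <- binDataset(ds@tracking, ds@spikes, bin_width_s)
  if (!is.null(cells)) b <- subsetBins(b, cells = cells)
  sp <- utLtSplit(ncol(b))[[split]]
  list(train = subsetBins(b, bins = sp$train),
       test = subsetBins(b, bins = sp$test))
}
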