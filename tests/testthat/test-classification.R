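test_that("mean vector length matches hand-computed resultants", {
  one_bin <- rep(0, 60); one_bin[10] <- 5
  expect_equal(meanVectorLength(curveWithRates(one_bin)), 1)

  expect_equal(meanVectorLength(curveWithRates(rep(3, 60))), 0, tolerance = 1e-12)

  # two equal rates 90 degrees apart: |(u1 + u2)| / 2 = cos(45) = sqrt(2)/2
  two <- rep(0, 60); two[c(1, 16)] <- 1   # centers 3 and 93 degrees
  expect_equal(meanVectorLength(curveWithRates(two)), sqrt(2) / 2, tolerance = 1e-12)

  # all-zero curve: undefined, reported as 0 with a flag
  z <- meanVectorLength(curveWithRates(rep(0, 60)))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
})

test_that("mvl is invariant to heading rotation and rate scaling", {
  trk <- simulateTrajectory(trajectoryConfig(duration_s = 120, seed = 21))
  sp <- simulateSpikes(trk, list(cellTuningParams(77, 25, 4, 0.5)), seed = 22)
  tc <- tuningCurve(trk, sp@spikes[[1]])
  m0 <- meanVectorLength(tc)
  rot <- tuningCurve(HDTracking(trk@timestamps, wrapDeg(trk@hd_deg + 42)),
                     sp@spikes[[1]])
  expect_equal(meanVectorLength(rot), m0, tolerance = 1e-9)
  scaled <- tc; scaled@rate_hz <- tc@rate_hz * 7.3
  expect_equal(meanVectorLength(scaled), m0, tolerance = 1e-12)
})

test_that("stability score separates stable, rotating and degenerate cells", {
  # identical trajectory sweep and identical spike pattern in all 4 quarters
  fr <- 30; qdur <- 150
  sweep_hd <- seq(0, 359.9, length.out = qdur * fr)
  trk <- trackFromHeadings(rep(sweep_hd, 4), fr)
  base_t <- trk@timestamps[1:(qdur * fr)][sweep_hd > 60 & sweep_hd < 120]
  sp_stable <- sort(unlist(lapply(0:3, function(q) base_t + q * qdur)))
  # one-frame edge effects at quarter boundaries keep it just below 1
  expect_equal(stabilityScore(trk, sp_stable), 1, tolerance = 1e-3)

  # preferred direction rotating 90 degrees per quarter
  qdur <- 150; fr <- 30
  hd <- rep(seq(0, 359.9, length.out = qdur * fr / 5), 5)  # sweeps all HDs
  hd <- rep(hd, 4)[1:(4 * qdur * fr)]
  trk2 <- trackFromHeadings(hd, fr)
  p <- function(pd) cellTuningParams(pd, 30, 6, 0)
  spikes <- sort(unlist(lapply(0:3, function(q) {
    seg <- HDTracking(trk2@timestamps[1:(qdur * fr)], hd[1:(qdur * fr)])
    simulateSpikes(seg, list(p(90 * q)), seed = q + 1)@spikes[[1]] + q * qdur
  })))
  expect_lt(stabilityScore(trk2, spikes), 0.2)

  # flat equal curves in every quarter: zero variance, flagged NA, not 1.0
  trk3 <- trackFromHeadings(rep(c(10, 100, 190, 280), 600), 30)
  reg <- seq(0.0125, 79.9, by = 1 / 30)  # one spike per frame: flat rates
  expect_true(is.na(stabilityScore(trk3, reg)))
})

test_that("circular shift preserves spike count and a full wrap is the identity", {
  trk <- simulateTrajectory(trajectoryConfig(duration_s = 120, seed = 31))
  sp <- simulateSpikes(trk, list(cellTuningParams(10, 20, 4, 0)), seed = 32)
  s <- sp@spikes[[1]]
  geom <- decodeHD:::sessionGeometry(trk)
  Tdur <- geom$Tdur
  shifted <- ((s - geom$t0 + Tdur) %% Tdur) + geom$t0   # full wrap
  tc1 <- tuningCurve(trk, s); tc2 <- tuningCurve(trk, sort(shifted))
  expect_equal(tc2@spike_count, tc1@spike_count)
  half <- ((s - geom$t0 + Tdur / 3) %% Tdur) + geom$t0
  expect_equal(length(half), length(s))                  # count preserved
  expect_equal(sum(tuningCurve(trk, sort(half))@spike_count), length(s))
})

test_that("shuffle classification accepts tuned cells and rejects flat ones", {
  ds <- generateDataset(trajectoryConfig(duration_s = 480, seed = 41),
                        populationConfig(n_cells = 4, n_nonhd_cells = 2,
                                         kappa_range = c(4, 4),
                                         rate_range = c(20, 20), seed = 42), "cls")
  sc <- classifyHDCells(ds, n_iter = 100, seed = 7)
  expect_true(all(sc$is_hd[ds@truth$is_hd]))
  expect_false(any(sc$is_hd[!ds@truth$is_hd]))
  expect_true(all(sc$mvl >= 0 & sc$mvl <= 1))

  # determinism of the null under a fixed seed
  sn1 <- shuffleNull(ds@tracking, ds@spikes@spikes[[1]], n_iter = 50, seed = 3)
  sn2 <- shuffleNull(ds@tracking, ds@spikes@spikes[[1]], n_iter = 50, seed = 3)
  expect_identical(sn1$mvl_null, sn2$mvl_null)

  # raising the percentile never lowers a threshold
  sn99 <- shuffleNull(ds@tracking, ds@spikes@spikes[[1]], n_iter = 50,
                      percentile = 0.99, seed = 3)
  expect_gte(sn99$mvl_threshold, sn1$mvl_threshold)
  expect_gte(sn99$stability_threshold, sn1$stability_threshold)

  expect_error(shuffleNull(trackFromHeadings(rep(1, 30)), 0.5, min_shift_s = 20),
               "too short")
})

test_that("parietal-style criteria enforce spike floor, Rayleigh test and peak stability", {
  # well-tuned, high-count cell passes on split halves
  ds <- generateDataset(trajectoryConfig(duration_s = 600, seed = 51),
                        populationConfig(n_cells = 1, kappa_range = c(4, 4),
                                         rate_range = c(10, 10), seed = 52), "pc")
  expect_message(sc <- classifyPCStyle(ds), "split halves")
  expect_true(sc$is_hd[1])
  expect_gte(sc$n_spikes[1], 250)
  expect_lt(sc$peak_shift_bins[1], 7)

  # under 250 spikes: excluded regardless of tuning
  thin <- ds
  thin@spikes <- SpikeTrains(list(hd01 = ds@spikes@spikes[[1]][1:200]))
  expect_message(sc2 <- classifyPCStyle(thin), "split halves")
  expect_false(sc2$is_hd[1])

  # preferred direction rotating 90 degrees (15 bins) between sessions: fails
  trk <- simulateTrajectory(trajectoryConfig(duration_s = 300, seed = 53))
  s1 <- simulateSpikes(trk, list(a = cellTuningParams(40, 15, 4, 0)), seed = 54)
  s2 <- simulateSpikes(trk, list(a = cellTuningParams(130, 15, 4, 0)), seed = 55)
  d1 <- new("HDDataset", dataset_id = "s1", tracking = trk, spikes = s1,
            truth = NULL, config = list())
  d2 <- new("HDDataset", dataset_id = "s2", tracking = trk, spikes = s2,
            truth = NULL, config = list())
  sc3 <- classifyPCStyle(list(d1, d2))
  expect_false(sc3$is_hd[1])
  expect_gte(sc3$peak_shift_bins[1], 7)
})
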