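#' Scaled-STD tuning-strength proxy
#'
#' The tuning curve is normalized by its peak rate and the (population)
#' standard deviation of the normalized rates over occupied bins is
#' returned. Dividing by the peak removes the firing-rate scale, so the
#' measure behaves like a signal-to-noise index: 0 for a flat curve, large
#' for a narrow peak; it is strictly increasing in the von Mises
#' concentration of the generator's cells.
#'
#' @param tc a \linkS4class{TuningCurve}.
#' @return the scaled standard deviation (unitless), \code{NA} with a
#'   warning for an all-zero curve.
#' @export
scaledStd <- function(tc) {
  ok <- tc@dwell_s > 0 & is.finite(tc@rate_hz)
  r <- tc@rate_hz[ok]
  mx <- max(r)
  if (!length(r) || mx <= 0) {
    warning("all-zero tuning curve: scaled std undefined", call. = FALSE)
    return(NA_real_)
  }
  z <- r / mx
  sqrt(mean((z - mean(z))^2))
}

#' Response rate of a cell
#'
#' The proportion of valid video frames whose frame interval contains at
#' least one spike of the cell. For a homogeneous Poisson cell at rate
#' \eqn{r} and frame rate \eqn{F} the expectation is \eqn{1 - e^{-r/F}}.
#' When comparing datasets, the convention is to take the HD cell with the
#' greatest spike count in each dataset.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param spike_times_s one cell's spike times.
#' @return fraction in \code{[0, 1]}.
#' @export
responseRate <- function(track, spike_times_s) {
  geom <- sessionGeometry(track)
  fi <- spikeFrames(geom, spike_times_s)
  n_valid <- sum(geom$ok)
  stopIfNot(n_valid > 0, "input error: no valid frames")
  length(unique(fi)) / n_valid
}

#' Mean absolute angular head velocity
#'
#' Heading is reduced to 0.2-s bins (circular mean of member frames), the
#' consecutive differences are rescaled to \code{[-180, 180]} — so a
#' 359-to-1-degree crossing counts as 2 degrees, not 358 — and the mean of
#' \code{|difference| / 0.2} is returned in deg/s.
#'
#' @param track an \linkS4class{HDTracking}.
#' @param bin_width_s velocity bin width (default 0.2 s).
#' @return mean absolute angular velocity, deg/s.
#' @export
meanAbsAngularVelocity <- function(track, bin_width_s = 0.2) {
  ts <- track@timestamps
  stopIfNot(length(ts) >= 2, "input error: need at least two frames")
  edges <- seq(ts[1], max(ts) + bin_width_s, by = bin_width_s)
  b <- findInterval(ts, edges, rightmost.closed = FALSE)
  hd <- vapply(seq_len(max(b)), function(k) circMeanDeg(track@hd_deg[b == k]),
               numeric(1))
  hd <- hd[is.finite(hd)]
  stopIfNot(length(hd) >= 2, "input error: too few valid velocity bins")
  mean(abs(rescaleAngle(diff(hd)))) / bin_width_s
}

#' Regress decoding error on a dataset-level factor
#'
#' Pearson correlation (with its two-sided p-value) and least-squares slope
#' of MAE against a factor, computed per method across datasets.
#'
#' @param table a data.frame with columns \code{method}, \code{mae_deg} and
#'   the factor column.
#' @param factor name of the factor column.
#' @param method optional method tag to restrict to; default regresses each
#'   method present.
#' @return a data.frame with one row per method: \code{method}, \code{r},
#'   \code{p}, \code{slope}, \code{n}.
#' @export
regressFactor <- function(table, factor, method = NULL) {
  stopIfNot(all(c("method", "mae_deg", factor) %in% names(table)),
            "input error: table must have method, mae_deg and the factor column")
  if (!is.null(method)) table <- table[table$method %in% method, , drop = FALSE]
  out <- lapply(split(table, table$method), function(d) {
    x <- d[[factor]]; y <- d$mae_deg
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(method = d$method[1], r = NA_real_, p = NA_real_,
                        slope = NA_real_, n = length(x)))
    ct <- stats::cor.test(x, y)
    data.frame(method = d$method[1], r = unname(ct$estimate), p = ct$p.value,
               slope = unname(stats::coef(stats::lm(y ~ x))[2]), n = length(x))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# One-way repeated-measures ANOVA, subjects x groups, complete cases only.
rmAnovaOnce <- function(df) {
  wide <- stats::reshape(df[c("subject", "group", "y")], direction = "wide",
                         idvar = "subject", timevar = "group")
  keep <- stats::complete.cases(wide)
  n_dropped <- sum(!keep)
  wide <- wide[keep, , drop = FALSE]
  Y <- as.matrix(wide[, -1, drop = FALSE])
  n <- nrow(Y); k <- ncol(Y)
  stopIfNot(n >= 2 && k >= 2, "input error: need >= 2 subjects and >= 2 groups")
  grand <- mean(Y)
  ss_groups <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_groups - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_groups / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE),
       group_means = colMeans(Y), n_subjects = n, n_dropped = n_dropped)
}

#' Sequential factor-removal repeated-measures ANOVA
#'
#' Runs a one-way repeated-measures ANOVA (subjects = datasets, groups =
#' methods or regions), and while the result is significant removes the
#' group whose mean is furthest from the grand mean and reruns, stopping at
#' the first non-significant ANOVA. This pinpoints which groups drive a
#' significant omnibus result without a battery of pairwise post-tests.
#' Subjects missing any remaining group are excluded listwise (count
#' reported per step).
#'
#' @param table data.frame with columns named by \code{subject},
#'   \code{group} and \code{value}.
#' @param subject,group,value column names (defaults \code{"dataset_id"},
#'   \code{"method"}, \code{"mae_deg"}).
#' @param alpha significance level (default 0.05).
#' @return a list: \code{steps} (data.frame of per-step F, df, p and the
#'   group removed after the step, \code{NA} at the stopping step) and
#'   \code{removed} (ordered character vector of removed groups).
#' @export
rmAnovaRemoval <- function(table, subject = "dataset_id", group = "method",
                           value = "mae_deg", alpha = 0.05) {
  df <- data.frame(subject = table[[subject]], group = table[[group]],
                   y = table[[value]])
  removed <- character(0)
  steps <- list()
  repeat {
    res <- rmAnovaOnce(df)
    sig <- is.finite(res$p) && res$p < alpha
    k <- length(res$group_means)
    drop_next <- if (sig && k > 2) {
      names(res$group_means)[which.max(abs(res$group_means - mean(res$group_means)))]
    } else NA_character_
    if (!is.na(drop_next)) drop_next <- sub("^y\\.", "", drop_next)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, F = res$F, df1 = res$df1, df2 = res$df2,
      p = res$p, n_subjects = res$n_subjects, n_dropped = res$n_dropped,
      removed_after = drop_next, stringsAsFactors = FALSE)
    if (is.na(drop_next)) break
    removed <- c(removed, drop_next)
    df <- df[df$group != drop_next, , drop = FALSE]
  }
  list(steps = do.call(rbind, steps), removed = removed)
}

#' Compare correlation magnitudes between factors
#'
#' Given per-method regression r-values for two or more factors, tests
#' whether factors differ in how strongly they predict decoding error: a
#' paired t-test on \code{|r|} for two factors, or a repeated-measures
#' omnibus ANOVA (methods as subjects) with the sequential-removal
#' follow-up for more.
#'
#' @param r_sets a named list of numeric vectors of r-values, aligned by
#'   method.
#' @param alpha significance level for the removal follow-up.
#' @return for two sets, the \code{htest} from \code{t.test}; for more, a
#'   list with the omnibus \code{rmAnovaRemoval} result.
#' @export
compareCorrelationMagnitudes <- function(r_sets, alpha = 0.05) {
  stopIfNot(is.list(r_sets) && length(r_sets) >= 2,
            "input error: supply at least two r-value sets")
  lens <- vapply(r_sets, length, integer(1))
  stopIfNot(length(unique(lens)) == 1L, "input error: r sets must be aligned")
  if (length(r_sets) == 2L) {
    d <- abs(r_sets[[1]]) - abs(r_sets[[2]])
    if (stats::sd(d) < 1e-12) {
      # constant differences: t.test is degenerate; report the exact limits
      t0 <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
      return(structure(list(statistic = c(t = t0), parameter = c(df = length(d) - 1),
                            p.value = if (t0 == 0) 1 else 0,
                            estimate = c(`mean difference` = mean(d)),
                            method = "Paired t-test (degenerate: zero variance)",
                            data.name = "abs(r) differences"),
                       class = "htest"))
    }
    return(stats::t.test(abs(r_sets[[1]]), abs(r_sets[[2]]), paired = TRUE))
  }
  long <- data.frame(
    method = rep(seq_len(lens[1]), times = length(r_sets)),
    factor = rep(names(r_sets), each = lens[1]),
    abs_r = abs(unlist(r_sets, use.names = FALSE)))
  rmAnovaRemoval(long, subject = "method", group = "factor", value = "abs_r",
                 alpha = alpha)
}

#' Build the dataset-level factor table
#'
#' One row per (dataset, method, split) result, carrying the decoding error
#' and the four accuracy factors: number of HD cells, scaled-STD tuning
#' strength and response rate of a designated cell, and the mean absolute
#' angular head velocity. The designated cell is either the maximum-spike
#' HD cell (\code{designate = "max_spikes"}, the response-rate convention)
#' or a seeded random HD cell (\code{"random"}, the tuning-strength
#' convention, avoiding repeated sampling of the same decoding score).
#'
#' @param datasets list of \linkS4class{HDDataset}s.
#' @param results list of \linkS4class{DecodeResult}s for those datasets.
#' @param designate \code{"max_spikes"} or \code{"random"}.
#' @param seed seed for random designation.
#' @return a data.frame factor table.
#' @export
factorTable <- function(datasets, results, designate = "max_spikes", seed = 1L) {
  names(datasets) <- vapply(datasets, function(d) d@dataset_id, character(1))
  per_ds <- lapply(datasets, function(ds) {
    ids <- if (!is.null(ds@truth)) ds@truth$cell_id[ds@truth$is_hd] else cellIds(ds@spikes)
    stopIfNot(length(ids) >= 1, "input error: dataset has no HD cells")
    n_sp <- vapply(ids, function(id) length(ds@spikes@spikes[[id]]), integer(1))
    pick <- if (designate == "random") {
      withSeed(seed + match(ds@dataset_id, names(datasets)),
               sample(ids, 1))
    } else ids[which.max(n_sp)]
    tc <- tuningCurve(ds@tracking, ds@spikes@spikes[[pick]], pick)
    data.frame(dataset_id = ds@dataset_id, n_hd_cells = length(ids),
               designated_cell = pick, scaled_std = scaledStd(tc),
               response_rate = responseRate(ds@tracking, ds@spikes@spikes[[pick]]),
               mean_abs_ang_vel_degps = meanAbsAngularVelocity(ds@tracking),
               stringsAsFactors = FALSE)
  })
  fac <- do.call(rbind, per_ds)
  res <- resultsTable(results)
  merge(res, fac, by = "dataset_id")
}
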