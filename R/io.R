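#' Derive heading from two-LED tracking
#'
#' Heading is the direction of the red-to-green LED axis (the facing
#' direction by the package's fixed convention; set \code{flip = TRUE} if the
#' rig mounts the green LED at the back): \code{atan2(dy, dx)} converted to
#' degrees in \code{[0, 360)}. Frames with a missing LED, or with the two
#' LEDs at coincident coordinates (direction undefined), yield \code{NA}.
#'
#' @param red_xy,green_xy n x 2 matrices of LED pixel coordinates.
#' @param flip reverse the axis (green-to-red).
#' @return heading per frame, degrees; \code{NA} where undefined.
#' @examples
#' hdFromLeds(cbind(0, 0), cbind(1, 0))  # 0 degrees
#' hdFromLeds(cbind(0, 0), cbind(0, 1))  # 90 degrees
#' @export
hdFromLeds <- function(red_xy, green_xy, flip = FALSE) {
  red_xy <- rbind(red_xy); green_xy <- rbind(green_xy)
  stopIfNot(ncol(red_xy) == 2L && ncol(green_xy) == 2L &&
              nrow(red_xy) == nrow(green_xy),
            "input error: LED coordinate matrices must be n x 2 and aligned")
  dx <- green_xy[, 1] - red_xy[, 1]
  dy <- green_xy[, 2] - red_xy[, 2]
  if (flip) { dx <- -dx; dy <- -dy }
  hd <- wrapDeg(atan2(dy, dx) * RAD2DEG)
  hd[!is.finite(dx) | !is.finite(dy)] <- NA_real_
  hd[dx == 0 & dy == 0] <- NA_real_
  hd
}

#' Read and write tracking CSV files
#'
#' The tracking format is a headered CSV with a \code{time_s} column plus
#' either \code{hd_deg} or the four LED columns
#' \code{red_x, red_y, green_x, green_y} (heading is then derived with
#' \code{\link{hdFromLeds}}). Missing samples are empty fields. Headings are
#' wrapped to \code{[0, 360)} on read; round-trips are lossless to 6 decimal
#' places.
#'
#' @param path file path.
#' @return \code{readTracking} returns an \linkS4class{HDTracking};
#'   \code{writeTracking} returns \code{path} invisibly.
#' @export
readTracking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIfNot("time_s" %in% names(df), "format error: tracking file needs a time_s column")
  known <- c("time_s", "hd_deg", "red_x", "red_y", "green_x", "green_y")
  bad <- setdiff(names(df), known)
  if (length(bad))
    stop("format error: unknown tracking columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ts <- as.numeric(df$time_s)
  if (any(diff(ts) <= 0)) {
    k <- which(diff(ts) <= 0)[1] + 1L
    stop(sprintf("format error: timestamps not strictly increasing at row %d", k),
         call. = FALSE)
  }
  if ("hd_deg" %in% names(df)) {
    hd <- wrapDeg(as.numeric(df$hd_deg))
    red <- green <- NULL
  } else {
    stopIfNot(all(c("red_x", "red_y", "green_x", "green_y") %in% names(df)),
              "format error: need hd_deg or all four LED columns")
    red <- cbind(as.numeric(df$red_x), as.numeric(df$red_y))
    green <- cbind(as.numeric(df$green_x), as.numeric(df$green_y))
    hd <- hdFromLeds(red, green)
  }
  HDTracking(timestamps = ts, hd_deg = hd, red_xy = red, green_xy = green)
}

#' @param track an \linkS4class{HDTracking}.
#' @rdname readTracking
#' @export
writeTracking <- function(track, path) {
  df <- data.frame(time_s = round(track@timestamps, 6),
                   hd_deg = round(track@hd_deg, 6))
  if (!is.null(track@red_xy)) {
    df$red_x <- track@red_xy[, 1]; df$red_y <- track@red_xy[, 2]
    df$green_x <- track@green_xy[, 1]; df$green_y <- track@green_xy[, 2]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write spike-time files
#'
#' Long-format CSV with columns \code{cell_id, spike_time_s} (one file for
#' the whole population) or a single-column \code{spike_time_s} file for one
#' cell. Unsorted times are sorted with a warning; duplicate timestamps are
#' preserved (Poisson ties at file precision are legitimate); negative times
#' are a format error.
#'
#' @param path file path.
#' @param cell_id cell id to assign when reading a single-cell file.
#' @return \code{readSpikes} returns a \linkS4class{SpikeTrains}.
#' @export
readSpikes <- function(path, cell_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    ids <- if (is.null(cell_id)) character(0) else cell_id
    sp <- stats::setNames(lapply(ids, function(i) numeric(0)), ids)
    return(SpikeTrains(sp))
  }
  if (!"spike_time_s" %in% names(df))
    stop("format error: spike file needs a spike_time_s column", call. = FALSE)
  if (any(df$spike_time_s < 0, na.rm = TRUE))
    stop("format error: negative spike times", call. = FALSE)
  if (!"cell_id" %in% names(df))
    df$cell_id <- if (is.null(cell_id)) "cell01" else cell_id
  sp <- split(as.numeric(df$spike_time_s), df$cell_id)
  if (any(vapply(sp, is.unsorted, logical(1))))
    warning("unsorted spike times; sorting", call. = FALSE)
  SpikeTrains(sp)
}

#' @param spikes a \linkS4class{SpikeTrains}.
#' @rdname readSpikes
#' @export
writeSpikes <- function(spikes, path) {
  ids <- cellIds(spikes)
  df <- data.frame(
    cell_id = rep.int(ids, vapply(spikes@spikes, length, integer(1))),
    spike_time_s = round(unlist(spikes@spikes, use.names = FALSE), 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the tracking CSV, the long-format spike CSV, a ground-truth JSON
#' sidecar (per-cell generating parameters and the config echo, seeds
#' included) and a manifest JSON naming the files and session bounds.
#'
#' @param ds an \linkS4class{HDDataset}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tp <- file.path(dir, "tracking.csv"); sp <- file.path(dir, "spikes.csv")
  writeTracking(ds@tracking, tp)
  writeSpikes(ds@spikes, sp)
  if (!is.null(ds@truth))
    jsonlite::write_json(list(truth = ds@truth, config = ds@config),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(dataset_id = ds@dataset_id, tracking = "tracking.csv",
                   spikes = "spikes.csv",
                   session_start_s = min(ds@tracking@timestamps),
                   session_end_s = max(ds@tracking@timestamps),
                   n_cells = nCells(ds@spikes))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' Read a dataset directory written by \code{\link{writeDataset}}
#'
#' @param dir dataset directory containing \code{manifest.json}.
#' @return an \linkS4class{HDDataset} (ground truth reattached if present).
#' @export
readDataset <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  stopIfNot(file.exists(mp), "input error: no manifest.json in directory")
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  track <- readTracking(file.path(dir, manifest$tracking))
  spikes <- readSpikes(file.path(dir, manifest$spikes))
  gt <- file.path(dir, "ground_truth.json")
  truth <- NULL; config <- list()
  if (file.exists(gt)) {
    g <- jsonlite::read_json(gt, simplifyVector = TRUE)
    truth <- as.data.frame(g$truth)
    config <- g$config
  }
  new("HDDataset", dataset_id = as.character(manifest$dataset_id),
      tracking = track, spikes = spikes, truth = truth, config = config)
}
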