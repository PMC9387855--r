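#' Construct an epoched task data set
#'
#' Container for epoched region-level time series: a 3D array of
#' trials x regions x samples plus per-trial metadata. Amplitudes are in
#' arbitrary units; time is in seconds on a uniform grid of spacing `1/fs`.
#'
#' @param data Numeric array `[trials x regions x samples]`.
#' @param fs Sampling rate in Hz.
#' @param times Numeric vector of per-sample times in seconds, strictly
#'   increasing with constant step `1/fs` (tolerance 1e-9 s).
#' @param lock `"stimulus"` or `"response"`.
#' @param condition Per-trial categorical label (e.g. `"left"`/`"right"`
#'   response hand).
#' @param rt Per-trial reaction time in seconds (required for
#'   response-locking); may be `NA` when never response-locked.
#' @param correct Per-trial logical.
#' @param region_ids Character vector naming the region axis.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, times, lock = c("stimulus", "response"),
                      condition, rt = NULL, correct = NULL,
                      region_ids = NULL) {
  lock <- match.arg(lock)
  if (length(dim(data)) != 3L) {
    stop("data must be a 3D array [trials x regions x samples]", call. = FALSE)
  }
  n_trials <- dim(data)[1]
  n_samples <- dim(data)[3]
  if (length(times) != n_samples) {
    stop("times length (", length(times), ") != sample count (", n_samples,
         ")", call. = FALSE)
  }
  check_uniform_times(times, fs)
  condition <- as.character(condition)
  if (length(condition) != n_trials) {
    stop("condition length != trial count", call. = FALSE)
  }
  if (is.null(rt)) rt <- rep(NA_real_, n_trials)
  if (is.null(correct)) correct <- rep(TRUE, n_trials)
  if (length(rt) != n_trials || length(correct) != n_trials) {
    stop("rt/correct length != trial count", call. = FALSE)
  }
  if (is.null(region_ids)) {
    region_ids <- paste0("R", seq_len(dim(data)[2]))
  }
  if (length(region_ids) != dim(data)[2]) {
    stop("region_ids length != region count", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, times = as.numeric(times), lock = lock,
         condition = condition, rt = as.numeric(rt),
         correct = as.logical(correct), region_ids = as.character(region_ids)),
    class = "epoch_set"
  )
}

check_uniform_times <- function(times, fs) {
  if (length(times) > 1) {
    steps <- diff(times)
    if (any(steps <= 0) || any(abs(steps - 1 / fs) > 1e-9)) {
      stop("times must be strictly increasing with constant step 1/fs",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a resting-state pseudo-trial set
#'
#' @param data Numeric array `[pseudo-trials x regions x samples]`.
#' @param fs Sampling rate in Hz.
#' @param region_ids Character vector naming the region axis.
#' @return An object of class `rest_set`.
#' @export
rest_set <- function(data, fs, region_ids = NULL) {
  if (length(dim(data)) != 3L) {
    stop("data must be a 3D array [pseudo-trials x regions x samples]",
         call. = FALSE)
  }
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(dim(data)[2]))
  if (length(region_ids) != dim(data)[2]) {
    stop("region_ids length != region count", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs,
         pseudo_trial_length = dim(data)[3] / fs,
         region_ids = as.character(region_ids)),
    class = "rest_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d regions x %d samples @ %g Hz (%s-locked)\n",
    d[1], d[2], d[3], x$fs, x$lock))
  cat(sprintf("  time %.3f..%.3f s; conditions: %s\n",
              min(x$times), max(x$times),
              paste(names(table(x$condition)), collapse = "/")))
  invisible(x)
}

#' @export
print.rest_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<rest_set> %d pseudo-trials x %d regions x %d samples @ %g Hz (%g s each)\n",
    d[1], d[2], d[3], x$fs, x$pseudo_trial_length))
  invisible(x)
}

#' Segment continuous rest data into non-overlapping pseudo-trials
#'
#' Consecutive, non-overlapping segments of `length_s` seconds are cut from a
#' continuous regions x samples matrix; any trailing remainder shorter than
#' one pseudo-trial is discarded. At the method's defaults (20 s at 200 Hz)
#' each pseudo-trial holds 4,000 samples.
#'
#' @param continuous Numeric matrix `[regions x samples]`.
#' @param fs Sampling rate in Hz.
#' @param length_s Pseudo-trial length in seconds.
#' @return A [rest_set].
#' @export
segment_rest <- function(continuous, fs, length_s) {
  stopifnot(is.matrix(continuous))
  seg_len <- round(length_s * fs)
  n_samples <- ncol(continuous)
  if (n_samples < seg_len) {
    stop("continuous duration (", n_samples / fs,
         " s) shorter than pseudo-trial length (", length_s, " s)",
         call. = FALSE)
  }
  n_seg <- n_samples %/% seg_len
  data <- array(NA_real_, c(n_seg, nrow(continuous), seg_len))
  for (k in seq_len(n_seg)) {
    data[k, , ] <- continuous[, ((k - 1) * seg_len + 1):(k * seg_len)]
  }
  rest_set(data, fs = fs, region_ids = rownames(continuous))
}

#' Re-lock stimulus-locked epochs to the behavioral response
#'
#' Re-epochs each trial around its response commission using the trial
#' reaction time, with nearest-sample rounding of the response time (no
#' interpolation). Trials whose requested window falls outside the
#' stimulus-locked epoch are dropped (and counted in a message); no padding
#' is ever applied.
#'
#' @param epochs A stimulus-locked [epoch_set] with finite `rt`.
#' @param window Length-2 numeric `(start_s, end_s)` relative to response
#'   commission; the default `c(-0.45, 0.45)` spans the response-locked
#'   analysis window.
#' @return A response-locked [epoch_set]; its time axis has a sample at t = 0
#'   aligned to the sample nearest the response.
#' @export
response_lock <- function(epochs, window = c(-0.45, 0.45)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$lock != "stimulus") {
    stop("epochs must be stimulus-locked", call. = FALSE)
  }
  if (anyNA(epochs$rt) || any(!is.finite(epochs$rt))) {
    stop("response_lock requires finite rt for all trials", call. = FALSE)
  }
  fs <- epochs$fs
  rel_idx <- round(window[1] * fs):round(window[2] * fs)
  out_times <- rel_idx / fs
  n_trials <- dim(epochs$data)[1]
  # nearest sample to each trial's response commission
  centre <- vapply(epochs$rt, function(r) which.min(abs(epochs$times - r)),
                   integer(1))
  keep <- logical(n_trials)
  n_samples <- dim(epochs$data)[3]
  for (tr in seq_len(n_trials)) {
    idx <- centre[tr] + rel_idx
    keep[tr] <- idx[1] >= 1 && idx[length(idx)] <= n_samples &&
      abs(epochs$times[centre[tr]] - epochs$rt[tr]) <= 0.5 / fs + 1e-9
  }
  if (!any(keep)) {
    stop("response_lock: all trials dropped (window exceeds every epoch)",
         call. = FALSE)
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("response_lock: dropped ", n_drop, " of ", n_trials,
            " trials whose window exceeded the epoch")
  }
  kept <- which(keep)
  data <- array(NA_real_, c(length(kept), dim(epochs$data)[2], length(rel_idx)))
  for (i in seq_along(kept)) {
    tr <- kept[i]
    data[i, , ] <- epochs$data[tr, , centre[tr] + rel_idx]
  }
  epoch_set(data, fs = fs, times = out_times, lock = "response",
            condition = epochs$condition[kept], rt = epochs$rt[kept],
            correct = epochs$correct[kept], region_ids = epochs$region_ids)
}

#' Decimate epochs by sequential sample selection
#'
#' Keeps every `factor`-th sample starting from the first, dividing the
#' sampling rate by `factor`. Deliberately applies no anti-alias filtering:
#' the decoding method treats decimation purely as sequential sample
#' selection.
#'
#' @param epochs An [epoch_set] or [rest_set].
#' @param factor Positive integer decimation factor.
#' @return The same type, decimated.
#' @export
decimate_epochs <- function(epochs, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  n_samples <- dim(epochs$data)[3]
  if (factor > n_samples) {
    stop("decimation factor (", factor, ") exceeds sample count (",
         n_samples, ")", call. = FALSE)
  }
  keep <- seq(1L, n_samples, by = as.integer(factor))
  if (inherits(epochs, "epoch_set")) {
    epoch_set(epochs$data[, , keep, drop = FALSE], fs = epochs$fs / factor,
              times = epochs$times[keep], lock = epochs$lock,
              condition = epochs$condition, rt = epochs$rt,
              correct = epochs$correct, region_ids = epochs$region_ids)
  } else if (inherits(epochs, "rest_set")) {
    rest_set(epochs$data[, , keep, drop = FALSE], fs = epochs$fs / factor,
             region_ids = epochs$region_ids)
  } else {
    stop("decimate_epochs expects an epoch_set or rest_set", call. = FALSE)
  }
}

#' Z-score each region's series within each trial
#'
#' Standardizes every (trial, region) series to mean 0 and variance 1. The
#' denominator is the population standard deviation (divide by n), the common
#' neural-time-series toolbox convention; this only rescales regressors
#' uniformly within a series.
#'
#' @param x An [epoch_set] or [rest_set].
#' @return The same type, standardized per trial and region.
#' @export
zscore_per_trial <- function(x) {
  stopifnot(inherits(x, "epoch_set") || inherits(x, "rest_set"))
  d <- x$data
  n <- dim(d)[3]
  mu <- rowMeans(d, dims = 2)
  centered <- d - as.vector(mu) # recycles over the sample axis
  sd_pop <- sqrt(rowMeans(centered^2, dims = 2))
  if (any(sd_pop == 0)) {
    bad <- which(sd_pop == 0, arr.ind = TRUE)[1, ]
    stop("zero-variance series at trial ", bad[1], ", region ", bad[2],
         call. = FALSE)
  }
  x$data <- centered / as.vector(sd_pop)
  x
}

#' Subset an epoch set by region and/or time
#'
#' @param epochs An [epoch_set].
#' @param regions Integer indices or region_id names to keep (default all).
#' @param time_range Optional `(start_s, end_s)`; samples with times inside
#'   the closed interval are kept.
#' @return An [epoch_set].
#' @export
subset_epochs <- function(epochs, regions = NULL, time_range = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  ridx <- seq_along(epochs$region_ids)
  if (!is.null(regions)) {
    ridx <- if (is.character(regions)) {
      match(regions, epochs$region_ids)
    } else {
      as.integer(regions)
    }
    if (anyNA(ridx)) stop("unknown region in subset", call. = FALSE)
  }
  tidx <- seq_along(epochs$times)
  if (!is.null(time_range)) {
    tidx <- which(epochs$times >= time_range[1] - 1e-9 &
                    epochs$times <= time_range[2] + 1e-9)
    if (!length(tidx)) stop("empty time selection", call. = FALSE)
  }
  epoch_set(epochs$data[, ridx, tidx, drop = FALSE], fs = epochs$fs,
            times = epochs$times[tidx], lock = epochs$lock,
            condition = epochs$condition, rt = epochs$rt,
            correct = epochs$correct,
            region_ids = epochs$region_ids[ridx])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an epoch set into a long tibble
#'
#' @param x An [epoch_set].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `region_id`, `time`, `amplitude`,
#'   `condition`, `correct`.
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    region_id = rep(rep(x$region_ids, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    amplitude = as.vector(x$data),
    condition = rep(x$condition, times = d[2] * d[3]),
    correct = rep(x$correct, times = d[2] * d[3])
  )
}

#' Read / write epoch and rest containers
#'
#' Serializes the full container (tensor plus all metadata fields) to a
#' single file via R's native serialization, with lossless round-trip: a
#' write followed by a read reproduces every field exactly.
#'
#' @param x An [epoch_set], [rest_set] or [mvar_fit].
#' @param path File path (conventionally `.rds`).
#' @return `read_epochs` returns the deserialized object; `write_epochs`
#'   returns `path` invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set") || inherits(x, "rest_set") ||
              inherits(x, "mvar_fit") || inherits(x, "flow_prediction"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_epochs
#' @param region_ids Optional character vector; when supplied, the stored
#'   region ids must match it exactly (consistency check against an atlas).
#' @export
read_epochs <- function(path, region_ids = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  x <- readRDS(path)
  if (!(inherits(x, "epoch_set") || inherits(x, "rest_set") ||
          inherits(x, "mvar_fit") || inherits(x, "flow_prediction"))) {
    stop("file does not contain a dynaflow container: ", path, call. = FALSE)
  }
  if (!is.null(region_ids) && !identical(x$region_ids, as.character(region_ids))) {
    stop("region_ids in file do not match the supplied atlas", call. = FALSE)
  }
  x
}
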