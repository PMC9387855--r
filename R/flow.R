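#' Configuration for dynamic activity flow prediction
#'
#' @param order Lag count p; must match the MVAR fit.
#' @param include_self_coupling Use the target's own lagged history (default
#'   `TRUE`; forced `FALSE` under network lesioning).
#' @param source_networks Character vector of predictor networks; default
#'   (`NULL`) means all networks except the target network. The target
#'   network is never a valid source.
#' @param leakage_regression Regress the target's contemporaneous series out
#'   of every source series (per trial, with intercept) before lagging, to
#'   control instantaneous field-spread leakage (default `TRUE`).
#' @return A `flow_config` list.
#' @export
flow_config <- function(order = 10, include_self_coupling = TRUE,
                        source_networks = NULL, leakage_regression = TRUE) {
  structure(
    list(order = order, include_self_coupling = include_self_coupling,
         source_networks = source_networks,
         leakage_regression = leakage_regression),
    class = "flow_config"
  )
}

#' Regress the target's series out of all source series
#'
#' Leakage control: per trial, every other region's series is replaced by
#' the residual of an ordinary least-squares fit (with intercept) of that
#' series on the target's series, removing all contemporaneous dependence
#' (residual-target Pearson correlation 0 within 1e-10). Run before any
#' lagging.
#'
#' @param task An [epoch_set].
#' @param target_index Region index whose series is regressed out.
#' @return An [epoch_set] with modified source series (target unchanged).
#' @export
regress_out_target <- function(task, target_index) {
  stopifnot(inherits(task, "epoch_set"))
  out <- task
  n_trials <- dim(task$data)[1]
  for (tr in seq_len(n_trials)) {
    y0 <- task$data[tr, target_index, ]
    v <- stats::var(y0)
    if (!is.finite(v) || v == 0) {
      stop("zero-variance target series in trial ", tr, call. = FALSE)
    }
    X <- task$data[tr, , ]
    y0c <- y0 - mean(y0)
    b1 <- (X %*% y0c) / sum(y0c^2) # per-row slope of source ~ target
    resid <- X - rowMeans(X) - b1 %*% t(y0c)
    resid[target_index, ] <- y0
    out$data[tr, , ] <- resid
  }
  out
}

flow_source_regions <- function(fit, cfg) {
  atlas <- fit$atlas
  nets <- cfg$source_networks
  if (is.null(nets)) nets <- setdiff(unique(atlas$network), fit$target_network)
  if (fit$target_network %in% nets) {
    stop("source_networks must exclude the target network", call. = FALSE)
  }
  which(atlas$network %in% nets)
}

#' Predict future target-network activation by dynamic activity flow
#'
#' One-step-ahead (teacher-forced) prediction: for each target region j,
#' trial, and time point t0 with a full p-lag history, the prediction is the
#' dot product of the lagged actual source activations with the rest-derived
#' lagged source weights, plus the lagged actual target activation weighted
#' by the self-coupling terms. Predictions never feed back into later
#' predictions. Sources are restricted to `cfg$source_networks`; the other
#' target-network regions and all contemporaneous terms are excluded.
#'
#' @param task An [epoch_set] at the sampling rate of the fit; when
#'   `cfg$leakage_regression` is `TRUE` the target's contemporaneous series
#'   is regressed out of the sources per target before lagging.
#' @param fit An `mvar_fit`.
#' @param cfg A [flow_config]; its order must match the fit.
#' @return A `flow_prediction`: an [epoch_set]-like object restricted to the
#'   target regions, with `valid_mask` marking time points having a full
#'   p-lag history (predictions elsewhere are `NA`). Trial metadata is
#'   copied verbatim from the actual data.
#' @export
predict_target <- function(task, fit, cfg = flow_config(order = fit$order)) {
  stopifnot(inherits(task, "epoch_set"), inherits(fit, "mvar_fit"))
  if (cfg$order != fit$order) {
    stop("config order (", cfg$order, ") does not match fit order (",
         fit$order, ")", call. = FALSE)
  }
  if (!identical(task$region_ids, fit$region_ids)) {
    stop("task region_ids do not match the fit", call. = FALSE)
  }
  p <- fit$order
  n_samp <- dim(task$data)[3]
  if (n_samp < p + 1) {
    stop("epoch too short: no sample has a full ", p, "-lag history",
         call. = FALSE)
  }
  allowed <- flow_source_regions(fit, cfg)
  targets <- fit$targets
  n_trials <- dim(task$data)[1]
  pred <- array(NA_real_, c(n_trials, length(targets), n_samp))
  valid <- seq_len(n_samp) > p
  for (j in seq_along(targets)) {
    tj <- targets[j]
    dat <- if (cfg$leakage_regression) {
      regress_out_target(task, tj)$data
    } else {
      task$data
    }
    W <- fit$F[j, allowed, , drop = FALSE] # 1 x sources x lags
    for (tr in seq_len(n_trials)) {
      acc <- numeric(n_samp - p)
      if (length(allowed)) {
        Xs <- dat[tr, allowed, , drop = TRUE]
        if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = 1)
        for (i in seq_len(p)) {
          acc <- acc + drop(crossprod(Xs[, (p + 1 - i):(n_samp - i),
                                         drop = FALSE], W[1, , i]))
        }
      }
      if (cfg$include_self_coupling) {
        yown <- task$data[tr, tj, ]
        for (i in seq_len(p)) {
          acc <- acc + yown[(p + 1 - i):(n_samp - i)] * fit$C[j, i]
        }
      }
      pred[tr, j, (p + 1):n_samp] <- acc
    }
  }
  structure(
    list(data = pred, fs = task$fs, times = task$times, lock = task$lock,
         condition = task$condition, rt = task$rt, correct = task$correct,
         region_ids = fit$region_ids[targets], valid_mask = valid,
         order = p, target_network = fit$target_network,
         source_networks = if (is.null(cfg$source_networks)) {
           setdiff(unique(fit$atlas$network), fit$target_network)
         } else {
           cfg$source_networks
         },
         include_self_coupling = cfg$include_self_coupling),
    class = c("flow_prediction", "epoch_set")
  )
}

#' @export
print.flow_prediction <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<flow_prediction> %d trials x %d %s targets x %d samples (%d valid)\n",
    d[1], d[2], x$target_network, d[3], sum(x$valid_mask)))
  cat("  sources:", paste(x$source_networks, collapse = ", "),
      if (x$include_self_coupling) "+ self-coupling" else "(no self-coupling)",
      "\n")
  invisible(x)
}

#' Crop a flow prediction to its valid samples
#'
#' Drops the leading buffer samples that lack a full lag history, returning
#' a plain [epoch_set] of predicted target activations.
#'
#' @param pred A `flow_prediction`.
#' @return An [epoch_set].
#' @export
crop_to_valid <- function(pred) {
  stopifnot(inherits(pred, "flow_prediction"))
  keep <- which(pred$valid_mask)
  epoch_set(pred$data[, , keep, drop = FALSE], fs = pred$fs,
            times = pred$times[keep], lock = pred$lock,
            condition = pred$condition, rt = pred$rt, correct = pred$correct,
            region_ids = pred$region_ids)
}

#' Predict with all networks lesioned except one
#'
#' Runs [predict_target] with the source set restricted to a single
#' functional network and the self-coupling terms excluded, reusing the full
#' fit's weights without re-estimation. The resulting time course captures
#' that network's unique contribution to activity flowing into the target
#' network; summing the single-network predictions plus a
#' self-coupling-only prediction reproduces the full model exactly.
#'
#' @param task An [epoch_set].
#' @param fit An `mvar_fit`.
#' @param network The one non-lesioned network (must not be the target
#'   network).
#' @param leakage_regression Passed through to [flow_config].
#' @return A `flow_prediction`.
#' @export
lesion_predict <- function(task, fit, network, leakage_regression = TRUE) {
  if (network == fit$target_network) {
    stop("cannot lesion down to the target network itself", call. = FALSE)
  }
  if (!network %in% fit$atlas$network) {
    stop("unknown network: ", network, call. = FALSE)
  }
  cfg <- flow_config(order = fit$order, include_self_coupling = FALSE,
                     source_networks = network,
                     leakage_regression = leakage_regression)
  predict_target(task, fit, cfg)
}

#' Self-coupling-only prediction
#'
#' Companion to [lesion_predict]: prediction from the target's own lagged
#' history alone, with every source network lesioned.
#'
#' @inheritParams lesion_predict
#' @return A `flow_prediction`.
#' @export
self_coupling_predict <- function(task, fit, leakage_regression = TRUE) {
  cfg <- flow_config(order = fit$order, include_self_coupling = TRUE,
                     source_networks = character(0),
                     leakage_regression = leakage_regression)
  predict_target(task, fit, cfg)
}
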