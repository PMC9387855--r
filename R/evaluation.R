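#' Predicted-to-actual time course overlap
#'
#' Quantifies how well predicted time courses capture the actual ones:
#' Pearson correlation of the group-mean time courses (`r_group`),
#' per-subject Pearson correlations tested against 0 by a one-sample t test
#' on Fisher-z values, and the per-subject coefficient of determination
#' `R^2 = 1 - SSres / SStot` (SStot about the actual subject mean, so R^2
#' may be negative and 0 marks the mean-only null model), tested against 0
#' untransformed.
#'
#' @param predicted,actual Numeric `[subjects x times]` matrices (or
#'   vectors for a single subject) on matched time axes.
#' @return An `overlap_report` list: `r_group`, `r_subjects`,
#'   `t_p_subjects`, `r2_subjects`, `r2_p`, `n_subjects`.
#' @export
timecourse_overlap <- function(predicted, actual) {
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  if (is.vector(actual)) actual <- matrix(actual, nrow = 1)
  stopifnot(all(dim(predicted) == dim(actual)))
  n_sub <- nrow(actual)
  for (s in seq_len(n_sub)) {
    if (stats::var(actual[s, ]) == 0) {
      stop("constant actual time course for subject ", s,
           "; correlation undefined", call. = FALSE)
    }
  }
  gm_pred <- colMeans(predicted)
  r_group <- if (stats::sd(gm_pred) == 0) NA_real_ else
    stats::cor(gm_pred, colMeans(actual))
  r_subjects <- vapply(seq_len(n_sub), function(s) {
    if (stats::var(predicted[s, ]) == 0) NA_real_ else
      stats::cor(predicted[s, ], actual[s, ])
  }, numeric(1))
  r2_subjects <- vapply(seq_len(n_sub), function(s) {
    1 - sum((actual[s, ] - predicted[s, ])^2) /
      sum((actual[s, ] - mean(actual[s, ]))^2)
  }, numeric(1))
  t_p <- if (n_sub >= 2 && sum(!is.na(r_subjects)) >= 2) {
    z <- atanh(pmin(pmax(r_subjects[!is.na(r_subjects)], -1 + 1e-12),
                    1 - 1e-12))
    if (stats::sd(z) == 0) 0 else stats::t.test(z)$p.value
  } else {
    NA_real_
  }
  r2_p <- if (n_sub >= 2 && stats::sd(r2_subjects) > 0) {
    stats::t.test(r2_subjects)$p.value
  } else {
    NA_real_
  }
  structure(
    list(r_group = r_group, r_subjects = r_subjects, t_p_subjects = t_p,
         r2_subjects = r2_subjects, r2_p = r2_p, n_subjects = n_sub),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> group r = %.3f; subject r mean = %.3f (p = %s); R2 mean = %.3f (p = %s)\n",
    x$r_group, mean(x$r_subjects, na.rm = TRUE), format.pval(x$t_p_subjects),
    mean(x$r2_subjects), format.pval(x$r2_p)))
  invisible(x)
}

#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(
    r_group = x$r_group,
    r_subject_mean = mean(x$r_subjects, na.rm = TRUE),
    t_p_subjects = x$t_p_subjects,
    r2_mean = mean(x$r2_subjects), r2_p = x$r2_p,
    n_subjects = x$n_subjects
  )
}

#' @export
tidy.overlap_report <- function(x, ...) {
  tibble::tibble(subject = seq_len(x$n_subjects), r = x$r_subjects,
                 r2 = x$r2_subjects)
}

scramble_fit <- function(fit, perm_seed) {
  atlas <- fit$atlas
  non_target <- which(atlas$network != fit$target_network)
  out <- fit
  withr_seed(perm_seed, {
    for (j in seq_len(dim(fit$F)[1])) {
      # one random source permutation per target, shared across lags,
      # preserving the lag structure and the self-coupling terms
      pm <- sample(non_target)
      out$F[j, non_target, ] <- fit$F[j, pm, ]
    }
  })
  out
}

#' FC-scrambling permutation null for the flow-prediction overlap
#'
#' Repeatedly scrambles the lagged source-weight tensor (the source-region
#' axis of `F` is permuted independently per target, one permutation shared
#' across lags) while leaving the autoregressive self-coupling terms intact,
#' re-runs the full predict-and-score pipeline, and returns the add-one
#' permutation p-value `p = (1 + #{permuted >= observed}) / (1 + n_perm)`.
#'
#' @param task An [epoch_set] for one subject.
#' @param fit The subject's `mvar_fit`.
#' @param statistic `"decode"` (default: decode the predicted target
#'   activations and correlate the decoding time course with the actual
#'   one), `"activation"` (Pearson r between predicted and actual target
#'   activation series over all trials and valid samples; far more sensitive
#'   at small region counts, where linear decoders are invariant to the
#'   linear map the weights implement — see the package vignette), or a
#'   custom function `(flow_prediction) -> scalar`.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @param cfg A [flow_config] for the predictions.
#' @param decode_args List of arguments for the `"decode"` statistic's
#'   decoding step (`set_size`, `n_iter`, `n_folds`, `train_frac`).
#' @return A list: `p`, `observed`, `permuted` (length `n_perm`).
#' @export
permutation_null <- function(task, fit, statistic = c("decode", "activation"),
                             n_perm = 500,
                             seed = 1, cfg = flow_config(order = fit$order),
                             decode_args = list(set_size = 14, n_iter = 2,
                                                n_folds = 5,
                                                train_frac = 0.2)) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.function(statistic)) {
    kind <- match.arg(statistic)
    if (kind == "decode") {
      # decode the actual target regions once; the statistic correlates each
      # prediction's decoding time course with this reference
      p <- fit$order
      actual_target <- subset_epochs(task, regions = fit$targets)
      actual_target <- subset_epochs(
        actual_target, time_range = c(task$times[p + 1], max(task$times)))
      ref <- do.call(decode_epochs,
                     c(list(actual_target, seed = expand_seed(seed, "ref")),
                       decode_args))
      statistic <- function(pred) {
        dec <- do.call(decode_epochs,
                       c(list(crop_to_valid(pred),
                              seed = expand_seed(seed, "stat")), decode_args))
        stats::cor(dec$accuracy, ref$accuracy)
      }
    } else {
      actual_mat <- task$data[, fit$targets, , drop = FALSE]
      statistic <- function(pred) {
        v <- pred$valid_mask
        stats::cor(as.vector(pred$data[, , v, drop = FALSE]),
                   as.vector(actual_mat[, , v, drop = FALSE]))
      }
    }
  }
  observed <- statistic(predict_target(task, fit, cfg))
  permuted <- vapply(seq_len(n_perm), function(b) {
    fit_b <- scramble_fit(fit, expand_seed(seed, "perm", b))
    statistic(predict_target(task, fit_b, cfg))
  }, numeric(1))
  list(p = (1 + sum(permuted >= observed)) / (1 + n_perm),
       observed = observed, permuted = permuted)
}

#' Template-correlation representational overlap
#'
#' Tests whether response information in held-out test data can be decoded
#' from condition templates learned in training data: per fold and time
#' point, templates are the mean training pattern per condition, and the
#' metric per test subtrial is `r(test pattern, correct template) -
#' r(test pattern, incorrect template)`, averaged over test subtrials,
#' folds, and subtrial iterations. Setting `train` to predicted activations
#' and `test` to actual ones gives the TrainPred-TestActual variant; using
#' the actual data for both gives TrainActual-TestActual. Train and test
#' sets share the subtrial assignment (the same trial indices), so folds
#' stay disjoint across the paired data sets.
#'
#' @param train,test [epoch_set]s sharing region set, time axis, and trial
#'   metadata.
#' @param set_size,n_iter Subtrial averaging parameters (see
#'   [make_subtrials]).
#' @param n_folds Cross-validation folds.
#' @param train_frac Training fraction per condition.
#' @param seed Integer seed.
#' @return A tibble with columns `time` and `information` (correct-minus-
#'   incorrect r).
#' @export
representational_overlap <- function(train, test, set_size = 14, n_iter = 10,
                                     n_folds = 10, train_frac = 0.2,
                                     seed = 1) {
  stopifnot(inherits(train, "epoch_set"), inherits(test, "epoch_set"))
  if (!identical(train$region_ids, test$region_ids) ||
        length(train$times) != length(test$times)) {
    stop("train and test must share region set and time axis", call. = FALSE)
  }
  st_train <- make_subtrials(train, set_size = set_size, n_iter = n_iter,
                             seed = expand_seed(seed, "subtrials"))
  st_test <- make_subtrials(test, set_size = set_size, n_iter = n_iter,
                            seed = expand_seed(seed, "subtrials"))
  n <- st_train$n_subtrials
  n_train <- ceiling(train_frac * n)
  n_test <- floor((1 - train_frac) * n)
  if (n_train + n_test > n) n_test <- n - n_train
  if (n_train < 1 || n_test < 1) {
    stop("train or test count is zero", call. = FALSE)
  }
  n_time <- length(st_train$times)
  info_iter <- matrix(0, n_iter, n_time)
  withr_seed(expand_seed(seed, "folds"), {
    for (it in seq_len(n_iter)) {
      tr1 <- st_train$iterations[[it]][[1]]$data
      tr2 <- st_train$iterations[[it]][[2]]$data
      te1 <- st_test$iterations[[it]][[1]]$data
      te2 <- st_test$iterations[[it]][[2]]$data
      folds <- sample_folds(n, n_train, n_test, n_folds)
      info_fold <- matrix(NA_real_, n_folds, n_time)
      for (f in seq_len(n_folds)) {
        fd <- folds[[f]]
        for (t in seq_len(n_time)) {
          tpl1 <- colMeans(tr1[fd$train[[1]], , t, drop = FALSE][, , 1,
                                                                 drop = FALSE])
          tpl2 <- colMeans(tr2[fd$train[[2]], , t, drop = FALSE][, , 1,
                                                                 drop = FALSE])
          if (stats::sd(tpl1) == 0 || stats::sd(tpl2) == 0) {
            stop("zero-variance condition template at time index ", t,
                 call. = FALSE)
          }
          vals <- c(
            vapply(fd$test[[1]], function(k) {
              pat <- te1[k, , t]
              stats::cor(pat, tpl1) - stats::cor(pat, tpl2)
            }, numeric(1)),
            vapply(fd$test[[2]], function(k) {
              pat <- te2[k, , t]
              stats::cor(pat, tpl2) - stats::cor(pat, tpl1)
            }, numeric(1))
          )
          info_fold[f, t] <- mean(vals)
        }
      }
      info_iter[it, ] <- colMeans(info_fold)
    }
  })
  tibble::tibble(time = st_train$times, information = colMeans(info_iter))
}

#' Lateralized motor ERP for one subject
#'
#' Labels target-network regions contralateral or ipsilateral to each
#' trial's response hand (left response <-> right hemisphere and vice
#' versa), averages across regions and trials, and returns the
#' contralateral-minus-ipsilateral difference wave plus per-region waveforms
#' for spatial overlap scoring.
#'
#' @param epochs A response-locked [epoch_set] whose condition labels are
#'   the response hands (`"left"`/`"right"`).
#' @param atlas A [region_atlas]; the target network must have regions in
#'   both hemispheres.
#' @param target_network Target network name.
#' @return A list: `diff_wave` tibble (`time`, `amplitude`),
#'   `region_waves` `[regions x times]` matrix of trial-averaged target
#'   activations, `times`, `region_ids`.
#' @export
motor_erp <- function(epochs, atlas, target_network = "Motor") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$lock != "response") {
    stop("motor ERP requires response-locked epochs", call. = FALSE)
  }
  tgt <- network_regions(atlas, target_network)
  hemi <- atlas$hemisphere[tgt]
  if (any(!hemi %in% c("left", "right"))) {
    stop("hemisphere missing (or midline) for a target region", call. = FALSE)
  }
  if (!all(c("left", "right") %in% hemi)) {
    stop("target network needs regions in both hemispheres", call. = FALSE)
  }
  keep <- which(epochs$correct & epochs$condition %in% c("left", "right"))
  if (!length(keep)) stop("no usable trials", call. = FALSE)
  n_time <- length(epochs$times)
  contra <- matrix(0, length(keep), n_time)
  ipsi <- matrix(0, length(keep), n_time)
  tgt_idx <- match(atlas$region_id[tgt], epochs$region_ids)
  if (anyNA(tgt_idx)) {
    stop("target regions absent from the epochs", call. = FALSE)
  }
  avg_regions <- function(tr, idx) {
    apply(epochs$data[tr, idx, , drop = FALSE], 3, mean)
  }
  for (i in seq_along(keep)) {
    tr <- keep[i]
    opp <- if (epochs$condition[tr] == "left") "right" else "left"
    contra[i, ] <- avg_regions(tr, tgt_idx[hemi == opp])
    ipsi[i, ] <- avg_regions(tr, tgt_idx[hemi != opp])
  }
  region_waves <- t(vapply(tgt_idx, function(rg) {
    apply(epochs$data[keep, rg, , drop = FALSE], 3, mean)
  }, numeric(n_time)))
  rownames(region_waves) <- atlas$region_id[tgt]
  list(
    diff_wave = tibble::tibble(time = epochs$times,
                               amplitude = colMeans(contra) - colMeans(ipsi)),
    region_waves = region_waves, times = epochs$times,
    region_ids = atlas$region_id[tgt]
  )
}

#' Group-level motor ERP report with predicted-to-actual overlap
#'
#' Combines per-subject [motor_erp] results for actual (and optionally
#' model-predicted) data: per-sample Wilcoxon signed-rank tests of the
#' difference wave against 0 with Bonferroni correction, and — when
#' predictions are supplied — temporal overlap (difference waves), spatial
#' overlap (per-region activations averaged over `spatial_window`, e.g. the
#' epoch of significance in the actual data), and spatiotemporal overlap
#' (region x time concatenation), each at group and subject level.
#'
#' @param actual_erps List of per-subject [motor_erp] results for the actual
#'   data.
#' @param predicted_erps Optional matching list for the predicted data.
#' @param spatial_window `(start_s, end_s)` epoch over which per-region
#'   activations are averaged for the spatial overlap (a parameter, derived
#'   by the caller from the actual data's significance mask).
#' @param alpha Significance level.
#' @return An `erp_report` list: `diff_stats` tibble for the actual data,
#'   `predicted_diff_stats` when predictions are given, and overlap reports
#'   `temporal`, `spatial`, `spatiotemporal` ([timecourse_overlap] objects).
#' @export
erp_report <- function(actual_erps, predicted_erps = NULL,
                       spatial_window = NULL, alpha = 0.05) {
  times <- actual_erps[[1]]$times
  amp <- do.call(rbind, lapply(actual_erps, function(e) e$diff_wave$amplitude))
  diff_stats_of <- function(m) {
    p_raw <- apply(m, 2, signed_rank_test)
    p_bonf <- pmin(1, p_raw * ncol(m))
    tibble::tibble(time = times, mean_amplitude = colMeans(m), p_raw = p_raw,
                   p_bonferroni = p_bonf, significant = p_bonf < alpha)
  }
  out <- list(diff_stats = diff_stats_of(amp), times = times)
  if (!is.null(predicted_erps)) {
    amp_p <- do.call(rbind,
                     lapply(predicted_erps, function(e) e$diff_wave$amplitude))
    out$predicted_diff_stats <- diff_stats_of(amp_p)
    out$temporal <- timecourse_overlap(amp_p, amp)
    if (!is.null(spatial_window)) {
      idx <- which(times >= spatial_window[1] - 1e-9 &
                     times <= spatial_window[2] + 1e-9)
      sp_a <- do.call(rbind, lapply(actual_erps, function(e) {
        rowMeans(e$region_waves[, idx, drop = FALSE])
      }))
      sp_p <- do.call(rbind, lapply(predicted_erps, function(e) {
        rowMeans(e$region_waves[, idx, drop = FALSE])
      }))
      out$spatial <- timecourse_overlap(sp_p, sp_a)
    }
    st_a <- do.call(rbind,
                    lapply(actual_erps, function(e) as.vector(e$region_waves)))
    st_p <- do.call(rbind, lapply(predicted_erps,
                                  function(e) as.vector(e$region_waves)))
    out$spatiotemporal <- timecourse_overlap(st_p, st_a)
  }
  class(out) <- "erp_report"
  out
}

#' @export
print.erp_report <- function(x, ...) {
  cat(sprintf("<erp_report> %d time points, %d significant (actual)\n",
              nrow(x$diff_stats), sum(x$diff_stats$significant)))
  if (!is.null(x$temporal)) {
    cat(sprintf("  temporal overlap r_group = %.3f\n", x$temporal$r_group))
  }
  if (!is.null(x$spatial)) {
    cat(sprintf("  spatial overlap r_group = %.3f\n", x$spatial$r_group))
  }
  invisible(x)
}
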