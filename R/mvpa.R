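#' Average trials into non-overlapping subtrial sets
#'
#' Boosts signal-to-noise before classification: incorrect trials are
#' removed, and within each condition the remaining trials are averaged over
#' non-overlapping sets of `set_size` (floor(n / set_size) subtrials per
#' condition; leftover trials unused). The assignment of trials to sets is
#' randomized over `n_iter` iterations while preserving non-overlap within
#' each iteration, and both conditions are truncated to the smaller subtrial
#' count so classes stay balanced.
#'
#' @param epochs An [epoch_set] with exactly two condition levels.
#' @param set_size Trials averaged per subtrial (default 14).
#' @param n_iter Number of randomized assignment iterations (default 10).
#' @param seed Integer seed; assignments are deterministic given the seed.
#' @return An object of class `subtrial_set`: per iteration and condition, a
#'   `[subtrials x regions x samples]` array plus the source trial indices.
#' @export
make_subtrials <- function(epochs, set_size = 14, n_iter = 10, seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(epochs$correct)
  conds <- sort(unique(epochs$condition[keep]))
  if (length(conds) != 2) {
    stop("decoding requires exactly 2 condition levels, got ",
         length(conds), call. = FALSE)
  }
  idx_by_cond <- lapply(conds, function(cc) keep[epochs$condition[keep] == cc])
  set_size <- as.integer(set_size)
  n_sub <- vapply(idx_by_cond, function(ix) length(ix) %/% set_size,
                  integer(1))
  n_sub_common <- min(n_sub)
  if (n_sub_common < 2) {
    stop("fewer than 2 subtrials per condition (",
         paste(n_sub, collapse = "/"), "); need >= 2*set_size correct trials",
         call. = FALSE)
  }
  n_regions <- dim(epochs$data)[2]
  n_samples <- dim(epochs$data)[3]
  iterations <- withr_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      per_cond <- lapply(seq_along(conds), function(ci) {
        ix <- sample(idx_by_cond[[ci]])
        sets <- lapply(seq_len(n_sub_common), function(k) {
          ix[((k - 1) * set_size + 1):(k * set_size)]
        })
        arr <- array(NA_real_, c(n_sub_common, n_regions, n_samples))
        for (k in seq_len(n_sub_common)) {
          arr[k, , ] <- colMeans(
            epochs$data[sets[[k]], , , drop = FALSE], dims = 1)
        }
        list(data = arr, indices = sets)
      })
      names(per_cond) <- conds
      per_cond
    })
  })
  structure(
    list(iterations = iterations, conditions = conds,
         n_subtrials = n_sub_common, set_size = set_size,
         times = epochs$times, region_ids = epochs$region_ids),
    class = "subtrial_set"
  )
}

# sample fold assignments: unique (train set, test set) combination per fold
sample_folds <- function(n, n_train, n_test, n_folds, max_tries = 100) {
  seen <- character(0)
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      tr1 <- sort(sample.int(n, n_train))
      tr2 <- sort(sample.int(n, n_train))
      te1 <- sort(sample(setdiff(seq_len(n), tr1), n_test))
      te2 <- sort(sample(setdiff(seq_len(n), tr2), n_test))
      key <- paste(c(tr1, te1, tr2, te2), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        folds[[f]] <- list(train = list(tr1, tr2), test = list(te1, te2))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not draw ", n_folds,
           " distinct train/test combinations after bounded retries",
           call. = FALSE)
    }
  }
  folds
}

svm_accuracy <- function(x_train, y_train, x_test, y_test) {
  fit <- e1071::svm(x = x_train, y = y_train, kernel = "linear", cost = 1,
                    scale = FALSE, type = "C-classification")
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  pos <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
  lab <- ifelse(dv > 0, pos, setdiff(levels(y_train), pos))
  # exactly-zero decision value counts as incorrect (conservative tie rule)
  100 * mean(lab == as.character(y_test) & dv != 0)
}

#' Time-resolved two-class decoding for one subject
#'
#' Trains a linear support vector machine (cost 1, no internal feature
#' scaling) separately at every trial time point, with regions as features
#' and subtrials as observations. Per fold the training count per condition
#' is `ceiling(train_frac * n)` (rounded up) and the testing count
#' `floor((1 - train_frac) * n)` (rounded down), equated across conditions;
#' no identical train/test combination repeats across folds. Fold accuracies
#' are averaged, then averaged across subtrial iterations.
#'
#' @param subtrials A [make_subtrials] result.
#' @param n_folds Cross-validation folds (default 10).
#' @param train_frac Training fraction per condition (default 0.2, matching
#'   the worked fold arithmetic: 8 subtrials give 2 training and 6 testing
#'   subtrials per condition; see the package vignette for why this default,
#'   not 0.8, honors the reference procedure).
#' @param seed Integer seed for fold assignment.
#' @return A tibble with columns `time` and `accuracy` (percent).
#' @export
decode_timecourse <- function(subtrials, n_folds = 10, train_frac = 0.2,
                              seed = 1) {
  stopifnot(inherits(subtrials, "subtrial_set"))
  n <- subtrials$n_subtrials
  n_train <- ceiling(train_frac * n)
  n_test <- floor((1 - train_frac) * n)
  if (n_train < 1 || n_test < 1) {
    stop("train or test count is zero (n = ", n, ", train_frac = ",
         train_frac, ")", call. = FALSE)
  }
  if (n_train + n_test > n) n_test <- n - n_train
  n_time <- length(subtrials$times)
  conds <- subtrials$conditions
  acc_iter <- matrix(0, length(subtrials$iterations), n_time)
  withr_seed(seed, {
    for (it in seq_along(subtrials$iterations)) {
      d1 <- subtrials$iterations[[it]][[1]]$data
      d2 <- subtrials$iterations[[it]][[2]]$data
      folds <- sample_folds(n, n_train, n_test, n_folds)
      acc_fold <- matrix(NA_real_, n_folds, n_time)
      for (f in seq_len(n_folds)) {
        fd <- folds[[f]]
        y_train <- factor(rep(conds, each = n_train), levels = conds)
        y_test <- factor(rep(conds, each = n_test), levels = conds)
        for (t in seq_len(n_time)) {
          x_train <- rbind(d1[fd$train[[1]], , t, drop = FALSE][, , 1],
                           d2[fd$train[[2]], , t, drop = FALSE][, , 1])
          x_test <- rbind(d1[fd$test[[1]], , t, drop = FALSE][, , 1],
                          d2[fd$test[[2]], , t, drop = FALSE][, , 1])
          acc_fold[f, t] <- svm_accuracy(x_train, y_train, x_test, y_test)
        }
      }
      acc_iter[it, ] <- colMeans(acc_fold)
    }
  })
  tibble::tibble(time = subtrials$times, accuracy = colMeans(acc_iter))
}

#' Decode one subject's epochs end to end
#'
#' Convenience wrapper: [make_subtrials] then [decode_timecourse].
#'
#' @param epochs An [epoch_set].
#' @inheritParams make_subtrials
#' @inheritParams decode_timecourse
#' @return A tibble with columns `time` and `accuracy`.
#' @export
decode_epochs <- function(epochs, set_size = 14, n_iter = 10, n_folds = 10,
                          train_frac = 0.2, seed = 1) {
  st <- make_subtrials(epochs, set_size = set_size, n_iter = n_iter,
                       seed = expand_seed(seed, "subtrials"))
  decode_timecourse(st, n_folds = n_folds, train_frac = train_frac,
                    seed = expand_seed(seed, "folds"))
}

#' Assemble per-subject decoding time courses into a group result
#'
#' @param timecourses List of per-subject tibbles from [decode_timecourse]
#'   (matching time axes), or a numeric `[subjects x times]` matrix.
#' @param times Time axis (required when a matrix is given).
#' @return An object of class `decoding_result` holding the
#'   `[subjects x times]` accuracy matrix; group statistics are added by
#'   [group_stats].
#' @export
decoding_result <- function(timecourses, times = NULL) {
  if (is.list(timecourses) && !is.matrix(timecourses)) {
    times <- timecourses[[1]]$time
    acc <- do.call(rbind, lapply(timecourses, function(d) d$accuracy))
  } else {
    acc <- as.matrix(timecourses)
    if (is.null(times)) stop("times required with a matrix input",
                             call. = FALSE)
  }
  structure(list(accuracy = acc, times = as.numeric(times), stats = NULL),
            class = "decoding_result")
}

# one-sample Wilcoxon signed-rank test, two-sided.
# Zero differences are discarded (classic signed-rank); exact distribution
# for n <= 25 without ties in |d|, otherwise normal approximation with
# continuity and tie corrections.
signed_rank_test <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(w, n), 1 - stats::psignrank(w - 1, n))
    return(min(1, p))
  }
  mu_w <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tie_tab^3 - tie_tab) / 48)
  if (sigma == 0) return(1)
  z <- (w - mu_w - sign(w - mu_w) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Group statistics for a decoding result
#'
#' Per time point, a two-sided one-sample Wilcoxon signed-rank test of the
#' subject accuracies against chance, Bonferroni-corrected across time
#' points.
#'
#' @param result A [decoding_result] (needs >= 6 subjects).
#' @param chance Chance level in percent (default 50).
#' @param alpha Family-wise significance level (default 0.05).
#' @return The `decoding_result` with a `stats` tibble (`time`, `mean_acc`,
#'   `p_raw`, `p_bonferroni`, `significant`) and fields `chance`, `alpha`.
#' @export
group_stats <- function(result, chance = 50, alpha = 0.05) {
  stopifnot(inherits(result, "decoding_result"))
  if (nrow(result$accuracy) < 6) {
    stop("group statistics need at least 6 subjects", call. = FALSE)
  }
  n_time <- length(result$times)
  p_raw <- vapply(seq_len(n_time), function(t) {
    signed_rank_test(result$accuracy[, t], mu = chance)
  }, numeric(1))
  p_bonf <- pmin(1, p_raw * n_time)
  result$stats <- tibble::tibble(
    time = result$times,
    mean_acc = colMeans(result$accuracy),
    p_raw = p_raw, p_bonferroni = p_bonf,
    significant = p_bonf < alpha
  )
  result$chance <- chance
  result$alpha <- alpha
  result
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d subjects x %d time points (%.3f..%.3f s)\n",
              nrow(x$accuracy), length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$stats)) {
    cat(sprintf("  peak group accuracy %.1f%%; %d significant time points\n",
                max(x$stats$mean_acc), sum(x$stats$significant)))
  }
  invisible(x)
}

#' Tidy a decoding result
#'
#' @param x A [decoding_result].
#' @param ... Unused.
#' @return A long tibble (`subject`, `time`, `accuracy`) joined with group
#'   statistics when present.
#' @export
tidy.decoding_result <- function(x, ...) {
  out <- tibble::tibble(
    subject = rep(seq_len(nrow(x$accuracy)), times = ncol(x$accuracy)),
    time = rep(x$times, each = nrow(x$accuracy)),
    accuracy = as.vector(x$accuracy)
  )
  if (!is.null(x$stats)) {
    out <- dplyr::left_join(out, x$stats, by = "time")
  }
  out
}

#' One-row summary of a decoding result
#'
#' @param x A [decoding_result].
#' @param ... Unused.
#' @return A tibble with subject count, peak group accuracy and its time,
#'   and the number of significant time points (when stats are present).
#' @export
glance.decoding_result <- function(x, ...) {
  gm <- colMeans(x$accuracy)
  tibble::tibble(
    n_subjects = nrow(x$accuracy),
    n_timepoints = length(x$times),
    peak_accuracy = max(gm),
    peak_time = x$times[which.max(gm)],
    n_significant = if (is.null(x$stats)) NA_integer_ else
      sum(x$stats$significant)
  )
}

#' Extract decoding peaks within time windows
#'
#' For each window, the group time-to-peak is the argmax of the group-mean
#' accuracy (earliest maximum on ties); each subject's peak is their
#' accuracy at that group time. `mode = "subject"` instead takes each
#' subject's own argmax within the window (the unbiased variant).
#'
#' @param result A [decoding_result].
#' @param peak_windows List of `(start_s, end_s)` windows within the decoded
#'   range.
#' @param mode `"group"` (default) or `"subject"`.
#' @return A tibble with columns `window`, `peak_time` (`NA` in subject
#'   mode), `subject`, `accuracy`.
#' @export
extract_peaks <- function(result, peak_windows, mode = c("group", "subject")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "decoding_result"))
  if (!is.list(peak_windows)) peak_windows <- list(peak_windows)
  gm <- colMeans(result$accuracy)
  purrr::map_dfr(seq_along(peak_windows), function(w) {
    win <- peak_windows[[w]]
    idx <- which(result$times >= win[1] - 1e-9 & result$times <= win[2] + 1e-9)
    if (!length(idx)) stop("empty peak window [", win[1], ", ", win[2], "]",
                           call. = FALSE)
    if (mode == "group") {
      pk <- idx[which.max(gm[idx])]
      tibble::tibble(window = w, peak_time = result$times[pk],
                     subject = seq_len(nrow(result$accuracy)),
                     accuracy = result$accuracy[, pk])
    } else {
      acc <- apply(result$accuracy[, idx, drop = FALSE], 1, max)
      tibble::tibble(window = w, peak_time = NA_real_,
                     subject = seq_len(nrow(result$accuracy)),
                     accuracy = acc)
    }
  })
}

#' Pairwise comparison of model decoding peaks
#'
#' Paired two-sided Wilcoxon signed-rank tests on subject peak accuracies
#' for every model pair, with Benjamini-Hochberg (default), Bonferroni, or
#' no correction across pairs. The returned matrix holds the mean
#' row-minus-column difference where the corrected p-value falls below
#' `alpha`, and 0 elsewhere.
#'
#' @param peaks_by_model Named list of equal-length per-subject peak vectors
#'   (paired across models).
#' @param correction `"fdr"`, `"bonferroni"`, or `"none"`.
#' @param alpha Significance level (default 0.05).
#' @return A list with `difference` (the thresholded signed matrix) and
#'   `tests` (a tibble of pairwise results).
#' @export
compare_groups <- function(peaks_by_model, correction = c("fdr", "bonferroni",
                                                          "none"),
                           alpha = 0.05) {
  correction <- match.arg(correction)
  models <- names(peaks_by_model)
  if (is.null(models) || length(models) < 2) {
    stop("need a named list of >= 2 models", call. = FALSE)
  }
  n_sub <- unique(vapply(peaks_by_model, length, integer(1)))
  if (length(n_sub) != 1) {
    stop("models must have equal (paired) subject counts", call. = FALSE)
  }
  pairs <- utils::combn(models, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    d <- peaks_by_model[[pr[1]]] - peaks_by_model[[pr[2]]]
    tibble::tibble(model_a = pr[1], model_b = pr[2],
                   mean_diff = mean(d), p_raw = signed_rank_test(d))
  })
  tests$p_adj <- switch(correction,
    fdr = stats::p.adjust(tests$p_raw, "BH"),
    bonferroni = stats::p.adjust(tests$p_raw, "bonferroni"),
    none = tests$p_raw
  )
  diff_mat <- matrix(0, length(models), length(models),
                     dimnames = list(models, models))
  for (i in seq_len(nrow(tests))) {
    if (tests$p_adj[i] < alpha) {
      diff_mat[tests$model_a[i], tests$model_b[i]] <- tests$mean_diff[i]
      diff_mat[tests$model_b[i], tests$model_a[i]] <- -tests$mean_diff[i]
    }
  }
  list(difference = diff_mat, tests = tests)
}
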