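# Shared fixtures, built once per test run and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small atlas: 4 networks x 3 regions, both hemispheres in each network
tiny_atlas <- function(n_regions = 12) synthetic_atlas(n_regions)

# stimulus-locked epochs with white-noise data and given condition patterns
# added to all samples (patterns: list of per-condition region vectors)
patterned_epochs <- function(n_per_cond = 30, n_regions = 4, n_samples = 20,
                             patterns = NULL, noise_sd = 1, fs = 200,
                             seed = 1) {
  conds <- rep(c("left", "right"), each = n_per_cond)
  arr <- array(0, c(length(conds), n_regions, n_samples))
  withr::with_seed(seed, {
    arr[] <- rnorm(length(arr), sd = noise_sd)
  })
  if (!is.null(patterns)) {
    for (tr in seq_along(conds)) {
      pat <- patterns[[if (conds[tr] == "left") 1 else 2]]
      arr[tr, , ] <- arr[tr, , ] + pat
    }
  }
  epoch_set(arr, fs = fs, times = seq(0, by = 1 / fs,
                                      length.out = n_samples),
            lock = "stimulus", condition = conds,
            rt = rep(0.5, length(conds)))
}

# parameter-recovery fixture at the reference scale:
# 20 regions, order 3, 30 pseudo-trials x 4,000 samples, density 0.2,
# stability bound 0.9
fx_recovery <- function() {
  fixture("recovery", function() {
    gtn <- make_random_stable_var(20, 3, density = 0.2,
                                  stability_bound = 0.9, seed = 101)
    rest <- simulate_rest(gtn, 30, 4000, seed = 102)
    fit <- fit_mvar(rest, gtn$atlas, target_network = "Motor", order = 3)
    list(gtn = gtn, rest = rest, fit = fit)
  })
}

# correlation between fitted and ground-truth lagged weights over the
# nonzero ground-truth entries (lagged sources + self-coupling)
recovery_cor <- function(fit, gtn) {
  est <- c()
  tru <- c()
  p <- fit$order
  for (j in seq_along(fit$targets)) {
    tj <- fit$targets[j]
    for (i in seq_len(p)) {
      mask <- gtn$coeffs[i, tj, ] != 0
      mask[tj] <- FALSE
      est <- c(est, fit$F[j, mask, i], fit$C[j, i])
      tru <- c(tru, gtn$coeffs[i, tj, mask], gtn$coeffs[i, tj, tj])
    }
  }
  stats::cor(est, tru)
}

# end-to-end flow-specificity study: per subject, rest-estimated weights,
# full / lesioned predictions, and decoding of predicted and actual target
# activations (response-locked, decimated by 5)
fx_flow_study <- function() {
  fixture("flow_study", function() {
    study <- simulate_study(n_subjects = 16, seed = 2024)
    prep <- function(ep, sd) {
      ep <- response_lock(ep, c(-0.45, 0.45))
      decode_epochs(decimate_epochs(ep, 5), set_size = 14, n_iter = 2,
                    n_folds = 5, seed = sd)
    }
    res <- lapply(seq_along(study$subjects), function(s) {
      sub <- study$subjects[[s]]
      fit <- fit_mvar(sub$rest, study$atlas, "Motor", order = 3)
      pred <- crop_to_valid(predict_target(sub$task, fit))
      act <- subset_epochs(sub$task, regions = fit$targets,
                          time_range = range(pred$times))
      keep_src <- crop_to_valid(lesion_predict(sub$task, fit, "Visual"))
      keep_iso <- crop_to_valid(lesion_predict(sub$task, fit, "DAN"))
      list(
        fit = fit,
        predicted = prep(pred, expand_seed(2024, "dp", s)),
        actual = prep(act, expand_seed(2024, "da", s)),
        keep_injected = prep(keep_src, expand_seed(2024, "dk", s)),
        keep_isolated = prep(keep_iso, expand_seed(2024, "di", s))
      )
    })
    as_result <- function(field) {
      group_stats(decoding_result(lapply(res, `[[`, field)))
    }
    list(
      study = study, fits = lapply(res, `[[`, "fit"),
      predicted = as_result("predicted"), actual = as_result("actual"),
      keep_injected = as_result("keep_injected"),
      keep_isolated = as_result("keep_isolated")
    )
  })
}
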