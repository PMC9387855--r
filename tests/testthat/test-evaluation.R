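test_that("time course overlap identities hold", {
  set.seed(41)
  actual <- matrix(rnorm(5 * 30), 5, 30) + 50
  # perfect prediction
  ov <- timecourse_overlap(actual, actual)
  expect_equal(ov$r_group, 1)
  expect_equal(ov$r2_subjects, rep(1, 5))
  # mean-only prediction: R^2 exactly 0
  mean_pred <- matrix(rowMeans(actual), 5, 30)
  ov0 <- timecourse_overlap(mean_pred, actual)
  expect_equal(ov0$r2_subjects, rep(0, 5), tolerance = 1e-12)
  expect_true(all(is.na(ov0$r_subjects))) # constant predictions: r undefined
  expect_true(is.na(ov0$r_group))
  # sign flip: r = -1, R^2 <= 0
  ovn <- timecourse_overlap(-actual, actual)
  expect_equal(ovn$r_group, -1)
  expect_equal(ovn$r_subjects, rep(-1, 5), tolerance = 1e-12)
  expect_true(all(ovn$r2_subjects <= 0))
  # r_group invariant to a common affine transform of both inputs
  pred <- actual + matrix(rnorm(5 * 30), 5, 30)
  r1 <- timecourse_overlap(pred, actual)$r_group
  r2 <- timecourse_overlap(3 * pred + 7, 3 * actual + 7)$r_group
  expect_equal(r1, r2, tolerance = 1e-12)
  # constant actual is an error naming the subject
  flat <- actual
  flat[3, ] <- 42
  expect_error(timecourse_overlap(pred, flat), "subject 3")
})

test_that("permutation p-values follow the add-one convention", {
  fx_gtn <- make_random_stable_var(8, 1, density = 0.5,
                                   stability_bound = 0.8, seed = 42,
                                   atlas = synthetic_atlas(8,
                                                           c("Motor",
                                                             "Visual")))
  des <- evoked_design(n_trials_per_condition = 28,
                       source_regions = network_regions(fx_gtn$atlas,
                                                        "Visual"),
                       seed = 43)
  task <- simulate_task(fx_gtn, des, "Motor")
  fit <- as_mvar_fit(fx_gtn, "Motor")
  # stateful statistic: observed value below every permuted value -> p = 1
  calls <- new.env()
  calls$n <- 0
  stat_low <- function(pred) {
    calls$n <- calls$n + 1
    if (calls$n == 1) -1 else 0
  }
  pn <- permutation_null(task, fit, statistic = stat_low, n_perm = 7,
                         seed = 44)
  expect_equal(pn$p, 1)
  # observed above every permuted value -> minimal attainable p
  calls$n <- 0
  stat_high <- function(pred) {
    calls$n <- calls$n + 1
    if (calls$n == 1) 1 else 0
  }
  pn2 <- permutation_null(task, fit, statistic = stat_high, n_perm = 7,
                          seed = 44)
  expect_equal(pn2$p, 1 / 8)
  expect_error(permutation_null(task, fit, n_perm = 0), "n_perm")
})

test_that("scrambling preserves self-coupling and the weight distribution", {
  fx_gtn <- make_random_stable_var(10, 2, density = 0.5,
                                   stability_bound = 0.8, seed = 45)
  fit <- as_mvar_fit(fx_gtn, "Motor")
  sc <- dynaflow:::scramble_fit(fit, 46)
  expect_identical(sc$C, fit$C)
  non_target <- which(fx_gtn$atlas$network != "Motor")
  for (j in seq_along(fit$targets)) {
    # same multiset of weights per lag, different arrangement
    for (i in seq_len(fit$order)) {
      expect_equal(sort(sc$F[j, non_target, i]),
                   sort(fit$F[j, non_target, i]))
    }
  }
  expect_false(identical(sc$F, fit$F))
})

test_that("ground-truth flow is detected against the scrambled null", {
  # targets driven specifically by the informative network, so misassigned
  # weights land on uninformative sources
  gtn <- make_random_stable_var(12, 2, density = 0.5, stability_bound = 0.85,
                                seed = 47,
                                receive_only_within = c("DAN", "FPN"))
  vis <- network_regions(gtn$atlas, "Visual")
  tg <- network_regions(gtn$atlas, "Motor")
  for (i in 1:2) {
    A <- gtn$coeffs[i, , ]
    A[tg, setdiff(1:12, vis)] <- 0
    gtn$coeffs[i, , ] <- A
  }
  des <- evoked_design(n_trials_per_condition = 28, source_regions = vis,
                       amplitude = 1, seed = 48)
  task <- simulate_task(gtn, des, "Motor")
  rest <- simulate_rest(gtn, 8, 1500, seed = 49)
  fit <- fit_mvar(rest, gtn$atlas, "Motor", order = 2, n_pcs = 30)
  small <- subset_epochs(task, time_range = c(0.0, 0.9))
  pn <- permutation_null(small, fit, statistic = "activation", n_perm = 19,
                         seed = 50,
                         cfg = flow_config(order = 2,
                                           leakage_regression = FALSE))
  expect_lte(pn$p, 0.05)
  expect_gt(pn$observed, max(pn$permuted))
})

test_that("representational overlap behaves on constructed templates", {
  n_samp <- 4
  u <- c(1, -1, 2, -2, 0, 0)
  v <- c(0, 0, 0, 0, 3, -3) # cor(u, v) = 0 about their means
  # noise-free: test pattern equals the correct template, templates
  # orthogonal -> information = 1 - 0 = 1 everywhere
  ep <- patterned_epochs(n_per_cond = 28, n_regions = 6, n_samples = n_samp,
                         patterns = list(u, v), noise_sd = 0, seed = 51)
  info <- representational_overlap(ep, ep, set_size = 14, n_iter = 1,
                                   n_folds = 3, seed = 52)
  expect_equal(info$information, rep(1 - cor(u, v), n_samp),
               tolerance = 1e-10)
  # identical templates across conditions -> information exactly 0
  ep0 <- patterned_epochs(n_per_cond = 28, n_regions = 6,
                          n_samples = n_samp, patterns = list(u, u),
                          noise_sd = 0, seed = 53)
  info0 <- representational_overlap(ep0, ep0, set_size = 14, n_iter = 1,
                                    n_folds = 3, seed = 54)
  expect_equal(info0$information, rep(0, n_samp), tolerance = 1e-10)
  # zero-variance template errors
  epz <- patterned_epochs(n_per_cond = 28, n_regions = 6,
                          n_samples = n_samp, patterns = list(u * 0, v),
                          noise_sd = 0, seed = 55)
  expect_error(representational_overlap(epz, epz, set_size = 14,
                                        n_iter = 1, n_folds = 3, seed = 56),
               "zero-variance")
})

test_that("train-on-predicted and train-on-actual information time courses agree under true weights", {
  gtn <- make_random_stable_var(12, 2, density = 0.4, stability_bound = 0.85,
                                seed = 57)
  tg <- network_regions(gtn$atlas, "Motor")
  for (i in 1:2) {
    A <- gtn$coeffs[i, , ]
    A[tg, tg] <- diag(diag(A[tg, tg, drop = FALSE]), nrow = length(tg))
    gtn$coeffs[i, , ] <- A
  }
  gtn$noise_sd <- rep(0.05, 12)
  des <- evoked_design(n_trials_per_condition = 28,
                       source_regions = network_regions(gtn$atlas, "Visual"),
                       amplitude = 2, seed = 58)
  task <- simulate_task(gtn, des, "Motor")
  fit <- as_mvar_fit(gtn, "Motor")
  pred <- crop_to_valid(predict_target(task, fit,
                                       flow_config(order = 2,
                                                   leakage_regression = FALSE)))
  act <- subset_epochs(task, regions = tg, time_range = range(pred$times))
  win <- c(0.1, 0.7)
  predw <- subset_epochs(pred, time_range = win)
  actw <- subset_epochs(act, time_range = win)
  args <- list(set_size = 14, n_iter = 1, n_folds = 3, seed = 59)
  tp <- do.call(representational_overlap, c(list(predw, actw), args))
  ta <- do.call(representational_overlap, c(list(actw, actw), args))
  expect_gt(cor(tp$information, ta$information), 0.9)
})

test_that("motor ERP recovers a planted contralateral effect", {
  atlas <- synthetic_atlas(8, c("Motor", "Visual"))
  motor <- network_regions(atlas, "Motor")
  left_h <- motor[atlas$hemisphere[motor] == "left"]
  right_h <- motor[atlas$hemisphere[motor] == "right"]
  fs <- 100
  times <- seq(-0.45, 0.45, by = 1 / fs)
  win <- times >= -0.05 & times <= 0.05
  d <- 2
  make_subject <- function(seed) {
    set.seed(seed)
    n_tr <- 40
    cond <- rep(c("left", "right"), each = n_tr / 2)
    arr <- array(rnorm(n_tr * 8 * length(times), sd = 0.3),
                 c(n_tr, 8, length(times)))
    for (tr in seq_len(n_tr)) {
      contra <- if (cond[tr] == "left") right_h else left_h
      arr[tr, contra, win] <- arr[tr, contra, win] + d
    }
    epoch_set(arr, fs = fs, times = times, lock = "response",
              condition = cond, rt = rep(0.5, n_tr),
              region_ids = atlas$region_id)
  }
  erps <- lapply(1:14, function(s) motor_erp(make_subject(s), atlas, "Motor"))
  rep_ <- erp_report(erps, predicted_erps = erps,
                     spatial_window = c(-0.05, 0.05))
  in_win <- rep_$diff_stats$time >= -0.05 & rep_$diff_stats$time <= 0.05
  expect_equal(mean(rep_$diff_stats$mean_amplitude[in_win]), d,
               tolerance = 0.15)
  expect_lt(max(abs(rep_$diff_stats$mean_amplitude[!in_win])), 0.3)
  expect_true(all(rep_$diff_stats$significant[in_win]))
  # predicted == actual: perfect overlap in all three domains
  expect_equal(rep_$temporal$r_group, 1)
  expect_equal(rep_$spatial$r_group, 1)
  expect_equal(rep_$spatiotemporal$r_group, 1)
  # identical contra/ipsi activation -> difference wave identically zero
  flat <- make_subject(99)
  flat$data[] <- 1 + flat$data * 0
  flat$data <- flat$data + array(rep(rnorm(length(times)),
                                     each = 40 * 8),
                                 c(40, 8, length(times)))
  e0 <- motor_erp(flat, atlas, "Motor")
  expect_lt(max(abs(e0$diff_wave$amplitude)), 1e-12)
  # stimulus-locked input is rejected
  stim <- make_subject(1)
  stim$lock <- "stimulus"
  expect_error(motor_erp(stim, atlas, "Motor"), "response-locked")
})
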