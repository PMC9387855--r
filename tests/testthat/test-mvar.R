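test_that("design matrix geometry and block layout are exact", {
  # full-scale geometry: 264 regions, order 10 -> 2,903 predictors
  pt <- matrix(rnorm(264 * 60), 264, 60)
  d <- build_design_matrix(pt, target_index = 1, order = 10)
  expect_identical(ncol(d$X), 263L + 2630L + 10L)
  expect_identical(nrow(d$X), 50L)
  # tiny case: R = 3, p = 1 -> 2 + 2 + 1 = 5
  pt3 <- matrix(rnorm(3 * 10), 3, 10)
  d3 <- build_design_matrix(pt3, 2, 1)
  expect_identical(ncol(d3$X), 5L)
  expect_identical(nrow(d3$X), 9L)
  # block content: contemporaneous sources, lagged sources, lagged self
  expect_equal(d3$X[, 1], pt3[1, 2:10])
  expect_equal(d3$X[, 3], pt3[1, 1:9])
  expect_equal(d3$X[, 5], pt3[2, 1:9])
  expect_equal(d3$y, pt3[2, 2:10])
  # no contemporaneous self term ever enters the design
  expect_false(any(d3$terms$term == "contemporaneous" & d3$terms$region == 2))
  expect_false(any(d$terms$term == "contemporaneous" & d$terms$region == 1))
  expect_error(build_design_matrix(pt3, 1, 10), "order")
})

test_that("pca regression reproduces least squares at full rank", {
  # closed-form toy: y = X [1, -1]
  set.seed(21)
  X <- matrix(rnorm(8), 4, 2)
  y <- drop(X %*% c(1, -1))
  expect_equal(unclass(pca_regression(X, y, 2))[1:2], c(1, -1),
               tolerance = 1e-8, ignore_attr = TRUE)
  # y orthogonal to all centered columns -> beta ~ 0
  Xc <- scale(matrix(rnorm(40), 10, 4), scale = FALSE)
  yo <- qr.resid(qr(cbind(1, Xc)), rnorm(10))
  expect_lt(max(abs(pca_regression(Xc, yo, 4))), 1e-10)
  expect_error(pca_regression(X, y, 3), "rank")
})

test_that("full-rank pca regression matches the normal-equations oracle on random draws", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(10:30, 1)
    k <- sample(2:6, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    beta <- pca_regression(X, y, k)
    # independent oracle: ordinary least squares with intercept
    oracle <- stats::lm.fit(cbind(1, X), y)$coefficients[-1]
    expect_lt(max(abs(beta - oracle)), 1e-6)
  }
})

test_that("sliding-window CV finds noiseless linear structure and planted low rank", {
  fs <- 100
  set.seed(23)
  # noiseless: region 1 is an exact lagged combination of regions 2..4, and
  # pseudo-trials repeat the identical segment so the relation survives
  # per-pseudo-trial standardization exactly
  n_pt <- 3; n_s <- 300
  seg <- matrix(rnorm(4 * n_s), 4, n_s)
  for (t in 2:n_s) {
    seg[1, t] <- 0.5 * seg[2, t - 1] - 0.3 * seg[3, t - 1] +
      0.2 * seg[4, t - 1]
  }
  data <- array(NA_real_, c(n_pt, 4, n_s))
  for (k in seq_len(n_pt)) data[k, , ] <- seg
  rs <- rest_set(data, fs = fs)
  sel <- cv_select_npcs(rs, targets = 1, order = 1, pc_grid = c(1, 7))
  expect_lt(min(sel$cv_mse[2, , ]), 1e-10)
  expect_identical(dim(sel$cv_mse), c(2L, 1L, 2L))
  # planted structure: the selected count beats the grid minimum of 1
  gtn <- make_random_stable_var(10, 2, density = 0.3, stability_bound = 0.85,
                                seed = 24)
  rest <- simulate_rest(gtn, 4, 800, seed = 25)
  sel2 <- cv_select_npcs(rest, targets = 1:2, order = 2,
                         pc_grid = c(1, 10, 20))
  mse_by_grid <- apply(sel2$cv_mse, 1, mean)
  expect_lt(min(mse_by_grid[-1]), mse_by_grid[1])
  expect_gt(sel2$n_pcs_selected, 1)
  # single pseudo-trial cannot be cross-validated
  one <- rest_set(rest$data[1, , , drop = FALSE], fs = 200)
  expect_error(cv_select_npcs(one, 1, 2), "2 pseudo-trials")
})

test_that("ties in CV error break toward the smaller grid value", {
  set.seed(26)
  data <- array(rnorm(2 * 3 * 200), c(2, 3, 200))
  rs <- rest_set(data, fs = 100)
  # both candidates exceed the 5-predictor rank, so their fits (clipped to
  # the rank) tie exactly; the smaller grid value must win
  sel <- cv_select_npcs(rs, targets = 1, order = 1, pc_grid = c(8, 6))
  expect_identical(max(abs(sel$cv_mse[1, , ] - sel$cv_mse[2, , ])), 0)
  expect_identical(sel$n_pcs_selected, 6L)
  expect_identical(sel$pc_grid, c(6L, 8L)) # grid is sorted ascending
})

test_that("fitted weights are the across-pseudo-trial mean of per-trial fits", {
  gtn <- make_random_stable_var(6, 2, density = 0.5, stability_bound = 0.8,
                                seed = 27,
                                atlas = synthetic_atlas(6, c("Motor", "Visual")))
  rest <- simulate_rest(gtn, 3, 300, seed = 28)
  fit <- fit_mvar(rest, gtn$atlas, "Motor", order = 2, n_pcs = 8)
  z <- zscore_per_trial(rest)
  tj <- fit$targets[1]
  betas <- sapply(1:3, function(k) {
    d <- build_design_matrix(z$data[k, , ], tj, 2)
    pca_regression(d$X, d$y, 8)
  })
  beta_bar <- rowMeans(betas)
  sources <- setdiff(1:6, tj)
  expect_equal(fit$B0[1, sources], beta_bar[1:5], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$F[1, sources, 1], beta_bar[6:10], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$F[1, sources, 2], beta_bar[11:15], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$C[1, ], beta_bar[16:17], tolerance = 1e-12,
               ignore_attr = TRUE)
  # own-region lagged weight lives only in C, never in F
  expect_true(all(fit$F[1, tj, ] == 0))
})

test_that("null rest data yields near-zero lagged weights", {
  gtn0 <- make_random_stable_var(8, 2, density = 0.5, stability_bound = 0.5,
                                 seed = 29)
  gtn0$coeffs[] <- 0
  rest <- simulate_rest(gtn0, 6, 1000, seed = 30)
  fit <- fit_mvar(rest, gtn0$atlas, "Motor", order = 2, n_pcs = 22)
  # estimation noise floor ~ 1/sqrt(rows per fit x pseudo-trials)
  noise_floor <- 1 / sqrt((1000 - 2) * 6)
  expect_lt(mean(abs(fit$F[, , ])), 3 * noise_floor)
})

test_that("tidy and glance summarize an MVAR fit", {
  fx <- fx_recovery()
  td <- tidy(fx$fit)
  expect_true(all(c("target", "source", "lag", "term", "weight") %in%
                    names(td)))
  expect_false(any(td$term == "contemporaneous" & td$target == td$source))
  gl <- glance(fx$fit)
  expect_identical(gl$order, 3)
  expect_true(gl$n_pcs_selected %in% fx$fit$pc_grid)
})
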