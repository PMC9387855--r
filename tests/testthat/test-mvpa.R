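test_that("subtrial averaging arithmetic and identities hold", {
  # 120 trials per condition at set size 14 -> 8 subtrials
  ep <- patterned_epochs(n_per_cond = 120, n_regions = 3, n_samples = 5)
  st <- make_subtrials(ep, set_size = 14, n_iter = 2, seed = 1)
  expect_identical(st$n_subtrials, 8L)
  # 28 trials -> 2 subtrials
  ep2 <- patterned_epochs(n_per_cond = 28, n_regions = 3, n_samples = 5)
  st2 <- make_subtrials(ep2, set_size = 14, n_iter = 1, seed = 1)
  expect_identical(st2$n_subtrials, 2L)
  # mean over subtrials equals mean over the included trials (exact)
  it <- st2$iterations[[1]][["left"]]
  used <- unlist(it$indices)
  expect_equal(apply(it$data, c(2, 3), mean),
               apply(ep2$data[used, , , drop = FALSE], c(2, 3), mean),
               tolerance = 1e-12)
  # index sets are disjoint within an iteration and sized exactly set_size
  expect_identical(anyDuplicated(used), 0L)
  expect_true(all(lengths(it$indices) == 14L))
  # incorrect trials are removed before averaging
  ep3 <- patterned_epochs(n_per_cond = 45, n_regions = 2, n_samples = 4)
  ep3$correct[1:10] <- FALSE
  st3 <- make_subtrials(ep3, set_size = 14, n_iter = 1, seed = 2)
  expect_false(any(unlist(st3$iterations[[1]][["left"]]$indices) %in% 1:10))
  expect_identical(st3$n_subtrials, 2L) # truncated to the smaller condition
  # fewer than 2 subtrials per condition errors
  ep4 <- patterned_epochs(n_per_cond = 20, n_regions = 2, n_samples = 4)
  expect_error(make_subtrials(ep4, set_size = 14), "2 subtrials")
  # deterministic given the seed
  stA <- make_subtrials(ep, set_size = 14, n_iter = 2, seed = 9)
  stB <- make_subtrials(ep, set_size = 14, n_iter = 2, seed = 9)
  expect_identical(stA$iterations[[2]][["right"]]$indices,
                   stB$iterations[[2]][["right"]]$indices)
})

test_that("fold counts follow the round-up/round-down rule", {
  # 8 subtrials at train fraction 0.2: 2 training, 6 testing per condition
  expect_identical(ceiling(0.2 * 8), 2)
  folds <- withr::with_seed(3, sample_folds(8, 2, 6, 10))
  expect_length(folds, 10)
  for (f in folds) {
    expect_true(all(lengths(f$train) == 2))
    expect_true(all(lengths(f$test) == 6))
    expect_length(intersect(f$train[[1]], f$test[[1]]), 0)
    expect_length(intersect(f$train[[2]], f$test[[2]]), 0)
  }
  keys <- vapply(folds, function(f) paste(unlist(f), collapse = ","), "")
  expect_identical(anyDuplicated(keys), 0L)
  # unsatisfiable uniqueness constraint errors after bounded retries
  expect_error(withr::with_seed(4, sample_folds(2, 1, 1, 10)),
               "distinct")
})

test_that("decoding is perfect on separable patterns and at chance on null ones", {
  u <- c(2, -2, 1, -1)
  sep <- patterned_epochs(n_per_cond = 28, n_regions = 4, n_samples = 6,
                          patterns = list(u, -u), noise_sd = 0.05, seed = 6)
  dec <- decode_epochs(sep, set_size = 14, n_iter = 2, n_folds = 5, seed = 7)
  expect_true(all(dec$accuracy == 100))
  # identically distributed conditions: accuracy inside the binomial 95%
  # interval around 50%
  nul <- patterned_epochs(n_per_cond = 56, n_regions = 4, n_samples = 30,
                          seed = 8)
  decn <- decode_epochs(nul, set_size = 14, n_iter = 3, n_folds = 10,
                        seed = 9)
  m <- mean(decn$accuracy)
  # per time point a fold tests 2x3 subtrials; decisions pool over
  # 30 time points x 10 folds x 3 iterations, heavily correlated, so the
  # binomial interval is computed on the per-fold decision count scale
  n_eff <- 10 * 3 * 6
  half_width <- 1.96 * sqrt(0.25 / n_eff) * 100
  expect_lt(abs(m - 50), half_width)
})

test_that("decoding is invariant to per-region affine rescaling absorbed by z-scoring", {
  u <- c(1.5, -1.5, 0, 0)
  ep <- patterned_epochs(n_per_cond = 28, n_regions = 4, n_samples = 5,
                         patterns = list(u, -u), noise_sd = 1, seed = 10)
  scaled <- ep
  for (rg in 1:4) scaled$data[, rg, ] <- 3.7 * scaled$data[, rg, ] + rg
  a <- decode_epochs(zscore_per_trial(ep), set_size = 14, n_iter = 2,
                     n_folds = 5, seed = 11)
  b <- decode_epochs(zscore_per_trial(scaled), set_size = 14, n_iter = 2,
                     n_folds = 5, seed = 11)
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-10)
})

test_that("label permutation stays at chance on informative data", {
  u <- c(2, -2, 1, -1)
  ep <- patterned_epochs(n_per_cond = 56, n_regions = 4, n_samples = 8,
                         patterns = list(u, -u), noise_sd = 0.5, seed = 12)
  shuffled <- ep
  set.seed(13)
  shuffled$condition <- sample(ep$condition)
  dec <- decode_epochs(shuffled, set_size = 14, n_iter = 3, n_folds = 10,
                       seed = 14)
  n_eff <- 10 * 3 * 6
  expect_lt(abs(mean(dec$accuracy) - 50), 1.96 * sqrt(0.25 / n_eff) * 100)
})

test_that("signed-rank group statistics follow the declared policy", {
  # exact branch: n = 20 subjects all strictly above chance
  p_exact <- dynaflow:::signed_rank_test(rep(55, 20) + runif(20), mu = 50)
  expect_equal(p_exact, 2 * 2^(-20), tolerance = 1e-12)
  # all subjects exactly at chance: zero differences are discarded, p = 1
  expect_identical(dynaflow:::signed_rank_test(rep(50, 10), mu = 50), 1)
  # normal-approximation branch at n = 32, checked against the closed form
  x <- 50 + seq_len(32)
  p32 <- dynaflow:::signed_rank_test(x, mu = 50)
  w <- 32 * 33 / 2
  z <- (w - 32 * 33 / 4 - 0.5) / sqrt(32 * 33 * 65 / 24)
  expect_equal(p32, 2 * pnorm(-z), tolerance = 1e-12)

  # Bonferroni arithmetic over 181 samples
  acc <- matrix(50, nrow = 8, ncol = 181)
  acc[, 1] <- c(60, 61, 59, 62, 58, 60, 61, 59)
  res <- group_stats(decoding_result(acc, times = seq(-0.45, 0.45,
                                                      length.out = 181)))
  expect_equal(res$stats$p_bonferroni[1],
               min(1, res$stats$p_raw[1] * 181))
  expect_false(any(res$stats$significant[-1]))
  expect_error(group_stats(decoding_result(acc[1:4, ],
                                           times = res$stats$time)),
               "6 subjects")
})

test_that("peak extraction uses the group time-to-peak with earliest-maximum ties", {
  times <- seq(0, 0.2, by = 0.025)
  acc <- rbind(c(50, 60, 70, 70, 65, 50, 50, 55, 52),
               c(50, 62, 72, 68, 64, 50, 50, 57, 54))
  res <- decoding_result(acc, times = times)
  pk <- extract_peaks(res, list(c(0, 0.1), c(0.15, 0.2)))
  # group mean peaks at index 3 (earliest maximum of a tie at subject level)
  expect_equal(unique(pk$peak_time[pk$window == 1]), 0.05)
  expect_equal(pk$accuracy[pk$window == 1], c(70, 72))
  # single-sample window returns that sample
  pk2 <- extract_peaks(res, list(c(0.025, 0.025)))
  expect_equal(pk2$accuracy, acc[, 2])
  # constant time course: earliest maximum = window start
  resc <- decoding_result(matrix(55, 2, 9), times = times)
  pkc <- extract_peaks(resc, list(c(0.05, 0.15)))
  expect_equal(unique(pkc$peak_time), 0.05)
  # per-subject mode takes each subject's own maximum
  pks <- extract_peaks(res, list(c(0, 0.2)), mode = "subject")
  expect_equal(pks$accuracy, c(70, 72))
  expect_error(extract_peaks(res, list(c(0.5, 0.6))), "empty")
})

test_that("pairwise model comparison applies the step-up FDR correction", {
  # Benjamini-Hochberg arithmetic: raw {0.01, 0.02, 0.20} -> {0.03, 0.03, 0.20}
  expect_equal(p.adjust(c(0.01, 0.02, 0.20), "BH"), c(0.03, 0.03, 0.20))
  set.seed(15)
  base <- 50 + rnorm(10)
  models <- list(A = base, B = base + 5, C = base)
  cmp <- compare_groups(models, correction = "fdr")
  # deterministic +5 shift: significant with the exact sign convention
  expect_equal(cmp$difference["B", "A"], 5)
  expect_equal(cmp$difference["A", "B"], -5)
  # a model against itself: difference 0, p = 1
  self_row <- cmp$tests[cmp$tests$model_a == "A" & cmp$tests$model_b == "C", ]
  expect_identical(self_row$p_raw, 1)
  expect_identical(cmp$difference["A", "C"], 0)
  expect_error(compare_groups(list(A = 1:3, B = 1:4)), "equal")
  expect_error(compare_groups(list(1:3, 1:3)), "named")
})
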