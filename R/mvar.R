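#' Build the MVAR design matrix for one target region
#'
#' For a single z-scored pseudo-trial, lays out predictors for the target's
#' series at time t0 in fixed column-block order: contemporaneous sources,
#' then lagged sources (lag-major: all sources at lag 1, then lag 2, ...),
#' then the target's own lagged self-coupling terms. The contemporaneous
#' self term is structurally excluded to prevent circularity. At full scale
#' (264 regions, order 10) this gives 263 + 2,630 + 10 = 2,903 predictors.
#'
#' @param ptrial Numeric matrix `[regions x samples]`, already z-scored.
#' @param target_index Row index of the target region.
#' @param order Lag count p.
#' @return A list with `X` (`[(samples - p) x n_pred]`), `y` (the target
#'   series at rows p..samples-1, 0-based), and `terms`, a tibble describing
#'   each column (`term`, `region`, `lag`).
#' @export
build_design_matrix <- function(ptrial, target_index, order) {
  stopifnot(is.matrix(ptrial))
  r <- nrow(ptrial)
  s <- ncol(ptrial)
  p <- order
  if (s <= p) {
    stop("pseudo-trial has ", s, " samples but order is ", p, call. = FALSE)
  }
  sources <- setdiff(seq_len(r), target_index)
  rows <- (p + 1):s
  y <- ptrial[target_index, rows]
  n_pred <- (r - 1) + (r - 1) * p + p
  X <- matrix(NA_real_, length(rows), n_pred)
  # contemporaneous sources
  X[, seq_along(sources)] <- t(ptrial[sources, rows, drop = FALSE])
  # lagged sources, lag-major
  col <- length(sources)
  for (i in seq_len(p)) {
    X[, col + seq_along(sources)] <- t(ptrial[sources, rows - i, drop = FALSE])
    col <- col + length(sources)
  }
  # lagged self-coupling
  for (i in seq_len(p)) {
    X[, col + i] <- ptrial[target_index, rows - i]
  }
  terms <- tibble::tibble(
    term = c(rep("contemporaneous", length(sources)),
             rep("lagged_source", length(sources) * p),
             rep("self_coupling", p)),
    region = c(sources, rep(sources, times = p), rep(target_index, p)),
    lag = c(rep(0L, length(sources)), rep(seq_len(p), each = length(sources)),
            seq_len(p))
  )
  list(X = X, y = y, terms = terms)
}

#' Principal-component regression
#'
#' Regularized least squares: predictor columns are centered, the response is
#' regressed onto the scores of the top `n_pcs` right-singular directions,
#' and the coefficients are mapped back to the original predictor space.
#' Component signs are fixed (largest-magnitude loading positive) so the fit
#' is deterministic. At `n_pcs = rank(X)` this reproduces the minimum-norm
#' least-squares solution.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param n_pcs Number of principal components to retain, `1..rank(X)`.
#' @return Coefficient vector `beta` of length `ncol(X)`, with attributes
#'   `center` (training column means) and `intercept` (training response
#'   mean) for out-of-sample prediction.
#' @export
pca_regression <- function(X, y, n_pcs) {
  ctr <- colMeans(X)
  Xc <- X - rep(ctr, each = nrow(X))
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (n_pcs < 1 || n_pcs > rank) {
    stop("n_pcs (", n_pcs, ") outside 1..rank(X) = ", rank, call. = FALSE)
  }
  k <- seq_len(n_pcs)
  # deterministic sign: largest-magnitude loading positive
  flip <- vapply(k, function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  V <- sv$v[, k, drop = FALSE]
  U <- sv$u[, k, drop = FALSE]
  V[, flip] <- -V[, flip]
  U[, flip] <- -U[, flip]
  # regress y on scores (= U d): coefficients are U'y / d
  b_pc <- drop(crossprod(U, y)) / sv$d[k]
  beta <- drop(V %*% b_pc)
  attr(beta, "center") <- ctr
  attr(beta, "intercept") <- mean(y) - sum(ctr * beta)
  beta
}

# SVD once, then betas for several n_pcs values cheaply
pca_regression_path <- function(X, y, n_pcs_grid) {
  ctr <- colMeans(X)
  Xc <- X - rep(ctr, each = nrow(X))
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  uy <- drop(crossprod(sv$u, y))
  lapply(n_pcs_grid, function(g) {
    g <- min(g, rank)
    k <- seq_len(g)
    beta <- drop(sv$v[, k, drop = FALSE] %*% (uy[k] / sv$d[k]))
    attr(beta, "center") <- ctr
    attr(beta, "intercept") <- mean(y) - sum(ctr * beta)
    attr(beta, "rank") <- rank
    beta
  })
}

predict_beta <- function(beta, X_new) {
  drop(X_new %*% beta) + attr(beta, "intercept")
}

#' Default principal-component grid
#'
#' At full scale the candidate grid steps in increments of 540 predictors
#' (with 1 included), intersected with the feasible rank; at reduced
#' synthetic scales the grid is the set of fractions
#' `{0.05, 0.2, 0.4, 0.6, 0.8, 1}` of the maximal rank.
#'
#' @param n_pred Number of predictor columns.
#' @param n_rows Number of design rows per pseudo-trial.
#' @return Sorted integer vector of candidate component counts.
#' @export
default_pc_grid <- function(n_pred, n_rows) {
  max_rank <- min(n_pred, n_rows - 1)
  grid <- if (n_pred >= 540) {
    c(1, seq(540, n_pred, by = 540))
  } else {
    round(c(0.05, 0.2, 0.4, 0.6, 0.8, 1) * max_rank)
  }
  sort(unique(pmax(1L, pmin(as.integer(grid), max_rank))))
}

#' Cross-validated selection of the principal-component count
#'
#' Sliding-window cross-validation preserving the serial order of the rest
#' pseudo-trials: for every candidate component count, the model is fit on
#' pseudo-trial k and used to predict the target series of pseudo-trial
#' k + 1 from that trial's own design matrix (train on 1, test on 2; train
#' on 2, test on 3; ...). The selected count minimizes the mean squared
#' error averaged over target regions and test pseudo-trials, ties broken
#' toward the smaller grid value.
#'
#' @param rest A [rest_set] (z-scored internally).
#' @param targets Integer target-region indices.
#' @param order Lag count p.
#' @param pc_grid Integer grid of candidate counts, or `NULL` for
#'   [default_pc_grid].
#' @return A list with `n_pcs_selected`, `pc_grid`, and `cv_mse`, an array
#'   `[grid x targets x test pseudo-trials]`.
#' @export
cv_select_npcs <- function(rest, targets, order, pc_grid = NULL) {
  stopifnot(inherits(rest, "rest_set"))
  n_pt <- dim(rest$data)[1]
  if (n_pt < 2) {
    stop("cross-validation needs at least 2 pseudo-trials", call. = FALSE)
  }
  z <- zscore_per_trial(rest)
  r <- dim(z$data)[2]
  s <- dim(z$data)[3]
  n_pred <- (r - 1) + (r - 1) * order + order
  if (is.null(pc_grid)) pc_grid <- default_pc_grid(n_pred, s - order)
  pc_grid <- sort(unique(as.integer(pc_grid)))
  cv_mse <- array(NA_real_, c(length(pc_grid), length(targets), n_pt - 1),
                  dimnames = list(pc_grid, NULL, NULL))
  for (k in seq_len(n_pt - 1)) {
    train <- z$data[k, , ]
    test <- z$data[k + 1, , ]
    for (j in seq_along(targets)) {
      dtr <- build_design_matrix(train, targets[j], order)
      dte <- build_design_matrix(test, targets[j], order)
      betas <- pca_regression_path(dtr$X, dtr$y, pc_grid)
      for (g in seq_along(pc_grid)) {
        yhat <- predict_beta(betas[[g]], dte$X)
        cv_mse[g, j, k] <- mean((dte$y - yhat)^2)
      }
    }
  }
  mean_mse <- apply(cv_mse, 1, mean)
  list(n_pcs_selected = pc_grid[which.min(mean_mse)], pc_grid = pc_grid,
       cv_mse = cv_mse)
}

new_mvar_fit <- function(F, C, B0, order, n_pcs_selected, pc_grid, cv_mse,
                         atlas, target_network, targets) {
  structure(
    list(F = F, C = C, B0 = B0, order = order,
         n_pcs_selected = n_pcs_selected, pc_grid = pc_grid, cv_mse = cv_mse,
         atlas = atlas, target_network = target_network, targets = targets,
         region_ids = atlas$region_id),
    class = "mvar_fit"
  )
}

#' Estimate lagged resting-state connectivity by regularized MVAR
#'
#' For every target region and every rest pseudo-trial, fits a
#' principal-component-regularized multivariate autoregression of the
#' target's series at t0 on contemporaneous sources, lagged sources, and the
#' target's own lagged self-coupling terms; final weights are the arithmetic
#' mean of the per-pseudo-trial fits. The source set comprises all regions
#' other than the target itself — including the other target-network
#' regions — while each target's own series enters only through its lagged
#' self-coupling terms. Contemporaneous weights are estimated (they sharpen
#' the lagged estimates) but never used for prediction.
#'
#' @param rest A [rest_set]; z-scored per pseudo-trial internally.
#' @param atlas A [region_atlas] matching the rest data's region order.
#' @param target_network Name of the to-be-predicted network.
#' @param order Lag count p (default 10, i.e. 50 ms at 200 Hz).
#' @param pc_grid Candidate component counts (`NULL` for [default_pc_grid]).
#' @param n_pcs Skip cross-validation and fit at this fixed component count.
#' @return An object of class `mvar_fit` with lagged source weights `F`
#'   (`[targets x regions x lags]`, own column zero), self-coupling `C`
#'   (`[targets x lags]`), contemporaneous `B0` (`[targets x regions]`), the
#'   selected component count and the cross-validation error record.
#' @export
fit_mvar <- function(rest, atlas, target_network = "Motor", order = 10,
                     pc_grid = NULL, n_pcs = NULL) {
  stopifnot(inherits(rest, "rest_set"), inherits(atlas, "region_atlas"))
  if (!identical(rest$region_ids, atlas$region_id)) {
    stop("rest region_ids do not match the atlas", call. = FALSE)
  }
  targets <- network_regions(atlas, target_network)
  z <- zscore_per_trial(rest)
  n_pt <- dim(z$data)[1]
  r <- dim(z$data)[2]
  p <- order
  sel <- NULL
  if (is.null(n_pcs)) {
    sel <- cv_select_npcs(rest, targets, order, pc_grid)
    n_pcs <- sel$n_pcs_selected
  }
  Fw <- array(0, c(length(targets), r, p))
  Cw <- matrix(0, length(targets), p)
  B0 <- matrix(0, length(targets), r)
  for (j in seq_along(targets)) {
    sources <- setdiff(seq_len(r), targets[j])
    beta_sum <- numeric((r - 1) + (r - 1) * p + p)
    for (k in seq_len(n_pt)) {
      d <- build_design_matrix(z$data[k, , ], targets[j], p)
      beta <- pca_regression_path(d$X, d$y, n_pcs)[[1]]
      beta_sum <- beta_sum + beta
    }
    beta_bar <- beta_sum / n_pt
    B0[j, sources] <- beta_bar[seq_along(sources)]
    col <- length(sources)
    for (i in seq_len(p)) {
      Fw[j, sources, i] <- beta_bar[col + seq_along(sources)]
      col <- col + length(sources)
    }
    Cw[j, ] <- beta_bar[col + seq_len(p)]
  }
  dimnames(Fw) <- list(atlas$region_id[targets], atlas$region_id, NULL)
  new_mvar_fit(
    F = Fw, C = Cw, B0 = B0, order = p, n_pcs_selected = n_pcs,
    pc_grid = if (is.null(sel)) integer(0) else sel$pc_grid,
    cv_mse = if (is.null(sel)) NULL else sel$cv_mse,
    atlas = atlas, target_network = target_network, targets = targets
  )
}

#' @export
print.mvar_fit <- function(x, ...) {
  cat(sprintf(
    "<mvar_fit> %d targets (%s) x %d regions, order %d, nPCs = %s\n",
    dim(x$F)[1], x$target_network, dim(x$F)[2], x$order,
    format(x$n_pcs_selected)))
  invisible(x)
}

#' Tidy the lagged connectivity weights of an MVAR fit
#'
#' @param x An `mvar_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (target, source, lag) weight; the
#'   self-coupling terms appear with `term = "self_coupling"` and
#'   contemporaneous weights with `lag = 0`.
#' @export
tidy.mvar_fit <- function(x, ...) {
  tg <- x$atlas$region_id[x$targets]
  rg <- x$region_ids
  p <- x$order
  lagged <- tibble::tibble(
    target = rep(tg, times = length(rg) * p),
    source = rep(rep(rg, each = length(tg)), times = p),
    lag = rep(seq_len(p), each = length(tg) * length(rg)),
    term = "lagged_source",
    weight = as.vector(x$F)
  )
  lagged <- lagged[lagged$target != lagged$source, ]
  self <- tibble::tibble(
    target = rep(tg, times = p), source = rep(tg, times = p),
    lag = rep(seq_len(p), each = length(tg)),
    term = "self_coupling", weight = as.vector(x$C)
  )
  contemp <- tibble::tibble(
    target = rep(tg, times = length(rg)),
    source = rep(rg, each = length(tg)),
    lag = 0L, term = "contemporaneous", weight = as.vector(x$B0)
  )
  contemp <- contemp[contemp$target != contemp$source, ]
  dplyr::arrange(dplyr::bind_rows(lagged, self, contemp),
                 .data$target, .data$term, .data$lag, .data$source)
}

#' One-row summary of an MVAR fit
#'
#' @param x An `mvar_fit`.
#' @param ... Unused.
#' @return A tibble with the fit geometry, selected component count and mean
#'   cross-validation error.
#' @export
glance.mvar_fit <- function(x, ...) {
  tibble::tibble(
    n_targets = dim(x$F)[1], n_regions = dim(x$F)[2], order = x$order,
    n_pcs_selected = x$n_pcs_selected,
    cv_mse_mean = if (is.null(x$cv_mse)) NA_real_ else mean(x$cv_mse),
    target_network = x$target_network
  )
}
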