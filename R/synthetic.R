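#' Build a synthetic region atlas
#'
#' Assigns `n_regions` regions to functional networks in contiguous blocks,
#' alternating left/right hemisphere within each network (so the target
#' network always has regions in both hemispheres, as the lateralized motor
#' ERP analysis requires).
#'
#' @param n_regions Number of regions.
#' @param networks Character vector of network names to cycle over in blocks.
#' @return A [region_atlas].
#' @export
synthetic_atlas <- function(n_regions,
                            networks = c("Motor", "Visual", "DAN", "FPN")) {
  net <- networks[ceiling(seq_len(n_regions) / (n_regions / length(networks)))]
  net[is.na(net)] <- networks[length(networks)]
  hemi <- rep(c("left", "right"), length.out = n_regions)
  region_atlas(
    region_id = sprintf("%s_%02d", net, seq_len(n_regions)),
    network = net, hemisphere = hemi
  )
}

#' Generate a random stable VAR ground-truth network
#'
#' Draws sparse random lagged propagation weights `A_1..A_p` and rescales
#' them so the spectral radius of the VAR companion matrix equals
#' `stability_bound` exactly (within 1e-6). Rescaling uses the exact identity
#' that replacing `A_i` with `s^i A_i` multiplies every companion eigenvalue
#' by `s`.
#'
#' @param n_regions Number of regions.
#' @param order VAR order (number of lags).
#' @param density Fraction of nonzero coefficients, in (0, 1].
#' @param stability_bound Target companion spectral radius, in (0, 1).
#' @param noise_sd Innovation standard deviation (scalar or per region).
#' @param atlas Optional [region_atlas]; defaults to [synthetic_atlas].
#' @param fs Sampling rate in Hz attached to simulated data.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param receive_only_within Character vector of networks whose regions
#'   receive connections only from within their own network (they still send
#'   connections everywhere). Such a network supports real resting-state
#'   flow into the target yet can never carry evoked task information from
#'   other networks — the information-isolated control that network
#'   lesioning should find uninvolved.
#' @return An object of class `ground_truth_network` with fields `coeffs`
#'   (`[order x regions x regions]`), `noise_sd`, `atlas`, `fs`, `seed`,
#'   `stability_bound`.
#' @export
make_random_stable_var <- function(n_regions, order, density,
                                   stability_bound = 0.9, noise_sd = 1,
                                   atlas = NULL, fs = 200, seed = 1,
                                   receive_only_within = character(0)) {
  stopifnot(density > 0, density <= 1,
            stability_bound > 0, stability_bound < 1)
  if (is.null(atlas)) atlas <- synthetic_atlas(n_regions)
  stopifnot(nrow(atlas) == n_regions)
  withr_seed(seed, {
    coeffs <- array(0, c(order, n_regions, n_regions))
    for (i in seq_len(order)) {
      mask <- matrix(stats::rbinom(n_regions^2, 1, density), n_regions)
      vals <- matrix(stats::rnorm(n_regions^2), n_regions)
      coeffs[i, , ] <- mask * vals
    }
    for (nw in receive_only_within) {
      rows <- which(atlas$network == nw)
      coeffs[, rows, -rows] <- 0 # no incoming edges from other networks
    }
  })
  rho0 <- companion_spectral_radius(coeffs)
  if (rho0 == 0) {
    stop("all-zero coefficient draw; cannot rescale to the stability bound",
         call. = FALSE)
  }
  s <- stability_bound / rho0
  for (i in seq_len(order)) coeffs[i, , ] <- s^i * coeffs[i, , ]
  structure(
    list(coeffs = coeffs, noise_sd = rep(noise_sd, length.out = n_regions),
         atlas = atlas, fs = fs, seed = seed,
         stability_bound = stability_bound),
    class = "ground_truth_network"
  )
}

#' Spectral radius of a VAR companion matrix
#'
#' @param coeffs Array `[order x regions x regions]` of lagged weights.
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
companion_spectral_radius <- function(coeffs) {
  p <- dim(coeffs)[1]
  r <- dim(coeffs)[2]
  comp <- matrix(0, r * p, r * p)
  for (i in seq_len(p)) {
    comp[1:r, ((i - 1) * r + 1):(i * r)] <- coeffs[i, , ]
  }
  if (p > 1) {
    comp[(r + 1):(r * p), 1:(r * (p - 1))] <- diag(r * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# run expr with a temporary RNG state set from seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# simulate one VAR realization [regions x n_samples] after burn-in;
# injection (optional) is [regions x n_samples], added to the innovations
simulate_var_segment <- function(gtn, n_samples, burn_in, injection = NULL) {
  p <- dim(gtn$coeffs)[1]
  r <- dim(gtn$coeffs)[2]
  total <- burn_in + n_samples
  eps <- matrix(stats::rnorm(r * total, sd = gtn$noise_sd), r, total)
  if (!is.null(injection)) {
    eps[, (burn_in + 1):total] <- eps[, (burn_in + 1):total] + injection
  }
  x <- matrix(0, r, total)
  A <- lapply(seq_len(p), function(i) gtn$coeffs[i, , ])
  for (t in seq_len(total)) {
    acc <- eps[, t]
    for (i in seq_len(min(p, t - 1))) {
      acc <- acc + A[[i]] %*% x[, t - i]
    }
    x[, t] <- acc
  }
  x[, (burn_in + 1):total, drop = FALSE]
}

#' Simulate resting-state pseudo-trials from a ground-truth network
#'
#' Each pseudo-trial is an independent realization of the stable VAR process
#' (Gaussian i.i.d. innovations), with a burn-in of at least 10x the model
#' order discarded so segments start near stationarity.
#'
#' @param gtn A [make_random_stable_var] ground-truth network.
#' @param n_pseudo_trials Number of pseudo-trials.
#' @param n_samples Samples per pseudo-trial (paper-scale geometry: 30
#'   pseudo-trials of 4,000 samples, i.e. 20 s at 200 Hz).
#' @param seed Integer seed (default derived from the network's seed).
#' @return A [rest_set].
#' @export
simulate_rest <- function(gtn, n_pseudo_trials, n_samples, seed = NULL) {
  stopifnot(inherits(gtn, "ground_truth_network"))
  rho <- companion_spectral_radius(gtn$coeffs)
  if (rho >= 1) {
    stop("refusing to simulate from an unstable network (spectral radius ",
         signif(rho, 4), ")", call. = FALSE)
  }
  if (is.null(seed)) seed <- expand_seed(gtn$seed, "rest")
  p <- dim(gtn$coeffs)[1]
  r <- dim(gtn$coeffs)[2]
  burn_in <- max(10 * p, 50)
  data <- array(NA_real_, c(n_pseudo_trials, r, n_samples))
  withr_seed(seed, {
    for (k in seq_len(n_pseudo_trials)) {
      data[k, , ] <- simulate_var_segment(gtn, n_samples, burn_in)
    }
  })
  rest_set(data, fs = gtn$fs, region_ids = gtn$atlas$region_id)
}

#' Describe condition-specific evoked inputs for task simulation
#'
#' Defines per-condition evoked input injected additively into the VAR
#' innovations of designated source regions, so condition information can
#' reach the target network only by propagating over the lagged ground-truth
#' weights. The default template is a half-cosine bump with
#' condition-specific sign patterns across the source regions, centered just
#' before each trial's response commission.
#'
#' @param n_trials_per_condition Trials per condition.
#' @param source_regions Integer region indices receiving injections; must
#'   lie outside the target network.
#' @param conditions Two condition labels (response hands).
#' @param amplitude Bump amplitude in innovation units.
#' @param duration Bump duration in seconds.
#' @param centre_offset Bump-centre offset (s) relative to response
#'   commission (negative = before the response).
#' @param templates Optional list (one per condition) of
#'   `[length(source_regions) x samples]` matrices laid out on the
#'   stimulus-locked epoch time axis; overrides the half-cosine default.
#' @param rt_mean,rt_sd,rt_min Truncated-normal reaction-time parameters (s).
#' @param accuracy Probability a trial is answered correctly.
#' @param leakage_mix Optional `[regions x regions]` diagonal-dominant
#'   instantaneous mixing matrix emulating field spread.
#' @param seed Integer seed.
#' @return An object of class `evoked_design`.
#' @export
evoked_design <- function(n_trials_per_condition, source_regions,
                          conditions = c("left", "right"),
                          amplitude = 1.5, duration = 0.3,
                          centre_offset = -0.1, templates = NULL,
                          rt_mean = 0.5, rt_sd = 0.1, rt_min = 0.2,
                          accuracy = 1, leakage_mix = NULL, seed = 1) {
  stopifnot(length(conditions) == 2, n_trials_per_condition >= 1,
            rt_min > 0, rt_sd >= 0, accuracy > 0, accuracy <= 1)
  if (!is.null(leakage_mix)) {
    dd <- abs(diag(leakage_mix))
    off <- rowSums(abs(leakage_mix)) - dd
    if (any(dd <= off)) {
      stop("leakage_mix must be diagonally dominant", call. = FALSE)
    }
  }
  structure(
    list(n_trials_per_condition = n_trials_per_condition,
         source_regions = as.integer(source_regions),
         conditions = as.character(conditions), amplitude = amplitude,
         duration = duration, centre_offset = centre_offset,
         templates = templates, rt_mean = rt_mean, rt_sd = rt_sd,
         rt_min = rt_min, accuracy = accuracy, leakage_mix = leakage_mix,
         seed = seed),
    class = "evoked_design"
  )
}

rt_truncnorm <- function(n, mean, sd, min) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= min) break
    }
    out[i] <- v
  }
  out
}

# half-cosine bump on a time axis, support [centre - dur/2, centre + dur/2]
half_cosine_bump <- function(times, centre, duration) {
  u <- (times - centre) / duration
  ifelse(abs(u) <= 0.5, cos(pi * u), 0)
}

#' Simulate a stimulus-locked task session from a ground-truth network
#'
#' Generates epoched task trials in which condition-specific evoked inputs
#' are injected into the innovations of non-target source regions and reach
#' the target network exclusively through the lagged ground-truth weights
#' (plus optional instantaneous leakage mixing applied after generation).
#' Conditions are balanced and interleaved; per-trial reaction times are
#' drawn from a truncated normal for later response-locking.
#'
#' @param gtn A ground-truth network.
#' @param design An [evoked_design].
#' @param target_network Name of the to-be-predicted network; injections into
#'   its regions are a validation error.
#' @param epoch_window `(start_s, end_s)` of the stimulus-locked epoch.
#' @return A stimulus-locked [epoch_set].
#' @export
simulate_task <- function(gtn, design, target_network = "Motor",
                          epoch_window = c(-0.5, 1.5)) {
  stopifnot(inherits(gtn, "ground_truth_network"),
            inherits(design, "evoked_design"))
  rho <- companion_spectral_radius(gtn$coeffs)
  if (rho >= 1) stop("refusing to simulate from an unstable network",
                     call. = FALSE)
  tgt <- which(gtn$atlas$network == target_network)
  if (any(design$source_regions %in% tgt)) {
    stop("evoked templates must not touch target-network regions",
         call. = FALSE)
  }
  fs <- gtn$fs
  times <- seq(round(epoch_window[1] * fs), round(epoch_window[2] * fs)) / fs
  n_samp <- length(times)
  r <- dim(gtn$coeffs)[2]
  p <- dim(gtn$coeffs)[1]
  n_per <- design$n_trials_per_condition
  condition <- rep(design$conditions, times = n_per) # interleaved, balanced
  n_trials <- length(condition)
  burn_in <- max(10 * p, 50)
  data <- array(NA_real_, c(n_trials, r, n_samp))
  withr_seed(design$seed, {
    rt <- rt_truncnorm(n_trials, design$rt_mean, design$rt_sd, design$rt_min)
    correct <- stats::runif(n_trials) < design$accuracy
    for (tr in seq_len(n_trials)) {
      cond_i <- match(condition[tr], design$conditions)
      inj <- matrix(0, r, n_samp)
      if (!is.null(design$templates)) {
        tpl <- design$templates[[cond_i]]
        stopifnot(nrow(tpl) == length(design$source_regions),
                  ncol(tpl) == n_samp)
        inj[design$source_regions, ] <- tpl
      } else {
        signs <- rep(c(1, -1), length.out = length(design$source_regions))
        if (cond_i == 2) signs <- -signs
        bump <- half_cosine_bump(times, rt[tr] + design$centre_offset,
                                 design$duration)
        inj[design$source_regions, ] <-
          design$amplitude * outer(signs, bump)
      }
      data[tr, , ] <- simulate_var_segment(gtn, n_samp, burn_in, inj)
      if (!is.null(design$leakage_mix)) {
        data[tr, , ] <- design$leakage_mix %*% data[tr, , ]
      }
    }
  })
  epoch_set(data, fs = fs, times = times, lock = "stimulus",
            condition = condition, rt = rt, correct = correct,
            region_ids = gtn$atlas$region_id)
}

#' Assemble an MVAR fit object from ground-truth coefficients
#'
#' Rearranges the generator's lagged weights into the fitted-connectivity
#' layout (per-target lagged source weights plus self-coupling), which is
#' exact by construction. Useful as a noise-free oracle for activity-flow
#' predictions and for parameter-recovery scoring.
#'
#' @param gtn A ground-truth network.
#' @param target_network Target network name.
#' @return An `mvar_fit` whose `F`/`C` equal the ground-truth weights and
#'   whose contemporaneous weights `B0` are zero.
#' @export
as_mvar_fit <- function(gtn, target_network = "Motor") {
  stopifnot(inherits(gtn, "ground_truth_network"))
  atlas <- gtn$atlas
  targets <- network_regions(atlas, target_network)
  p <- dim(gtn$coeffs)[1]
  r <- dim(gtn$coeffs)[2]
  Fw <- array(0, c(length(targets), r, p))
  Cw <- matrix(0, length(targets), p)
  for (j in seq_along(targets)) {
    for (i in seq_len(p)) {
      Fw[j, , i] <- gtn$coeffs[i, targets[j], ]
      Cw[j, i] <- gtn$coeffs[i, targets[j], targets[j]]
      Fw[j, targets[j], i] <- 0
    }
  }
  new_mvar_fit(
    F = Fw, C = Cw, B0 = matrix(0, length(targets), r), order = p,
    n_pcs_selected = NA_integer_, pc_grid = integer(0), cv_mse = NULL,
    atlas = atlas, target_network = target_network, targets = targets
  )
}

#' Simulate a multi-subject synthetic study
#'
#' Each subject receives an independent ground-truth network (same atlas and
#' geometry, different coefficient draw), an independent rest session, and an
#' independent task session, mirroring a cohort in which connectivity is
#' individual but the experimental design is shared.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions,order,density,stability_bound,noise_sd Ground-truth
#'   parameters, see [make_random_stable_var].
#' @param n_pseudo_trials,n_rest_samples Rest geometry per subject.
#' @param design_args List of arguments forwarded to [evoked_design]
#'   (everything except `source_regions` and `seed`, which are filled in).
#' @param source_networks Networks whose regions receive evoked injections.
#' @param target_network Target network name.
#' @param isolated_networks Networks made information-isolated (see
#'   `receive_only_within` in [make_random_stable_var]); the default keeps
#'   one control network that never carries task information, so simulated
#'   lesioning has a known-uninvolved comparison.
#' @param atlas Optional shared [region_atlas].
#' @param epoch_window Stimulus-locked epoch window (s).
#' @param seed Master seed; per-subject seeds are expanded from it.
#' @return A list with elements `atlas`, `target_network` and `subjects`, the
#'   latter a list of per-subject lists `(gtn, rest, task)`.
#' @export
simulate_study <- function(n_subjects, n_regions = 16, order = 3,
                           density = 0.2, stability_bound = 0.9,
                           noise_sd = 1, n_pseudo_trials = 10,
                           n_rest_samples = 2000,
                           design_args = list(n_trials_per_condition = 56),
                           source_networks = "Visual",
                           target_network = "Motor",
                           isolated_networks = "DAN", atlas = NULL,
                           epoch_window = c(-0.5, 1.5), seed = 1) {
  if (is.null(atlas)) atlas <- synthetic_atlas(n_regions)
  src <- which(atlas$network %in% source_networks)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    gtn <- make_random_stable_var(
      n_regions, order, density, stability_bound, noise_sd, atlas = atlas,
      seed = expand_seed(seed, "gtn", s),
      receive_only_within = isolated_networks
    )
    rest <- simulate_rest(gtn, n_pseudo_trials, n_rest_samples,
                          seed = expand_seed(seed, "rest", s))
    design <- do.call(evoked_design, c(
      design_args,
      list(source_regions = src, seed = expand_seed(seed, "task", s))
    ))
    task <- simulate_task(gtn, design, target_network = target_network,
                          epoch_window = epoch_window)
    list(gtn = gtn, rest = rest, task = task)
  })
  list(atlas = atlas, target_network = target_network, subjects = subjects)
}
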