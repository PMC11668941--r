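#' Per-network On-vs-Off effect amplitudes
#'
#' Amplitudes are in percent-signal units (negative = suppression of BOLD
#' with stimulation On) and are specified separately for therapeutic and
#' non-therapeutic stimulation configurations. The default therapeutic
#' profile suppresses the default mode network by 0.3% and leaves the other
#' networks at zero; the default non-therapeutic profile is null everywhere
#' (run-to-run heterogeneity then comes from noise alone).
#'
#' @param network_names Character vector of network names.
#' @param therapeutic Named (or positional) numeric amplitudes per network
#'   for therapeutic runs.
#' @param nontherapeutic Same for non-therapeutic runs.
#' @param parcel_jitter_sd SD of an optional per-parcel amplitude jitter
#'   (percent signal), 0 for none.
#' @return Object of class `network_effect_profile`.
#' @export
network_effect_profile <- function(network_names = c("Vis", "SomMot",
                                                     "DorsAttn",
                                                     "SalVentAttn", "Limbic",
                                                     "Cont", "Default"),
                                   therapeutic = NULL, nontherapeutic = NULL,
                                   parcel_jitter_sd = 0) {
  K <- length(network_names)
  if (is.null(therapeutic)) {
    therapeutic <- stats::setNames(numeric(K), network_names)
    if ("Default" %in% network_names) therapeutic["Default"] <- -0.3
  }
  if (is.null(nontherapeutic)) {
    nontherapeutic <- stats::setNames(numeric(K), network_names)
  }
  therapeutic <- .match_net(therapeutic, network_names)
  nontherapeutic <- .match_net(nontherapeutic, network_names)
  stopifnot(all(is.finite(therapeutic)), all(is.finite(nontherapeutic)),
            parcel_jitter_sd >= 0)
  structure(list(network_names = network_names, therapeutic = therapeutic,
                 nontherapeutic = nontherapeutic,
                 parcel_jitter_sd = parcel_jitter_sd),
            class = "network_effect_profile")
}

.match_net <- function(x, nms) {
  if (!is.null(names(x))) {
    out <- stats::setNames(numeric(length(nms)), nms)
    stopifnot(all(names(x) %in% nms))
    out[names(x)] <- x
    out
  } else {
    stopifnot(length(x) == length(nms))
    stats::setNames(as.numeric(x), nms)
  }
}

#' Noise model for synthetic BOLD runs
#'
#' @param sd Voxel noise SD in percent signal (marginal SD of the AR(1)
#'   process).
#' @param ar1 Lag-1 autocorrelation in `[0, 1)`.
#' @param drift_coefs Legendre drift coefficients (orders 0..3) in percent
#'   signal, applied multiplicatively to the baseline.
#' @param spike_prob Per-frame probability of a motion spike.
#' @param spike_mm Translation magnitude of a spike, mm.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 1, ar1 = 0.3, drift_coefs = c(0, 0.3, -0.2, 0.1),
                       spike_prob = 0.02, spike_mm = 1) {
  stopifnot(sd >= 0, ar1 >= 0, ar1 < 1, length(drift_coefs) <= 4,
            spike_prob >= 0, spike_prob <= 1, spike_mm >= 0)
  structure(list(sd = sd, ar1 = ar1,
                 drift_coefs = c(drift_coefs, numeric(4))[1:4],
                 spike_prob = spike_prob, spike_mm = spike_mm),
            class = "noise_spec")
}

#' Simulate one cycling-paradigm BOLD run
#'
#' Voxel time series are built as
#' `100 + drift~(t) + amplitude_v * r~_on(t) + noise(t)`, where `r_on` is
#' the On stimulus regressor convolved with the canonical HRF (the same
#' constructor the GLM uses) and `drift` a Legendre polynomial in percent
#' units; `~` denotes within-run mean-centering, so a noiseless voxel has
#' mean exactly 100, the mean-100 scaling step is the identity, and the GLM
#' (whose intercept absorbs the centering constant) recovers `amplitude_v`
#' to machine precision. `amplitude_v` is the run condition's network
#' amplitude of the voxel's parcel (plus optional parcel jitter) and noise
#' is AR(1) with marginal SD `noise$sd`. Background voxels carry baseline + noise only. Head-motion
#' parameter traces (slow random walk plus occasional spikes) are returned
#' alongside for the QC stage; spikes also add a matching intensity
#' disturbance to the volume so that DVARS sees them.
#'
#' @param design A [cycling_design()].
#' @param atlas A `parcel_atlas`.
#' @param effects A [network_effect_profile()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed; the run is a pure function of the arguments.
#' @param condition `"therapeutic"` or `"nontherapeutic"`: which amplitude
#'   column of `effects` is injected.
#' @param ramp_mode Stimulus regressor ramp handling (see
#'   [stimulus_boxcars()]); keep equal to the GLM's mode for exact noiseless
#'   recovery, set `"linear"` here only for model-mismatch experiments.
#' @return List with `bold` (4D array x,y,z,t), `motion` (data.frame of
#'   trans_x/y/z mm and rot_x/y/z rad), `truth` (per-parcel injected
#'   amplitudes), and the design.
#' @export
simulate_run <- function(design, atlas, effects = network_effect_profile(),
                         noise = noise_spec(), seed = 1,
                         condition = c("therapeutic", "nontherapeutic"),
                         ramp_mode = c("excluded", "linear")) {
  condition <- match.arg(condition)
  ramp_mode <- match.arg(ramp_mode)
  stopifnot(inherits(design, "cycling_design"),
            inherits(atlas, "parcel_atlas"),
            inherits(effects, "network_effect_profile"),
            inherits(noise, "noise_spec"),
            length(effects$network_names) >= max(atlas$assignment))

  n <- design$n_frames
  dims <- dim(atlas$labels)
  nvox <- prod(dims)
  kern <- hrf_kernel(design$tr_s)
  r_on <- convolve_regressor(stimulus_boxcars(design, ramp_mode)$on, kern)
  r_on <- r_on - mean(r_on)
  drift <- as.numeric(legendre_basis(n, 3) %*% noise$drift_coefs)
  base_ts <- 100 + (drift - mean(drift))

  amp_net <- if (condition == "therapeutic") effects$therapeutic else
    effects$nontherapeutic

  withr::with_seed(seed, {
    amp_parcel <- amp_net[atlas$assignment]
    if (effects$parcel_jitter_sd > 0) {
      amp_parcel <- amp_parcel +
        stats::rnorm(length(amp_parcel), 0, effects$parcel_jitter_sd)
    }
    amp_vox <- numeric(nvox)
    inb <- atlas$labels > 0
    amp_vox[inb] <- amp_parcel[atlas$labels[inb]]

    # frames x voxels signal matrix
    Y <- outer(base_ts, rep(1, nvox)) + outer(r_on, amp_vox)
    if (noise$sd > 0) {
      innov_sd <- noise$sd * sqrt(1 - noise$ar1^2)
      eps <- matrix(stats::rnorm(n * nvox, 0, innov_sd), n, nvox)
      if (noise$ar1 > 0) {
        eps <- apply(eps, 2, function(e)
          as.numeric(stats::filter(e, noise$ar1, method = "recursive")))
      }
      Y <- Y + eps
    }

    motion <- .simulate_motion(n, noise)
    spikes <- attr(motion, "spike_frames")
    if (length(spikes) > 0 && noise$sd >= 0) {
      # a motion spike perturbs the whole volume for one frame
      Y[spikes, ] <- Y[spikes, , drop = FALSE] +
        matrix(stats::rnorm(length(spikes) * nvox, 0,
                            2 * max(noise$sd, 0.5)),
               length(spikes), nvox)
    }
    bold <- array(t(Y), dim = c(dims, n))
    truth <- stats::setNames(amp_parcel, seq_along(amp_parcel))
    list(bold = bold, motion = motion, truth = truth, design = design,
         condition = condition)
  })
}

.simulate_motion <- function(n, noise) {
  walk <- function(sd) cumsum(stats::rnorm(n, 0, sd))
  m <- data.frame(trans_x = walk(0.01), trans_y = walk(0.01),
                  trans_z = walk(0.01), rot_x = walk(2e-4),
                  rot_y = walk(2e-4), rot_z = walk(2e-4))
  spikes <- integer(0)
  if (noise$spike_prob > 0 && noise$spike_mm > 0) {
    hit <- which(stats::runif(n) < noise$spike_prob)
    hit <- hit[hit > 1]
    if (length(hit) > 0) {
      ax <- sample(1:3, length(hit), replace = TRUE)
      for (i in seq_along(hit)) {
        m[hit[i], ax[i]] <- m[hit[i], ax[i]] +
          noise$spike_mm * sign(stats::rnorm(1))
      }
      spikes <- hit
    }
  }
  attr(m, "spike_frames") <- spikes
  m
}
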