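#' Specification of a synthetic cortical activation
#'
#' A spherical gray-matter activation whose O2Hb time course is the task
#' design convolved with the canonical HRF, peaking at \code{peak_o2hb}
#' micromolar, with an opposite HHb change \code{hhb_ratio} times smaller —
#' the canonical neurovascular response (a few uM O2Hb increase with a
#' 2-3x smaller HHb decrease).
#'
#' @param center Activation center in mm (must fall in gray matter).
#' @param radius Sphere radius in mm (default 10).
#' @param peak_o2hb Peak O2Hb change, uM (default +1).
#' @param hhb_ratio O2Hb-to-HHb magnitude ratio (default 2.5; the HHb peak
#'   is \code{-peak_o2hb / hhb_ratio}).
#' @param hrf Optional list of \code{\link{canonical_hrf}} parameter
#'   overrides.
#' @export
activation_spec <- function(center, radius = 10, peak_o2hb = 1.0,
                            hhb_ratio = 2.5, hrf = list()) {
  if (radius <= 0) stopf("radius must be positive")
  if (hhb_ratio <= 0) stopf("hhb_ratio must be positive")
  structure(list(center = as.numeric(center), radius = radius,
                 peak_o2hb = peak_o2hb, hhb_ratio = hhb_ratio, hrf = hrf),
            class = "activation_spec")
}

#' Specification of simulated noise and nuisance signals
#'
#' Amplitudes are micromolar hemoglobin oscillations except where noted.
#' The defaults are calibrated so that band-pass filtered channel-level
#' hemoglobin noise has a standard deviation of roughly 0.1-0.3 uM,
#' a plausible background for activations of a few uM.
#'
#' @param cardiac,respiratory,mayer Named vectors \code{c(freq =, amp =)}:
#'   sinusoidal gray-matter oscillations at the cardiac (~1.1 Hz),
#'   respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz) frequencies.
#' @param drift Random-walk scale of slow hemodynamic drift, uM per sqrt(s).
#' @param measurement Multiplicative white intensity noise fraction.
#' @param ect_gain Amplitude of extracranial (scalp-layer) hemodynamic
#'   interference, uM.
#' @param motion Named vector \code{c(rate =, amp =, shift_prob =)}: spike
#'   rate per minute, spike amplitude in OD, and probability that a spike
#'   also causes a persistent baseline shift.
#' @export
noise_spec <- function(cardiac = c(freq = 1.1, amp = 0.6),
                       respiratory = c(freq = 0.25, amp = 0.3),
                       mayer = c(freq = 0.1, amp = 0.25),
                       drift = 0.03,
                       measurement = 0.003,
                       ect_gain = 0.4,
                       motion = c(rate = 0, amp = 0.2, shift_prob = 0.3)) {
  spec <- list(cardiac = cardiac, respiratory = respiratory, mayer = mayer,
               drift = drift, measurement = measurement, ect_gain = ect_gain,
               motion = motion)
  amps <- c(cardiac["amp"], respiratory["amp"], mayer["amp"], drift,
            measurement, ect_gain, motion["amp"], motion["rate"])
  if (any(amps < 0)) stopf("noise amplitudes must be nonnegative")
  structure(spec, class = "noise_spec")
}

#' Zero-noise specification (for oracle and round-trip tests)
#' @export
noise_none <- function() {
  noise_spec(cardiac = c(freq = 1.1, amp = 0), respiratory = c(freq = 0.25, amp = 0),
             mayer = c(freq = 0.1, amp = 0), drift = 0, measurement = 0,
             ect_gain = 0, motion = c(rate = 0, amp = 0, shift_prob = 0))
}

#' Simulate a dual-wavelength DC intensity recording
#'
#' Generates raw channel intensities with a known ground truth:
#' \enumerate{
#'   \item voxel chromophore time series = HRF-convolved design response in
#'     a gray-matter sphere, plus physiological oscillations (cardiac,
#'     respiratory, Mayer) and random-walk drift in gray matter and
#'     extracranial interference in the scalp layer;
#'   \item chromophores map to per-wavelength absorption changes through
#'     the pinned extinction table;
#'   \item absorption changes map to channel optical density through the
#'     Jacobian (Rytov);
#'   \item intensities \eqn{I = A_{sd} e^{-\Delta OD} (1 + \epsilon)} with
#'     multiplicative measurement noise, after motion artifacts are
#'     injected in the OD domain (identically at both wavelengths).
#' }
#' Regenerating with the same seed reproduces the recording exactly.
#'
#' @param head A \code{head_model}.
#' @param layout A \code{probe_layout} on the head surface.
#' @param design A \code{task_design}.
#' @param activation An \code{\link{activation_spec}} (center must be in
#'   gray matter).
#' @param noise A \code{\link{noise_spec}}.
#' @param jacobian A precomputed \code{\link{compute_jacobian}} result for
#'   this head/layout (checked by geometry hash).
#' @param seed Integer seed.
#' @return Object of class \code{synthetic_recording}: list with
#'   \code{recording} (an \code{optical_recording}), \code{truth} (activation
#'   map indices/gains, chromophore time courses, injected artifacts) and
#'   \code{seed}.
#' @export
simulate_recording <- function(head, layout, design, activation,
                               noise = noise_spec(), jacobian, seed = 1L) {
  if (jacobian$geometry_hash != geometry_hash(head, layout)) {
    stopf("jacobian geometry hash does not match this head/layout")
  }
  fs <- design$event_table$sampling_rate
  n <- round(design$event_table$total_duration * fs)
  lab <- as.vector(head$tissue)[jacobian$voxel_index]
  coords <- voxel_centers(head, jacobian$voxel_index)

  cv <- point_to_voxel(head, activation$center)
  if (is.na(cv) || as.vector(head$tissue)[cv] != 3L) {
    stopf("activation center must lie inside gray matter")
  }
  d2 <- rowSums(sweep(coords, 2L, activation$center)^2)
  act_map <- as.numeric(lab == 3L & d2 <= activation$radius^2)
  if (!any(act_map > 0)) stopf("activation sphere contains no gray-matter voxels")
  gray_map <- as.numeric(lab == 3L)
  scalp_map <- as.numeric(lab == 1L)

  tt <- (seq_len(n) - 1) / fs
  indicator <- design_vector(design, n, fs)
  resp <- hrf_response(indicator, fs, peak = activation$peak_o2hb,
                       hrf_params = activation$hrf)

  with_seed(seed, {
    phases <- stats::runif(4L, 0, 2 * pi)
    osc <- function(par, ph) par[["amp"]] * sin(2 * pi * par[["freq"]] * tt + ph)
    drift_o <- noise$drift / sqrt(fs) * cumsum(stats::rnorm(n))
    drift_h <- noise$drift / sqrt(fs) * cumsum(stats::rnorm(n))
    # components: spatial gain map, O2Hb/HHb amplitudes (uM), time course
    comps <- list(
      list(map = act_map, o2hb = 1, hhb = -1 / activation$hhb_ratio, ts = resp),
      list(map = gray_map, o2hb = 1, hhb = -0.25, ts = osc(noise$cardiac, phases[1L])),
      list(map = gray_map, o2hb = 1, hhb = 0.25, ts = osc(noise$respiratory, phases[2L])),
      list(map = gray_map, o2hb = 1, hhb = -0.3, ts = osc(noise$mayer, phases[3L])),
      list(map = gray_map, o2hb = 1, hhb = 0, ts = drift_o),
      list(map = gray_map, o2hb = 0, hhb = 1, ts = drift_h),
      list(map = scalp_map, o2hb = 1, hhb = -0.2,
           ts = noise$ect_gain * (0.6 * sin(2 * pi * 0.08 * tt + phases[4L]) +
                                    0.4 * sin(2 * pi * noise$cardiac[["freq"]] * tt + phases[1L])))
    )

    ext <- extinction_coefficients()
    wls <- as.character(layout$wavelengths)
    nch <- nrow(layout$channels)
    od <- array(0, dim = c(2L, nch, n), dimnames = list(wls, NULL, NULL))
    for (k in seq_along(comps)) {
      cm <- comps[[k]]
      if (all(cm$ts == 0) || all(cm$map == 0)) next
      for (w in 1:2) {
        gain_mu <- ext[wls[w], "o2hb"] * cm$o2hb + ext[wls[w], "hhb"] * cm$hhb
        jch <- as.numeric(jacobian$J[[wls[w]]] %*% cm$map) * gain_mu
        od[w, , ] <- od[w, , ] + outer(jch, cm$ts)
      }
    }

    artifacts <- NULL
    if (noise$motion[["rate"]] > 0) {
      mot <- inject_motion(od, noise$motion, fs, seed = NULL)
      od <- mot$od
      artifacts <- mot$artifacts
    }

    intens <- array(0, dim = dim(od), dimnames = dimnames(od))
    for (w in 1:2) {
      eps <- if (noise$measurement > 0) {
        matrix(stats::rnorm(nch * n, sd = noise$measurement), nch, n)
      } else 0
      intens[w, , ] <- jacobian$amplitudes[, wls[w]] * exp(-od[w, , ]) * (1 + eps)
    }

    rec <- optical_recording(intens, sampling_rate = fs, layout = layout,
                             events = design$event_table)
    structure(
      list(recording = rec,
           truth = list(activation = activation, map = act_map,
                        voxel_index = jacobian$voxel_index,
                        o2hb_ts = resp, hhb_ts = -resp / activation$hhb_ratio,
                        artifacts = artifacts, design = design),
           seed = seed),
      class = "synthetic_recording"
    )
  })
}

#' Inject motion artifacts into an optical-density series
#'
#' Adds transient spikes (decaying exponential, under 2 s) and, with some
#' probability, persistent step baseline shifts at Poisson-distributed
#' times, identically across the wavelengths of a channel (motion moves the
#' optode, not the chromophores).
#'
#' @param od Array (wavelength x channel x time) or matrix (channel x time)
#'   of OD values.
#' @param motion_params Named vector \code{c(rate, amp, shift_prob)}; rate
#'   in events/minute, amp in OD.
#' @param sampling_rate Hz.
#' @param seed Optional integer seed (NULL inherits the caller's RNG
#'   stream).
#' @return List with the modified \code{od} and an \code{artifacts} data
#'   frame (\code{channel}, \code{sample}, \code{type}, \code{amplitude})
#'   usable as ground truth by motion-correction tests.
#' @export
inject_motion <- function(od, motion_params, sampling_rate, seed = NULL) {
  run <- function() {
    arr <- length(dim(od)) == 3L
    nch <- if (arr) dim(od)[2L] else nrow(od)
    n <- if (arr) dim(od)[3L] else ncol(od)
    rate <- motion_params[["rate"]]
    amp <- motion_params[["amp"]]
    shift_prob <- motion_params[["shift_prob"]]
    log <- list()
    for (ch in seq_len(nch)) {
      n_ev <- stats::rpois(1L, rate * n / sampling_rate / 60)
      if (n_ev == 0L) next
      at <- sort(sample.int(n, n_ev))
      for (t0 in at) {
        sgn <- sample(c(-1, 1), 1L)
        tau <- stats::runif(1L, 0.15, 0.4)
        len <- min(n - t0 + 1L, ceiling(2 * sampling_rate))
        shape <- sgn * amp * exp(-(seq_len(len) - 1) / (tau * sampling_rate))
        idx <- t0:(t0 + len - 1L)
        step <- 0
        if (stats::runif(1L) < shift_prob) step <- sgn * amp / 2
        if (arr) {
          for (w in seq_len(dim(od)[1L])) {
            od[w, ch, idx] <- od[w, ch, idx] + shape
            if (step != 0 && t0 < n) od[w, ch, t0:n] <- od[w, ch, t0:n] + step
          }
        } else {
          od[ch, idx] <- od[ch, idx] + shape
          if (step != 0 && t0 < n) od[ch, t0:n] <- od[ch, t0:n] + step
        }
        log[[length(log) + 1L]] <- data.frame(
          channel = ch, sample = t0,
          type = if (step != 0) "spike+shift" else "spike",
          amplitude = sgn * amp)
      }
    }
    artifacts <- if (length(log)) do.call(rbind, log) else
      data.frame(channel = integer(), sample = integer(),
                 type = character(), amplitude = numeric())
    list(od = od, artifacts = artifacts)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
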