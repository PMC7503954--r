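#' Channel-level optical recording
#'
#' @param intensities Array (wavelength x channel x time) of strictly
#'   positive DC intensities; the first dimension must be named with the
#'   wavelengths.
#' @param sampling_rate Hz (default 39.7365).
#' @param layout A \code{probe_layout}.
#' @param events An \code{event_table} or NULL.
#' @return Object of class \code{optical_recording}.
#' @export
optical_recording <- function(intensities, sampling_rate = 39.7365,
                              layout = NULL, events = NULL) {
  if (length(dim(intensities)) != 3L) {
    stopf("intensities must be a (wavelength x channel x time) array")
  }
  if (any(intensities <= 0)) {
    bad <- which(intensities <= 0, arr.ind = TRUE)[1L, ]
    stopf("nonpositive intensity at wavelength %s, channel %d, sample %d",
          dimnames(intensities)[[1L]][bad[1L]] %||% bad[1L], bad[2L], bad[3L])
  }
  if (!is.null(events)) {
    expected <- events$total_duration * sampling_rate
    if (abs(dim(intensities)[3L] - expected) > 1) {
      stopf("time axis (%d samples) inconsistent with %g s at %g Hz",
            dim(intensities)[3L], events$total_duration, sampling_rate)
    }
  }
  structure(list(intensities = intensities, sampling_rate = sampling_rate,
                 layout = layout, events = events),
            class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<optical_recording> %d wavelengths x %d channels x %d samples at %g Hz (%.1f s)\n",
              d[1L], d[2L], d[3L], x$sampling_rate, d[3L] / x$sampling_rate))
  invisible(x)
}

#' Convert intensities to optical density
#'
#' Each channel/wavelength series is normalized by its temporal mean and
#' log-transformed: \eqn{OD(t) = -\ln(I(t) / \bar I)}. The result is
#' invariant to any positive per-channel intensity scaling.
#'
#' @param rec An \code{optical_recording}.
#' @return Object of class \code{od_series}: the OD array plus sampling
#'   rate, layout, events and provenance flags.
#' @export
to_optical_density <- function(rec) {
  stopifnot(inherits(rec, "optical_recording"))
  i_arr <- rec$intensities
  d <- dim(i_arr)
  od <- array(0, dim = d, dimnames = dimnames(i_arr))
  for (w in seq_len(d[1L])) {
    iw <- matrix(i_arr[w, , , drop = FALSE], d[2L], d[3L])
    od[w, , ] <- -log(iw / rowMeans(iw))
  }
  structure(list(od = od, sampling_rate = rec$sampling_rate,
                 layout = rec$layout, events = rec$events,
                 flags = list(normalized = TRUE, motion_corrected = FALSE,
                              filtered = FALSE),
                 bad_channels = integer()),
            class = "od_series")
}

#' Detect and correct motion artifacts
#'
#' Artifact samples are detected per channel from the first difference of
#' the wavelength-maximum OD: samples whose increment exceeds
#' \code{k_spike} robust standard deviations (MAD) are flagged and dilated
#' by \code{pad} seconds. Persistent baseline steps across a flagged
#' segment are re-leveled by matching the segment-flank medians; the
#' flagged span is then replaced by cubic-spline interpolation through the
#' surrounding clean samples. Unflagged samples are never altered. Channels
#' with more than half their samples flagged are marked bad and excluded
#' downstream.
#'
#' @param od An \code{od_series} (not yet filtered).
#' @param k_spike Detection threshold in robust SDs (default 5).
#' @param pad Dilation around detections, s (default 0.3).
#' @param flank Flank length used for step re-leveling, s (default 2).
#' @return The corrected \code{od_series}; the artifact log is attached as
#'   attribute \code{"artifact_log"} (data frame: channel, start, end,
#'   step).
#' @export
motion_correct <- function(od, k_spike = 5, pad = 0.3, flank = 2) {
  stopifnot(inherits(od, "od_series"))
  if (od$flags$filtered) stopf("motion correction must precede filtering")
  arr <- od$od
  d <- dim(arr)
  fs <- od$sampling_rate
  npad <- round(pad * fs)
  nflank <- max(3L, round(flank * fs))
  log <- list()
  bad <- integer()
  for (ch in seq_len(d[2L])) {
    ref <- apply(abs(arr[, ch, , drop = FALSE]), 3L, max)
    dd <- diff(ref)
    s <- stats::mad(dd)
    if (s <= 0) next
    flag <- c(FALSE, abs(dd) > k_spike * s)
    if (!any(flag)) next
    # dilate flagged samples
    hits <- which(flag)
    for (h in hits) flag[max(1L, h - npad):min(d[3L], h + npad)] <- TRUE
    if (mean(flag) > 0.5) {
      bad <- c(bad, ch)
      next
    }
    segs <- split(which(flag), cumsum(c(1, diff(which(flag)) != 1)))
    for (sg in segs) {
      a <- min(sg); b <- max(sg)
      pre <- max(1L, a - nflank):(a - 1L)
      post <- (b + 1L):min(d[3L], b + nflank)
      pre <- pre[pre >= 1L & pre < a]
      post <- post[post > b & post <= d[3L]]
      step <- 0
      for (w in seq_len(d[1L])) {
        x <- arr[w, ch, ]
        if (length(pre) >= 3L && length(post) >= 3L) {
          delta <- stats::median(x[post]) - stats::median(x[pre])
          if (abs(delta) > k_spike * s) {  # persistent level shift
            x[(b + 1L):d[3L]] <- x[(b + 1L):d[3L]] - delta
            step <- delta
          }
        }
        good <- c(pre, post)
        if (length(good) >= 4L) {
          x[a:b] <- stats::spline(good, x[good], xout = a:b)$y
        } else if (length(good) >= 1L) {
          x[a:b] <- mean(x[good])
        }
        arr[w, ch, ] <- x
      }
      log[[length(log) + 1L]] <- data.frame(channel = ch, start = a, end = b,
                                            step = step)
    }
  }
  if (length(bad)) {
    warning(sprintf("channel(s) %s flagged >50%% and marked bad",
                    paste(sort(unique(bad)), collapse = ", ")), call. = FALSE)
  }
  out <- od
  out$od <- arr
  out$flags$motion_corrected <- TRUE
  out$bad_channels <- sort(unique(c(od$bad_channels, bad)))
  attr(out, "artifact_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(channel = integer(), start = integer(), end = integer(),
               step = numeric())
  out
}

# Butterworth band-pass as second-order sections. A single (b, a)
# transfer function is numerically unstable at the very low normalized
# cutoff this application needs (0.01 Hz at ~40 Hz sampling), so the
# digital filter is built by bilinear transform of the analog prototype
# and kept factored into biquads.
butter_bandpass_sos <- function(order, low, high, fs) {
  wl <- 2 * fs * tan(pi * low / fs)
  wh <- 2 * fs * tan(pi * high / fs)
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k - 1 + order) / (2 * order))  # LHP prototype poles
  s_poles <- c()
  for (p in proto) {
    pb <- p * bw
    disc <- sqrt(pb^2 - 4 * w0^2)
    s_poles <- c(s_poles, (pb + disc) / 2, (pb - disc) / 2)
  }
  zd <- (1 + s_poles / (2 * fs)) / (1 - s_poles / (2 * fs))
  # conjugate-pair the poles into biquads with one zero at z = 1 and one
  # at z = -1 each
  up <- zd[order(Im(zd))][seq_len(order) + order]  # poles with Im >= 0 (sorted)
  sos <- lapply(up, function(z) {
    list(b = c(1, 0, -1), a = c(1, -2 * Re(z), abs(z)^2))
  })
  # unit gain at the digital center frequency
  f0 <- fs / pi * atan(w0 / (2 * fs))
  zc <- exp(1i * 2 * pi * f0 / fs)
  h <- vapply(sos, function(s) {
    abs(sum(s$b * zc^(0:-2)) / sum(s$a * zc^(0:-2)))
  }, numeric(1))
  # per-section gain normalization keeps intermediate signals O(1)
  for (i in seq_along(sos)) sos[[i]]$b <- sos[[i]]$b / h[i]
  list(sos = sos)
}

apply_sos <- function(x, filt) {
  for (s in filt$sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# Zero-phase (forward-backward) application with reflect padding.
filtfilt_reflect <- function(x, filt, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  xp <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- apply_sos(xp, filt)
  y <- rev(apply_sos(rev(y), filt))
  y[(npad + 1L):(npad + n)]
}

#' Zero-lag Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (default 0.01-0.3 Hz) forward
#' and backward, giving zero net phase; series are reflect-padded by three
#' low-cutoff periods before filtering and trimmed afterwards. The DC
#' component is removed by the pass band.
#'
#' @param od An \code{od_series}.
#' @param low,high Band edges, Hz.
#' @param order Butterworth order (default 4).
#' @return The filtered \code{od_series} (flag \code{filtered} set, the
#'   band stored in \code{$band}).
#' @export
bandpass <- function(od, low = 0.01, high = 0.3, order = 4) {
  stopifnot(inherits(od, "od_series"))
  fs <- od$sampling_rate
  if (low <= 0 || high <= low) stopf("need 0 < low < high")
  if (high >= fs / 2) stopf("high cutoff %g Hz is at or above Nyquist (%g Hz)", high, fs / 2)
  d <- dim(od$od)
  # settling scale of the low-frequency edge (impulse-response decay time)
  settle <- fs / (2 * pi * low)
  if (d[3L] < 3 * settle) {
    stopf("series of %d samples is shorter than 3 filter settling lengths (%d)",
          d[3L], ceiling(3 * settle))
  }
  bw <- butter_bandpass_sos(order, low, high, fs)
  npad <- ceiling(3 * fs / low)
  arr <- od$od
  for (w in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      arr[w, ch, ] <- filtfilt_reflect(od$od[w, ch, ], bw, npad)
    }
  }
  out <- od
  out$od <- arr
  out$flags$filtered <- TRUE
  out$band <- c(low, high)
  out$filter_order <- order
  out
}

#' Decimate an optical-density series
#'
#' Keeps every \code{factor}-th sample. Intended for use after band-pass
#' filtering, where the retained band (up to 0.3 Hz) is far below the
#' decimated Nyquist frequency, so no further anti-aliasing is needed.
#'
#' @param od A filtered \code{od_series}.
#' @param factor Positive integer decimation factor.
#' @export
decimate_od <- function(od, factor) {
  stopifnot(inherits(od, "od_series"))
  factor <- as.integer(factor)
  if (factor < 1L) stopf("factor must be a positive integer")
  if (factor == 1L) return(od)
  if (!od$flags$filtered) stopf("decimate only after band-pass filtering")
  keep <- seq(1L, dim(od$od)[3L], by = factor)
  out <- od
  out$od <- od$od[, , keep, drop = FALSE]
  out$sampling_rate <- od$sampling_rate / factor
  out
}

#' Channel-space hemoglobin conversion (modified Beer-Lambert law)
#'
#' For each channel solves the 2x2 spectral system
#' \deqn{\Delta OD(\lambda) = [\epsilon_{O2Hb}(\lambda)\,\Delta C_{O2Hb} +
#'   \epsilon_{HHb}(\lambda)\,\Delta C_{HHb}]\, d \cdot DPF(\lambda)}
#' with \eqn{d} the source-detector distance, giving channel O2Hb/HHb
#' concentration changes in micromolar. Used for signal-quality inspection;
#' volumetric chromophore estimates come from the tomography module.
#'
#' @param od An \code{od_series} (both wavelengths present).
#' @param layout Probe layout (defaults to the one carried by \code{od}).
#' @param dpf Differential pathlength factors, named by wavelength.
#' @param extinction 2x2 extinction matrix (see
#'   \code{\link{extinction_coefficients}}).
#' @return Object of class \code{channel_hb}: \code{o2hb}, \code{hhb}
#'   (channel x time matrices, uM), plus the conversion constants.
#' @export
mbll_channels <- function(od, layout = od$layout, dpf = dpf_defaults(),
                          extinction = extinction_coefficients()) {
  stopifnot(inherits(od, "od_series"))
  d <- dim(od$od)
  if (d[1L] != 2L) stopf("both wavelengths are required")
  wls <- dimnames(od$od)[[1L]]
  dist <- layout$channels$distance
  if (any(dist <= 0)) stopf("zero source-detector distance in layout")
  o2hb <- hhb <- matrix(0, d[2L], d[3L])
  for (ch in seq_len(d[2L])) {
    m <- extinction * (dist[ch] * dpf[wls])  # row-wise: d * DPF(lambda)
    sol <- solve(m, rbind(od$od[1L, ch, ], od$od[2L, ch, ]))
    o2hb[ch, ] <- sol[1L, ]
    hhb[ch, ] <- sol[2L, ]
  }
  structure(list(o2hb = o2hb, hhb = hhb, dpf = dpf, extinction = extinction,
                 sampling_rate = od$sampling_rate, layout = layout,
                 events = od$events, bad_channels = od$bad_channels),
            class = "channel_hb")
}

#' Task-locked block average
#'
#' Epochs the channel hemoglobin series around each stimulation onset,
#' subtracts the pre-onset baseline mean, and averages across epochs.
#'
#' @param hb A \code{channel_hb}.
#' @param design A \code{task_design} with at least one stimulation epoch.
#' @param pre Baseline window before onset, s (default 5).
#' @param post Time kept after the end of the stimulation epoch, s
#'   (default 15).
#' @return List with \code{time} (s, relative to onset), \code{o2hb} and
#'   \code{hhb} (channel x time averages, uM) and \code{n_epochs}.
#' @export
block_average <- function(hb, design, pre = 5, post = 15) {
  stopifnot(inherits(hb, "channel_hb"))
  fs <- hb$sampling_rate
  epochs <- stimulation_epochs(design)
  if (nrow(epochs) == 0L) stopf("design has no stimulation epochs")
  span <- max(epochs$duration)
  rel <- seq(-round(pre * fs), round((span + post) * fs)) / fs
  n <- ncol(hb$o2hb)
  acc_o <- acc_h <- matrix(0, nrow(hb$o2hb), length(rel))
  used <- 0L
  truncated <- FALSE
  for (i in seq_len(nrow(epochs))) {
    idx <- round(epochs$onset[i] * fs) + round(rel * fs) + 1L
    if (any(idx < 1L) || any(idx > n)) {
      truncated <- TRUE
      next
    }
    base <- idx[rel < 0]
    acc_o <- acc_o + hb$o2hb[, idx, drop = FALSE] -
      rowMeans(hb$o2hb[, base, drop = FALSE])
    acc_h <- acc_h + hb$hhb[, idx, drop = FALSE] -
      rowMeans(hb$hhb[, base, drop = FALSE])
    used <- used + 1L
  }
  if (truncated) warning("epochs extending past the recording were dropped", call. = FALSE)
  if (used == 0L) stopf("no complete epoch inside the recording")
  list(time = rel, o2hb = acc_o / used, hhb = acc_h / used, n_epochs = used)
}
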