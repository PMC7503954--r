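toy_recording <- function(i_arr, fs = 40) {
  optical_recording(i_arr, sampling_rate = fs)
}

test_that("optical density conversion follows -ln(I / mean)", {
  n <- 1000
  i_arr <- array(2.5, dim = c(2, 1, n), dimnames = list(c("690", "830")))
  od <- to_optical_density(toy_recording(i_arr))
  expect_equal(max(abs(od$od)), 0)

  # a single sample dipped by exp(-0.1): OD there is 0.1 minus the mean shift
  i2 <- i_arr
  i2[1, 1, 500] <- 2.5 * exp(-0.1)
  od2 <- to_optical_density(toy_recording(i2))
  mean_i <- mean(i2[1, 1, ])
  expect_equal(as.numeric(od2$od[1, 1, 500]), 0.1 - log(2.5 / mean_i),
               tolerance = 1e-12)
  # OD has (near) zero temporal mean by construction of the normalization
  expect_lt(abs(mean(od2$od[1, 1, ])), 1e-4)

  # positive rescaling of a channel leaves OD untouched
  i3 <- i2
  i3[1, 1, ] <- i3[1, 1, ] * 37.2
  od3 <- to_optical_density(toy_recording(i3))
  expect_equal(od3$od, od2$od, tolerance = 1e-12)

  bad <- i_arr; bad[2, 1, 3] <- 0
  expect_error(toy_recording(bad), "channel 1, sample 3")
})

test_that("motion correction repairs spikes and leaves clean data alone", {
  fs <- 40
  n <- 4000
  tt <- (1:n) / fs
  set.seed(21)
  clean <- 0.01 * sin(2 * pi * 0.05 * tt) + 0.002 * sin(2 * pi * 1.1 * tt) +
    rnorm(n, sd = 5e-4)
  arr <- array(rep(clean, each = 2), dim = c(2, 1, n),
               dimnames = list(c("690", "830")))
  od <- make_od(arr, fs)

  # false-positive audit: artifact-free series is nearly untouched
  fixed <- motion_correct(od)
  altered <- mean(fixed$od[1, 1, ] != od$od[1, 1, ])
  expect_lte(altered, 0.01)

  # one injected 0.5-OD spike is strongly suppressed
  mot <- inject_motion(arr, c(rate = 0, amp = 0, shift_prob = 0), fs)$od
  spike_at <- 2000
  decay <- exp(-(0:39) / (0.25 * fs))
  arr_sp <- arr
  for (w in 1:2) arr_sp[w, 1, spike_at + 0:39] <- arr_sp[w, 1, spike_at + 0:39] + 0.5 * decay
  od_sp <- make_od(arr_sp, fs)
  fixed_sp <- motion_correct(od_sp)
  err_before <- max(abs(arr_sp[1, 1, ] - clean))
  err_after <- max(abs(fixed_sp$od[1, 1, ] - clean))
  expect_gte(err_before / err_after, 5)
  # samples outside the logged corrections are bit-identical (a logged
  # step re-levels everything after its segment, so exclude those tails)
  log <- attr(fixed_sp, "artifact_log")
  flagged <- unique(unlist(lapply(seq_len(nrow(log)), function(i) {
    if (log$step[i] != 0) log$start[i]:n else log$start[i]:log$end[i]
  })))
  expect_identical(fixed_sp$od[1, 1, -flagged], od_sp$od[1, 1, -flagged])

  # an all-zero series passes through unchanged
  zeros <- make_od(array(0, dim = c(2, 1, n), dimnames = list(c("690", "830"))), fs)
  expect_identical(motion_correct(zeros)$od, zeros$od)
})

test_that("a persistent step shift is re-leveled", {
  fs <- 40
  n <- 4000
  set.seed(3)
  clean <- stats::rnorm(n, sd = 5e-4)
  arr <- array(rep(clean, each = 2), dim = c(2, 1, n),
               dimnames = list(c("690", "830")))
  arr[, 1, 2000:n] <- arr[, 1, 2000:n] + 0.3
  fixed <- motion_correct(make_od(arr, fs))
  resid <- fixed$od[1, 1, ] - clean
  expect_lt(max(abs(resid[2100:n])), 0.05)
})

test_that("band-pass is zero-lag with the specified band", {
  fs <- 39.7365
  n <- 16000
  tt <- (1:n) / fs
  mk <- function(x) make_od(array(rep(x, each = 2), dim = c(2, 1, n),
                                  dimnames = list(c("690", "830"))), fs)

  # cardiac line strongly attenuated (4th order, two passes)
  card <- sin(2 * pi * 1.1 * tt)
  out <- bandpass(mk(card))$od[1, 1, ]
  expect_gt(1 / sine_amplitude(out, 1.1, fs), 100)

  # passband tone preserved in amplitude and phase
  slow <- sin(2 * pi * 0.05 * tt)
  outs <- bandpass(mk(slow))$od[1, 1, ]
  expect_lt(abs(sine_amplitude(outs, 0.05, fs) - 1), 0.05)
  idx <- 4000:12000
  s <- sin(2 * pi * 0.05 * tt[idx]); cc <- cos(2 * pi * 0.05 * tt[idx])
  phase <- atan2(2 * mean(outs[idx] * cc), 2 * mean(outs[idx] * s)) * 180 / pi
  expect_lt(abs(phase), 1)

  # filtering twice changes a passband tone by < 5% further (idempotence)
  twice <- bandpass(bandpass(mk(slow)))$od[1, 1, ]
  expect_lt(abs(sine_amplitude(twice, 0.05, fs) /
                  sine_amplitude(outs, 0.05, fs) - 1), 0.05)

  # impulse response is symmetric about the impulse (zero-lag signature)
  imp <- numeric(n); imp[n / 2] <- 1
  outi <- bandpass(mk(imp))$od[1, 1, ]
  win <- (n / 2 - 3000):(n / 2 + 3000)
  expect_lt(max(abs(outi[win] - rev(outi[win]))), 1e-3 * max(abs(outi)))

  expect_error(bandpass(mk(card), low = 0.5, high = 0.3), "low < high")
  expect_error(bandpass(mk(card), high = 30), "Nyquist")
  short <- make_od(array(1e-3, dim = c(2, 1, 100), dimnames = list(c("690", "830"))), fs)
  expect_error(bandpass(short), "settling")
})

test_that("channel MBLL inverts a constructed spectral mixture exactly", {
  fs <- 10
  lay <- default_prefrontal_layout(center = c(0, 0), z = 0)
  nch <- nrow(lay$channels)
  n <- 50
  dpf <- dpf_defaults()
  ext <- extinction_coefficients()
  truth_o <- 1.0; truth_h <- -0.4
  od <- array(0, dim = c(2, nch, n), dimnames = list(c("690", "830")))
  for (ch in seq_len(nch)) {
    d <- lay$channels$distance[ch]
    for (w in 1:2) {
      wl <- c("690", "830")[w]
      od[w, ch, ] <- (ext[wl, "o2hb"] * truth_o + ext[wl, "hhb"] * truth_h) *
        d * dpf[wl]
    }
  }
  hb <- mbll_channels(make_od(od, fs, layout = lay))
  expect_lt(max(abs(hb$o2hb - truth_o)), 1e-10)
  expect_lt(max(abs(hb$hhb - truth_h)), 1e-10)

  # zero OD maps to zero concentrations
  hb0 <- mbll_channels(make_od(od * 0, fs, layout = lay))
  expect_equal(max(abs(hb0$o2hb)), 0)
  expect_equal(max(abs(hb0$hhb)), 0)
})

test_that("block averaging reduces independent noise like sqrt(n)", {
  fs <- 10
  design <- build_swg(sampling_rate = fs)
  n <- round(420 * fs)
  tt <- (1:n) / fs
  # identical epochs (60 s periodic signal, matching the block period):
  # the average equals any single epoch
  signal <- sin(2 * pi * tt / 60)
  hb_id <- structure(list(o2hb = matrix(signal, 1), hhb = matrix(-signal / 2.5, 1),
                          sampling_rate = fs), class = "channel_hb")
  ba <- block_average(hb_id, design, pre = 5, post = 10)
  on1 <- fnirsdot:::stimulation_epochs(design)$onset[2]
  idx <- round(on1 * fs) + round(ba$time * fs) + 1
  single <- signal[idx] - mean(signal[idx[ba$time < 0]])
  expect_equal(as.numeric(ba$o2hb[1, ]), single, tolerance = 1e-6)

  # zero signal + noise: averaging 5 epochs shrinks noise by about sqrt(5)
  set.seed(8)
  ratios <- replicate(40, {
    noise <- rnorm(n, sd = 1)
    hb_n <- structure(list(o2hb = matrix(noise, 1), hhb = matrix(noise, 1),
                           sampling_rate = fs), class = "channel_hb")
    ban <- block_average(hb_n, design, pre = 5, post = 10)
    sd(ban$o2hb[1, ban$time > 0])
  })
  expect_equal(mean(ratios), 1 / sqrt(5), tolerance = 0.15)
})
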