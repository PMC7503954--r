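# Shared fixtures, memoized so expensive geometry (Jacobians) is built once
# per test run.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(fixture_env[[name]])) assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

# Analytic oracle for the homogeneous semi-infinite medium: isotropic point
# source at depth src_depth with an image source across the extrapolated
# boundary. Independent of the package's finite-difference solver.
semi_infinite_fluence <- function(rho, depth, src_depth, mu_a, mu_s, eta = 1.4) {
  d <- 1 / (3 * (mu_a + mu_s))
  mueff <- sqrt(3 * mu_a * (mu_a + mu_s))
  reff <- -1.440 / eta^2 + 0.710 / eta + 0.668 + 0.0636 * eta
  zb <- 2 * d * (1 + reff) / (1 - reff)
  r1 <- sqrt(rho^2 + (depth - src_depth)^2)
  r2 <- sqrt(rho^2 + (depth + src_depth + 2 * zb)^2)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * d)
}

# Homogeneous optical phantom (mu_a = 0.01, mu_s' = 1.0 mm^-1, eta = 1.4).
homog_optics <- function(mu_a = 0.01, mu_s = 1.0) {
  p <- tissue_optics()
  p$mu_a <- mu_a
  p$mu_s_prime <- mu_s
  p
}

# Small layered slab head shared by simulation/tomography/stats tests:
# 96 x 72 x 32 mm at 4 mm voxels, scalp 10 / CSF 2 / gray 8 mm.
test_head <- function() {
  fx("test_head", build_layered_head(c(24, 18, 8), voxel_size = 4,
                                     layer_thicknesses = c(10, 2, 8)))
}

# Default prefrontal array snapped onto the test slab's top surface.
test_layout <- function() {
  fx("test_layout", {
    head <- test_head()
    extent <- head$grid_shape * head$voxel_size
    lay <- default_prefrontal_layout(center = extent[1:2] / 2, z = extent[3])
    project_optodes_to_surface(lay, head, max_snap = 20)
  })
}

test_jacobian <- function() {
  jac <- fx("test_jacobian", compute_jacobian(test_head(), test_layout()))
  # share with run_pipeline's session cache: identical geometry need not be
  # solved twice in one test run
  cache <- getOption("fnirsdot.jacobian_cache", new.env(parent = emptyenv()))
  options(fnirsdot.jacobian_cache = cache)
  if (is.null(cache[[jac$geometry_hash]])) cache[[jac$geometry_hash]] <- jac
  jac
}

# A gray-matter activation centered under the array.
test_activation <- function(...) {
  head <- test_head()
  extent <- head$grid_shape * head$voxel_size
  gray_z <- max(voxel_centers(head, which(as.vector(head$tissue) == 3L))[, 3])
  activation_spec(c(extent[1] / 2, extent[2] / 2, gray_z), ...)
}

# Build an od_series object around a raw (wavelength x channel x time)
# array, bypassing intensity conversion, for inversion/statistic tests.
make_od <- function(arr, fs, layout = NULL, events = NULL, filtered = FALSE) {
  structure(list(od = arr, sampling_rate = fs, layout = layout,
                 events = events,
                 flags = list(normalized = TRUE, motion_corrected = FALSE,
                              filtered = filtered),
                 bad_channels = integer()),
            class = "od_series")
}

# Build an hb_movie directly from chromophore matrices (voxel x time).
make_hb_movie <- function(o2hb, hhb, fs, design = NULL) {
  structure(list(o2hb = o2hb, hhb = hhb, mask = NULL,
                 voxel_index = seq_len(nrow(o2hb)),
                 sampling_rate = fs,
                 events = if (!is.null(design)) design$event_table else NULL,
                 grid_shape = NULL, voxel_size = NULL,
                 geometry_hash = "synthetic"),
            class = "hb_movie")
}

# Amplitude of the fr-Hz component of x (least-squares projection).
sine_amplitude <- function(x, fr, fs, trim = 0.25) {
  n <- length(x)
  idx <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  tt <- idx / fs
  s <- sin(2 * pi * fr * tt); c <- cos(2 * pi * fr * tt)
  2 * sqrt(mean(x[idx] * s)^2 + mean(x[idx] * c)^2)
}
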