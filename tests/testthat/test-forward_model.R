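small_phantom <- function(mu_a = 0.01) {
  build_layered_head(c(30, 20, 12), voxel_size = 4,
                     layer_thicknesses = c(0, 0, 0),
                     properties = homog_optics(mu_a = mu_a))
}

test_that("finite-difference fluence matches the semi-infinite Green's function", {
  head <- build_layered_head(c(60, 40, 30), voxel_size = 2,
                             layer_thicknesses = c(0, 0, 0),
                             properties = homog_optics())
  # source embedded 1 mm (one transport mean free path) below the surface,
  # which is exactly the top voxel-center depth at 2 mm resolution; source
  # and measurement points sit on voxel centers so separations are exact
  src <- c(31, 41, 59)
  fl <- solve_diffusion_cw(head, src, 690)
  for (rho in seq(10, 40, by = 2)) {
    v <- fnirsdot:::point_to_voxel(head, c(31 + rho, 41, 59))
    num <- fl$values[v]
    ana <- semi_infinite_fluence(rho, 1, 1, 0.01, 1.0)
    expect_lt(abs(num / ana - 1), 0.10)
  }
})

test_that("fluence is nonnegative and decays with distance from the source", {
  head <- small_phantom()
  src <- c(60, 40, 46)
  fl <- solve_diffusion_cw(head, src, 690)
  expect_true(all(fl$values >= 0))
  # decay along a lateral ray at source depth
  ray <- vapply(seq(0, 48, by = 4), function(dx) {
    fl$values[fnirsdot:::point_to_voxel(head, src + c(dx, 0, 0))]
  }, numeric(1))
  expect_true(all(diff(ray) < 0))
})

test_that("doubling absorption strictly decreases fluence away from the source", {
  src <- c(60, 40, 46)
  f1 <- solve_diffusion_cw(small_phantom(0.01), src, 690)
  f2 <- solve_diffusion_cw(small_phantom(0.02), src, 690)
  head <- small_phantom()
  pts <- voxel_centers(head)
  far <- sqrt(rowSums(sweep(pts, 2, src)^2)) >= 5
  expect_true(all(f2$values[far] < f1$values[far]))
})

test_that("the discrete operator is linear in the source term", {
  head <- small_phantom()
  op <- diffusion_operator(head, 830)
  v <- fnirsdot:::point_to_voxel(head, c(60, 40, 46))
  red <- match(v, op$inside_idx)
  b <- numeric(length(op$inside_idx)); b[red] <- 1 / op$h^3
  x1 <- fnirsdot:::cg_solve(op$A, b)
  x3 <- fnirsdot:::cg_solve(op$A, 3 * b)
  expect_equal(x3, 3 * x1, tolerance = 1e-8)
})

test_that("source positions outside the grid or tissue are rejected", {
  head <- build_layered_head(c(20, 20, 10), voxel_size = 4,
                             layer_thicknesses = c(10, 2, 8),
                             shape = "hemisphere")
  expect_error(solve_diffusion_cw(head, c(-5, 10, 10), 690), "outside the grid")
  expect_error(solve_diffusion_cw(head, c(2, 2, 38), 690), "not inside tissue")
})

test_that("Jacobian rows are nonnegative with banana-shaped sensitivity", {
  jac <- test_jacobian()
  head <- test_head()
  lay <- test_layout()
  for (wl in c("690", "830")) expect_true(all(jac$J[[wl]] >= 0))

  # row maximum lies laterally between the channel's source and detector
  pts <- voxel_centers(head, jac$voxel_index)
  for (ci in c(1, nrow(lay$channels) %/% 2, nrow(lay$channels))) {
    s <- lay$source_positions[lay$channels$source[ci], ]
    d <- lay$detector_positions[lay$channels$detector[ci], ]
    peak <- pts[which.max(jac$J[["830"]][ci, ]), ]
    for (ax in 1:2) {
      lo <- min(s[ax], d[ax]) - head$voxel_size
      hi <- max(s[ax], d[ax]) + head$voxel_size
      expect_gte(peak[ax], lo)
      expect_lte(peak[ax], hi)
    }
  }
})

test_that("longer channels put more relative sensitivity into gray matter", {
  jac <- test_jacobian()
  head <- test_head()
  dist <- jac$channels$distance
  short_ch <- which.min(dist)
  long_ch <- which(dist > 28)[1]
  gray <- as.vector(head$tissue)[jac$voxel_index] == 3L
  frac <- function(ci) {
    row <- jac$J[["830"]][ci, ]
    sum(row[gray]) / sum(row)
  }
  expect_gt(frac(long_ch), frac(short_ch))
})

test_that("adjoint Jacobian matches brute-force absorption perturbation", {
  head <- test_head()
  lay <- test_layout()
  jac <- test_jacobian()
  mask <- sensitivity_mask(jac)
  wl <- 690
  ci <- which(jac$channels$distance > 25)[1]
  s_idx <- jac$channels$source[ci]
  d_idx <- jac$channels$detector[ci]
  op <- diffusion_operator(head, wl)
  sv <- fnirsdot:::embed_optode(head, op, lay$source_positions[s_idx, ])
  dv <- fnirsdot:::embed_optode(head, op, lay$detector_positions[d_idx, ])
  phi0 <- solve_diffusion_cw(head, voxel_centers(head, sv)[1, ], wl, op = op)
  a0 <- phi0$values[dv]

  # probe gray-matter voxels inside the mask, laterally between the
  # channel's source and detector (where the Rytov linearization and the
  # voxel quadrature are both well resolved)
  pts <- voxel_centers(head, jac$voxel_index)
  s_pos <- lay$source_positions[s_idx, ]
  d_pos <- lay$detector_positions[d_idx, ]
  gray <- as.vector(head$tissue)[jac$voxel_index] == 3L
  between <- pts[, 1] > min(s_pos[1], d_pos[1]) & pts[, 1] < max(s_pos[1], d_pos[1]) &
    abs(pts[, 2] - (s_pos[2] + d_pos[2]) / 2) < 10
  cand <- which(mask$mask & gray & between)
  set.seed(11)
  probes <- sample(cand, 4)
  eps <- 1e-4
  for (pv in probes) {
    full_idx <- jac$voxel_index[pv]
    # a one-voxel mu_a bump enters the finite-difference operator only
    # through its diagonal mass term
    op2 <- diffusion_operator(head, wl)
    red <- match(full_idx, op2$inside_idx)
    op2$A[red, red] <- op2$A[red, red] + eps
    b <- numeric(length(op2$inside_idx))
    b[match(sv, op2$inside_idx)] <- 1 / op2$h^3
    phi1 <- fnirsdot:::cg_solve(op2$A, b)
    a1 <- phi1[match(dv, op2$inside_idx)]
    dod_fd <- -log(a1 / a0)
    dod_adj <- jac$J[[as.character(wl)]][ci, pv] * eps
    expect_lt(abs(dod_fd / dod_adj - 1), 0.05)
  }
})

test_that("reciprocity: swapping source and detector leaves the row unchanged", {
  head <- test_head()
  lay <- test_layout()
  jac <- test_jacobian()
  ci <- 1L
  swapped <- lay
  s <- lay$channels$source[ci]
  d <- lay$channels$detector[ci]
  swapped$source_positions[s, ] <- lay$detector_positions[d, ]
  swapped$detector_positions[d, ] <- lay$source_positions[s, ]
  jac2 <- compute_jacobian(head, swapped)
  ci2 <- which(jac2$channels$source == s & jac2$channels$detector == d)
  r1 <- jac$J[["690"]][ci, ]
  r2 <- jac2$J[["690"]][ci2, ]
  expect_lt(sqrt(sum((r1 - r2)^2)) / sqrt(sum(r1^2)), 1e-6)
})

test_that("zero absorption change produces zero optical density change", {
  jac <- test_jacobian()
  expect_equal(as.numeric(jac$J[["830"]] %*% numeric(ncol(jac$J[["830"]]))),
               numeric(nrow(jac$J[["830"]])))
})

test_that("sensitivity mask thresholds aggregate sensitivity correctly", {
  jac <- test_jacobian()
  m1 <- sensitivity_mask(jac, attenuation_factor = 1)
  agg <- m1$aggregate
  expect_true(all(which(m1$mask) %in% which(agg == max(agg))))
  expect_true(any(m1$mask))

  minf <- sensitivity_mask(jac, attenuation_factor = Inf)
  expect_equal(minf$mask, agg > 0)

  expect_error(sensitivity_mask(jac, attenuation_factor = 0.5), "at least 1")

  # default mask: under the array, not on the far side of the slab
  head <- test_head()
  m <- sensitivity_mask(jac)
  pts <- voxel_centers(head, jac$voxel_index)
  expect_true(any(m$mask))
  expect_equal(sum(m$mask & pts[, 3] < head$voxel_size), 0)
})
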