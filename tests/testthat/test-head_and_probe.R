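test_that("layered slab partitions the grid into the requested tissues", {
  head <- build_layered_head(c(60, 60, 40), voxel_size = 2,
                             layer_thicknesses = c(10, 2, 6))
  counts <- table(factor(head$tissue, levels = 0:4))
  expect_equal(sum(counts), 60 * 60 * 40)
  expect_equal(unname(counts[["0"]]), 0)         # slab has no outside voxels
  expect_equal(unname(counts[["1"]]), 60 * 60 * 5)  # 10 mm of 2 mm voxels
  expect_equal(unname(counts[["2"]]), 60 * 60 * 1)
  expect_equal(unname(counts[["3"]]), 60 * 60 * 3)
  expect_true(counts[["4"]] > 0)
})

test_that("zero-thickness CSF layer produces no CSF voxels", {
  head <- build_layered_head(c(20, 20, 12), voxel_size = 2,
                             layer_thicknesses = c(6, 0, 6))
  expect_equal(sum(head$tissue == 2L), 0)
  expect_true(all(head$tissue %in% c(1L, 3L, 4L)))
})

test_that("grid too small for the requested layers is rejected", {
  expect_error(build_layered_head(c(10, 10, 4), voxel_size = 2,
                                  layer_thicknesses = c(10, 2, 6)),
               "too small")
})

test_that("default gray-matter absorption lies in the physiological range", {
  p <- tissue_optics()
  for (wl in c(690, 830)) {
    mua <- p$mu_a[p$tissue == "gray" & p$wavelength == wl]
    expect_gt(mua, 0.005)
    expect_lt(mua, 0.05)
  }
  # spectral ordering required for unmixing to behave
  e <- extinction_coefficients()
  expect_gt(e["690", "hhb"], e["690", "o2hb"])
  expect_gt(e["830", "o2hb"], e["830", "hhb"])
  expect_lt(kappa(e), 100)
})

test_that("hemispheric model has gray matter interior to scalp and outside label", {
  head <- build_layered_head(c(30, 30, 15), voxel_size = 4,
                             layer_thicknesses = c(10, 2, 8),
                             shape = "hemisphere")
  expect_true(any(head$tissue == 0L))
  expect_true(any(head$tissue == 3L))
  # every gray voxel is deeper (farther from the dome surface) than scalp
  ctr <- c(head$grid_shape[1:2] * head$voxel_size / 2, 0)
  r_of <- function(lab) {
    pts <- voxel_centers(head, which(as.vector(head$tissue) == lab))
    sqrt(rowSums(sweep(pts, 2, ctr)^2))
  }
  expect_lt(max(r_of(3L)), min(r_of(1L)) + head$voxel_size * sqrt(3))
})

test_that("fiducial alignment recovers known transforms exactly", {
  tri <- rbind(c(0, 90, -30), c(-75, 0, -45), c(78, 0, -44))
  t0 <- fiducial_align(tri, tri)
  expect_equal(t0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(t0$translation, c(0, 0, 0), tolerance = 1e-12)

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  moved <- tri %*% t(rot90) + matrix(c(10, 0, 0), 3, 3, byrow = TRUE)
  t1 <- fiducial_align(moved, tri)
  back <- apply_transform(t1, moved)
  expect_lt(max(abs(back - tri)), 1e-9)

  # round trip over random rigid transforms
  set.seed(42)
  for (i in 1:20) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    tr <- rnorm(3, sd = 30)
    moved <- tri %*% t(q) + matrix(tr, 3, 3, byrow = TRUE)
    est <- fiducial_align(moved, tri)
    expect_lt(max(abs(apply_transform(est, moved) - tri)), 1e-9)
  }
})

test_that("jittered congruent triangles align with residual below the jitter", {
  tri <- rbind(c(0, 90, -30), c(-75, 0, -45), c(78, 0, -44))
  set.seed(7)
  for (i in 1:10) {
    jit <- matrix(rnorm(9, sd = 1 / sqrt(3)), 3)   # ~1 mm isotropic jitter
    est <- fiducial_align(tri + jit, tri)
    rms <- sqrt(mean((apply_transform(est, tri + jit) - tri)^2))
    expect_lte(rms, sqrt(mean(jit^2)) + 1e-9)
  }
})

test_that("collinear fiducials are rejected", {
  line <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  tri <- rbind(c(0, 90, -30), c(-75, 0, -45), c(78, 0, -44))
  expect_error(fiducial_align(line, tri), "collinear")
})

test_that("rigid transforms preserve geometry when applied to layouts", {
  lay <- default_prefrontal_layout(center = c(50, 40), z = 30)
  ident <- identity_transform()
  expect_equal(apply_transform(ident, lay)$source_positions,
               lay$source_positions, ignore_attr = TRUE)

  shift <- fnirsdot:::new_rigid_transform(diag(3), c(0, 0, 5))
  lay2 <- apply_transform(shift, lay)
  expect_equal(lay2$source_positions[, 3], lay$source_positions[, 3] + 5)
  expect_equal(lay2$channels, lay$channels)

  # rigidity: all pairwise optode distances unchanged under a random rotation
  set.seed(1)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rt <- fnirsdot:::new_rigid_transform(q, c(3, -2, 8))
  lay3 <- apply_transform(rt, lay)
  all_pts <- rbind(lay$source_positions, lay$detector_positions)
  all_pts3 <- rbind(lay3$source_positions, lay3$detector_positions)
  expect_equal(as.vector(dist(all_pts)), as.vector(dist(all_pts3)),
               tolerance = 1e-9)

  # composition equals sequential application
  comp <- compose_transforms(shift, rt)
  expect_equal(apply_transform(comp, lay)$detector_positions,
               apply_transform(shift, apply_transform(rt, lay))$detector_positions,
               tolerance = 1e-9)
})

test_that("default array has 15+15 optodes, all used by channels", {
  lay <- default_prefrontal_layout(center = c(50, 40), z = 32)
  expect_equal(nrow(lay$source_positions), 15)
  expect_equal(nrow(lay$detector_positions), 15)
  expect_true(all(seq_len(15) %in% lay$channels$source))
  expect_true(all(seq_len(15) %in% lay$channels$detector))
  expect_true(all(lay$channels$distance >= 10 & lay$channels$distance <= 45))
  expect_equal(lay$wavelengths, c(690, 830))
})

test_that("optodes snap to the head surface", {
  head <- test_head()
  extent <- head$grid_shape * head$voxel_size
  h <- head$voxel_size
  ztop <- extent[3] - h / 2   # surface voxel centers
  # optodes laterally aligned with voxel centers, already on the surface
  src <- cbind(seq(extent[1] / 4, 3 * extent[1] / 4, by = 4 * h) + h / 2,
               extent[2] / 2 + h / 2, ztop)
  det <- src + matrix(c(2 * h, 0, 0), nrow(src), 3, byrow = TRUE)
  fid <- rbind(nasion = c(extent[1] / 2, extent[2], 0),
               lpa = c(0, extent[2] / 2, 0), rpa = c(extent[1], extent[2] / 2, 0))
  lay <- probe_layout(src, det, fid, sd_range = c(5, 45))
  snapped <- project_optodes_to_surface(lay, head)
  expect_equal(max(attr(snapped, "displacement")), 0)
  expect_equal(snapped$source_positions, src, ignore_attr = TRUE)

  # optode 3 mm above its surface voxel comes straight down 3 mm
  lay3 <- lay
  lay3$source_positions[, 3] <- ztop + 3
  snapped3 <- project_optodes_to_surface(lay3, head)
  expect_equal(unname(attr(snapped3, "displacement")[paste0("S", seq_len(nrow(src)))]),
               rep(3, nrow(src)), tolerance = 1e-9)
  expect_equal(snapped3$source_positions[, 3], rep(ztop, nrow(src)))

  # far-away optode is a coupling error naming the optode
  far <- lay
  far$detector_positions[2, 3] <- extent[3] + 40
  expect_error(project_optodes_to_surface(far, head), "detector 2")
})

test_that("hemisphere snapping lands every optode on tissue", {
  head <- build_layered_head(c(30, 30, 15), voxel_size = 4,
                             layer_thicknesses = c(10, 2, 8),
                             shape = "hemisphere")
  extent <- head$grid_shape * head$voxel_size
  lay <- default_prefrontal_layout(center = extent[1:2] / 2, z = extent[3],
                                   spacing = 16)
  snapped <- project_optodes_to_surface(lay, head, max_snap = 30)
  lab <- as.vector(head$tissue)
  for (p in seq_len(15)) {
    vs <- fnirsdot:::point_to_voxel(head, snapped$source_positions[p, ])
    vd <- fnirsdot:::point_to_voxel(head, snapped$detector_positions[p, ])
    expect_true(lab[vs] != 0L)
    expect_true(lab[vd] != 0L)
  }
})
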