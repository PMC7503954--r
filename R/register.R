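#' Rigid fiducial alignment (three-point Procrustes)
#'
#' Estimates the least-squares rigid transform (rotation + translation, no
#' scaling) mapping measured fiducials onto template fiducials, using the
#' closed-form Kabsch solution: centroids are removed, the rotation comes
#' from the SVD of the cross-covariance with the determinant constrained to
#' +1, and the translation re-aligns the centroids. With congruent triangles
#' the recovery is exact; with jittered points it is the least-squares fit.
#'
#' @param measured,template 3 x 3 matrices of corresponding points (rows =
#'   nasion, left pre-auricula, right pre-auricula), mm.
#' @return An object of class \code{rigid_transform}: list with a 3 x 3
#'   \code{rotation} (determinant +1) and a length-3 \code{translation}.
#' @export
fiducial_align <- function(measured, template) {
  p <- as.matrix(measured)
  q <- as.matrix(template)
  if (!all(dim(p) == c(3L, 3L)) || !all(dim(q) == c(3L, 3L))) {
    stopf("fiducial_align needs exactly three 3-D point pairs")
  }
  check_noncollinear <- function(x, what) {
    v1 <- x[2L, ] - x[1L, ]
    v2 <- x[3L, ] - x[1L, ]
    n <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
           v1[3L] * v2[1L] - v1[1L] * v2[3L],
           v1[1L] * v2[2L] - v1[2L] * v2[1L])
    scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)), 1)
    if (sqrt(sum(n^2)) < 1e-9 * scale^2) {
      stopf("degenerate geometry: %s fiducials are collinear", what)
    }
  }
  check_noncollinear(p, "measured")
  check_noncollinear(q, "template")

  pc <- colMeans(p)
  qc <- colMeans(q)
  h <- crossprod(sweep(p, 2L, pc), sweep(q, 2L, qc))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- qc - as.vector(rot %*% pc)
  new_rigid_transform(rot, trans)
}

new_rigid_transform <- function(rotation, translation) {
  if (abs(det(rotation) - 1) > 1e-9) {
    stopf("rotation must be proper (determinant +1)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @export
identity_transform <- function() new_rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first} then
#' \code{second}.
#' @param second,first \code{rigid_transform} objects.
#' @export
compose_transforms <- function(second, first) {
  new_rigid_transform(second$rotation %*% first$rotation,
                      as.vector(second$rotation %*% first$translation) +
                        second$translation)
}

#' Apply a rigid transform to points or a probe layout
#'
#' For a \code{probe_layout} all optode and fiducial positions are mapped;
#' the channel list, separations and wavelengths are untouched (rigidity
#' preserves all pairwise distances).
#'
#' @param transform A \code{rigid_transform}.
#' @param x An n x 3 point matrix or a \code{probe_layout}.
#' @return Object of the same type as \code{x}.
#' @export
apply_transform <- function(transform, x) {
  map <- function(pts) {
    sweep(pts %*% t(transform$rotation), 2L, transform$translation, "+")
  }
  if (inherits(x, "probe_layout")) {
    out <- x
    out$source_positions <- map(x$source_positions)
    out$detector_positions <- map(x$detector_positions)
    fid <- map(x$fiducials)
    rownames(fid) <- rownames(x$fiducials)
    out$fiducials <- fid
    return(out)
  }
  map(as.matrix(x))
}

#' Snap optodes onto the head surface
#'
#' Moves every source and detector to the center of the nearest surface
#' voxel of the head model, emulating scalp-optode coupling after
#' co-registration. Optodes farther from the surface than
#' \code{max_snap} mm indicate a mis-registration and raise an error.
#'
#' @param layout A \code{probe_layout} (already co-registered to the head
#'   frame).
#' @param head A \code{head_model}.
#' @param max_snap Maximum allowed displacement in mm (default 15).
#' @return The layout with snapped positions; the per-optode displacements
#'   are attached as attribute \code{"displacement"} (named numeric vector).
#' @export
project_optodes_to_surface <- function(layout, head, max_snap = 15) {
  surf_idx <- surface_voxels(head)
  surf <- voxel_centers(head, surf_idx)
  snap <- function(pts, what) {
    d <- point_distances(as.matrix(pts), surf)
    nearest <- max.col(-d, ties.method = "first")
    disp <- d[cbind(seq_len(nrow(pts)), nearest)]
    too_far <- which(disp > max_snap)
    if (length(too_far)) {
      stopf("poor scalp coupling: %s %s farther than %g mm from the surface (%.1f mm)",
            what, paste(too_far, collapse = ", "), max_snap, max(disp[too_far]))
    }
    list(pos = surf[nearest, , drop = FALSE], disp = disp)
  }
  s <- snap(layout$source_positions, "source")
  d <- snap(layout$detector_positions, "detector")
  out <- layout
  out$source_positions <- s$pos
  out$detector_positions <- d$pos
  # snapping (unlike a rigid transform) changes separations: refresh the
  # channel distances while keeping the channel pairing
  dd <- point_distances(out$source_positions, out$detector_positions)
  out$channels$distance <- dd[cbind(out$channels$source, out$channels$detector)]
  disp <- c(stats::setNames(s$disp, paste0("S", seq_along(s$disp))),
            stats::setNames(d$disp, paste0("D", seq_along(d$disp))))
  attr(out, "displacement") <- disp
  out
}
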