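#' @importFrom Matrix sparseMatrix Cholesky solve crossprod t diag
NULL

# Internal-reflection boundary coefficient A = (1+Reff)/(1-Reff) from the
# tissue/air refractive-index mismatch (Groenhuis-style polynomial fit).
reflection_coefficient <- function(n_rel) {
  reff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + reff) / (1 - reff)
}

#' Assemble the continuous-wave diffusion operator
#'
#' Discretizes \eqn{-\nabla\cdot(D\nabla\Phi) + \mu_a\Phi = q} on the voxel
#' grid with a 7-point finite-difference stencil, harmonic-mean diffusion
#' coefficients at tissue interfaces, and Robin (partial-current) boundary
#' conditions on every face between tissue and non-tissue (or the grid
#' boundary), with the internal-reflection parameter derived from the tissue
#' refractive index against air. The resulting matrix is symmetric positive
#' definite over the tissue voxels.
#'
#' @param head A \code{head_model}.
#' @param wavelength Operating wavelength in nm (must be present in the
#'   property table).
#' @return A list with the sparse system matrix \code{A} (tissue voxels
#'   only), \code{inside_idx} (full-grid linear indices of those voxels),
#'   per-voxel \code{mu_a}, \code{D}, the voxel edge \code{h}, and the
#'   wavelength.
#' @export
diffusion_operator <- function(head, wavelength) {
  gs <- head$grid_shape
  h <- head$voxel_size
  lab <- as.integer(as.vector(head$tissue))
  inside <- lab > 0L
  n <- sum(inside)
  if (n == 0L) stopf("head model contains no tissue voxels")
  red <- integer(length(lab))
  red[inside] <- seq_len(n)

  tissue_names <- c("scalp_skull", "csf", "gray", "white")
  present <- sort(unique(lab[inside]))
  mua_by <- mus_by <- eta_by <- numeric(4L)
  for (t in present) {
    mua_by[t] <- tissue_property(head$properties, tissue_names[t], wavelength, "mu_a")
    mus_by[t] <- tissue_property(head$properties, tissue_names[t], wavelength, "mu_s_prime")
    eta_by[t] <- tissue_property(head$properties, tissue_names[t], wavelength, "refractive_index")
  }
  mua <- mua_by[lab[inside]]
  dcof <- 1 / (3 * (mua + mus_by[lab[inside]]))
  arefl <- reflection_coefficient(eta_by[lab[inside]])

  idx <- array(seq_along(lab), dim = gs)
  ii <- jj <- xx <- vector("list", 8L)
  slot <- 0L
  dvec <- numeric(n)  # diagonal accumulator

  add_diag <- function(r, v) {
    agg <- rowsum(v, r)
    dvec[as.integer(rownames(agg))] <<- dvec[as.integer(rownames(agg))] + agg[, 1L]
  }

  for (axis in 1:3) {
    if (gs[axis] < 2L) {
      a <- integer(0); b <- integer(0)
    } else if (axis == 1L) {
      a <- as.vector(idx[-gs[1L], , , drop = FALSE]); b <- as.vector(idx[-1L, , , drop = FALSE])
    } else if (axis == 2L) {
      a <- as.vector(idx[, -gs[2L], , drop = FALSE]); b <- as.vector(idx[, -1L, , drop = FALSE])
    } else {
      a <- as.vector(idx[, , -gs[3L], drop = FALSE]); b <- as.vector(idx[, , -1L, drop = FALSE])
    }
    both <- inside[a] & inside[b]
    ra <- red[a[both]]; rb <- red[b[both]]
    da <- dcof[ra]; db <- dcof[rb]
    w <- (2 * da * db / (da + db)) / h^2
    slot <- slot + 1L
    ii[[slot]] <- c(ra, rb); jj[[slot]] <- c(rb, ra); xx[[slot]] <- c(-w, -w)
    add_diag(c(ra, rb), c(w, w))

    # faces where exactly one side is tissue: Robin boundary for that side
    onlya <- inside[a] & !inside[b]
    onlyb <- !inside[a] & inside[b]
    rb1 <- c(red[a[onlya]], red[b[onlyb]])
    if (length(rb1)) add_diag(rb1, robin_coef(dcof[rb1], arefl[rb1], h))
    # grid-boundary faces at both ends of this axis
    lo <- switch(axis,
                 as.vector(idx[1L, , , drop = FALSE]),
                 as.vector(idx[, 1L, , drop = FALSE]),
                 as.vector(idx[, , 1L, drop = FALSE]))
    hi <- switch(axis,
                 as.vector(idx[gs[1L], , , drop = FALSE]),
                 as.vector(idx[, gs[2L], , drop = FALSE]),
                 as.vector(idx[, , gs[3L], drop = FALSE]))
    edge <- c(lo[inside[lo]], hi[inside[hi]])
    re <- red[edge]
    if (length(re)) add_diag(re, robin_coef(dcof[re], arefl[re], h))
  }

  slot <- slot + 1L
  ii[[slot]] <- seq_len(n); jj[[slot]] <- seq_len(n); xx[[slot]] <- dvec + mua

  a_mat <- Matrix::sparseMatrix(
    i = unlist(ii[seq_len(slot)]), j = unlist(jj[seq_len(slot)]),
    x = unlist(xx[seq_len(slot)]), dims = c(n, n), symmetric = FALSE
  )
  a_mat <- Matrix::forceSymmetric(a_mat)
  list(A = a_mat, inside_idx = which(inside), mu_a = mua, D = dcof,
       h = h, wavelength = wavelength, grid_shape = gs)
}

# Robin boundary contribution to the diagonal for a face of area h^2 on a
# voxel of volume h^3: outgoing partial current Phi_b/(2A) with the face
# value extrapolated from the voxel center.
robin_coef <- function(dcof, arefl, h) {
  (2 * dcof / h) / (1 + 4 * arefl * dcof / h) / h
}

# Jacobi-preconditioned conjugate gradient for the SPD diffusion system.
cg_solve <- function(a_mat, b, tol = 1e-10, maxit = 10000L) {
  minv <- 1 / Matrix::diag(a_mat)
  x <- numeric(length(b))
  r <- b
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    ap <- as.numeric(a_mat %*% p)
    alpha <- rz / sum(p * ap)
    x <- x + alpha * p
    r <- r - alpha * ap
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stopf("diffusion solve did not converge: relative residual %.3e after %d iterations",
        sqrt(sum(r^2)) / bnorm, maxit)
}

#' Solve the continuous-wave photon diffusion equation
#'
#' Computes the fluence field of an isotropic unit point source inside the
#' head, \eqn{-\nabla\cdot(D\nabla\Phi) + \mu_a\Phi = \delta(r - r_s)}, with
#' Robin boundaries. Small grids use a sparse Cholesky factorization; large
#' ones a Jacobi-preconditioned conjugate-gradient solve to relative
#' residual \code{tol}.
#'
#' @param head A \code{head_model}.
#' @param source Length-3 source position in mm (must lie in tissue).
#' @param wavelength Wavelength in nm.
#' @param op Optional pre-assembled operator from
#'   \code{\link{diffusion_operator}} (reused across sources).
#' @param method \code{"auto"}, \code{"direct"} or \code{"cg"}.
#' @param tol Relative residual tolerance for the iterative solve.
#' @return An object of class \code{fluence_field}: list with \code{values}
#'   (3-D array, zero outside tissue, units mm^-2 per unit source power),
#'   \code{source_location} and \code{wavelength}.
#' @export
solve_diffusion_cw <- function(head, source, wavelength, op = NULL,
                               method = c("auto", "direct", "cg"),
                               tol = 1e-10) {
  method <- match.arg(method)
  if (is.null(op)) op <- diffusion_operator(head, wavelength)
  v <- point_to_voxel(head, source)
  if (is.na(v)) stopf("source position (%g, %g, %g) lies outside the grid",
                      source[1L], source[2L], source[3L])
  red <- match(v, op$inside_idx)
  if (is.na(red)) stopf("source position (%g, %g, %g) is not inside tissue",
                        source[1L], source[2L], source[3L])
  n <- length(op$inside_idx)
  b <- numeric(n)
  b[red] <- 1 / op$h^3
  # Jacobi-preconditioned CG converges in a few hundred iterations for this
  # well-conditioned (absorption-shifted) system and beats sparse Cholesky
  # on 3-D grids of any useful size.
  if (method == "auto") method <- "cg"
  phi <- if (method == "direct") {
    fac <- attr(op, "cholesky")
    if (is.null(fac)) fac <- Matrix::Cholesky(op$A, LDL = FALSE, perm = TRUE)
    as.numeric(Matrix::solve(fac, b, system = "A"))
  } else {
    cg_solve(op$A, b, tol = tol)
  }
  phi[phi < 0] <- 0  # clip solver roundoff; the continuum solution is nonnegative
  vals <- array(0, dim = op$grid_shape)
  vals[op$inside_idx] <- phi
  structure(list(values = vals, source_location = as.numeric(source),
                 wavelength = wavelength),
            class = "fluence_field")
}

# Embedding point for an optode: one transport mean free path (1/mu_s')
# below its surface voxel, along the local inward normal. Returns the
# full-grid linear index of the embedding voxel.
embed_optode <- function(head, op, position) {
  v <- point_to_voxel(head, position)
  if (is.na(v)) stopf("optode position outside the grid")
  gs <- head$grid_shape
  lab <- as.vector(head$tissue)
  idx0 <- v - 1L
  ijk <- c(idx0 %% gs[1L], (idx0 %/% gs[1L]) %% gs[2L], idx0 %/% (gs[1L] * gs[2L])) + 1L
  # outward normal: mean direction of non-tissue (or out-of-grid) face neighbors
  normal <- c(0, 0, 0)
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[axis] <- nb[axis] + s
      outside <- nb[axis] < 1L || nb[axis] > gs[axis]
      if (!outside) {
        lin <- 1L + (nb[1L] - 1L) + gs[1L] * ((nb[2L] - 1L) + gs[2L] * (nb[3L] - 1L))
        outside <- lab[lin] == 0L
      }
      if (outside) normal[axis] <- normal[axis] + s
    }
  }
  if (all(normal == 0)) return(v)  # already interior: use as is
  normal <- normal / sqrt(sum(normal^2))
  red <- match(v, op$inside_idx)
  mus_eff <- 1 / (3 * op$D[red]) - op$mu_a[red]
  target <- voxel_centers(head, v)[1L, ] - normal * (1 / mus_eff)
  v2 <- point_to_voxel(head, target)
  if (!is.na(v2) && as.vector(head$tissue)[v2] > 0L) v2 else v
}
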