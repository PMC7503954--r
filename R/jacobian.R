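#' Channel-by-voxel sensitivity (Jacobian) matrices
#'
#' Builds, for each wavelength, the Rytov/adjoint sensitivity of channel
#' optical density to voxel absorption changes:
#' \deqn{J[ch, v] = \Phi_s(v)\,\Phi_d(v)\,V_{vox} / A_{sd}}
#' where \eqn{\Phi_s} and \eqn{\Phi_d} are diffusion fluences from the
#' channel's source and (by reciprocity) its detector, and \eqn{A_{sd}} the
#' unperturbed channel amplitude. Rows map \eqn{\Delta\mu_a} (mm^-1) to
#' optical-density change (natural log, dimensionless). Each optode is
#' embedded one transport mean free path below its surface position before
#' solving; detector fluences are obtained by solving with the detector as
#' a source (reciprocity), halving the solve count.
#'
#' @param head A \code{head_model}.
#' @param layout A \code{probe_layout} whose optodes lie on the head
#'   surface (see \code{\link{project_optodes_to_surface}}).
#' @param wavelengths Wavelengths to compute (default: the layout's).
#' @param tol Relative residual tolerance of the diffusion solves.
#' @return Object of class \code{jacobian}: list with \code{J} (named list
#'   of channel x voxel matrices, one per wavelength), \code{voxel_index}
#'   (full-grid linear indices of the tissue voxels, i.e. the columns),
#'   \code{amplitudes} (channel x wavelength), \code{channels},
#'   \code{voxel_volume}, \code{geometry_hash}, \code{grid_shape} and
#'   \code{voxel_size}.
#' @export
compute_jacobian <- function(head, layout, wavelengths = layout$wavelengths,
                             tol = 1e-10) {
  nch <- nrow(layout$channels)
  jmats <- list()
  amps <- matrix(NA_real_, nch, length(wavelengths),
                 dimnames = list(NULL, as.character(wavelengths)))
  for (wl in wavelengths) {
    op <- diffusion_operator(head, wl)
    src_vox <- vapply(seq_len(nrow(layout$source_positions)), function(i) {
      embed_optode(head, op, layout$source_positions[i, ])
    }, integer(1))
    det_vox <- vapply(seq_len(nrow(layout$detector_positions)), function(i) {
      embed_optode(head, op, layout$detector_positions[i, ])
    }, integer(1))
    used_src <- sort(unique(layout$channels$source))
    used_det <- sort(unique(layout$channels$detector))
    fl_src <- lapply(used_src, function(i) {
      solve_diffusion_cw(head, voxel_centers(head, src_vox[i])[1L, ], wl,
                         op = op, tol = tol)$values[op$inside_idx]
    })
    names(fl_src) <- used_src
    fl_det <- lapply(used_det, function(i) {
      solve_diffusion_cw(head, voxel_centers(head, det_vox[i])[1L, ], wl,
                         op = op, tol = tol)$values[op$inside_idx]
    })
    names(fl_det) <- used_det

    jm <- matrix(0, nch, length(op$inside_idx))
    vol <- head$voxel_size^3
    red_det <- match(det_vox, op$inside_idx)
    for (c_i in seq_len(nch)) {
      s <- layout$channels$source[c_i]
      d <- layout$channels$detector[c_i]
      phis <- fl_src[[as.character(s)]]
      phid <- fl_det[[as.character(d)]]
      a_sd <- phis[red_det[d]]
      if (!is.finite(a_sd) || a_sd <= 0) {
        stopf("channel %d (S%d-D%d) has nonpositive amplitude", c_i, s, d)
      }
      jm[c_i, ] <- phis * phid * vol / a_sd
      amps[c_i, as.character(wl)] <- a_sd
    }
    jmats[[as.character(wl)]] <- jm
  }
  structure(
    list(J = jmats, voxel_index = diffusion_operator_index(head),
         amplitudes = amps, channels = layout$channels,
         voxel_volume = head$voxel_size^3,
         geometry_hash = geometry_hash(head, layout),
         grid_shape = head$grid_shape, voxel_size = head$voxel_size),
    class = "jacobian"
  )
}

# Tissue-voxel linear indices (Jacobian column order) without reassembly.
diffusion_operator_index <- function(head) which(as.vector(head$tissue) > 0L)

#' Geometry fingerprint tying derived artifacts to a head/layout pair
#' @param head A \code{head_model}.
#' @param layout A \code{probe_layout}.
#' @return Character hash.
#' @export
geometry_hash <- function(head, layout) {
  object_hash(list(
    gs = head$grid_shape, h = head$voxel_size,
    tissue = as.integer(c(table(factor(head$tissue, levels = 0:4)))),
    src = round(layout$source_positions, 6), det = round(layout$detector_positions, 6),
    ch = layout$channels[, c("source", "detector")]
  ))
}

#' Sensitivity mask of the optical array
#'
#' Aggregates the absolute Jacobian over channels and wavelengths into a
#' per-voxel sensitivity and retains voxels within a given attenuation
#' factor of the most sensitive voxel (default 1000x), the region where
#' tomographic values are reportable.
#'
#' @param jac A \code{jacobian}.
#' @param attenuation_factor Retain voxels with aggregate sensitivity at
#'   least \code{max / attenuation_factor}; must be >= 1 (1 keeps only the
#'   argmax voxel).
#' @return Object of class \code{sensitivity_mask}: list with logical
#'   \code{mask} over the Jacobian's voxels, \code{aggregate} sensitivity,
#'   \code{voxel_index}, and \code{attenuation_factor}.
#' @export
sensitivity_mask <- function(jac, attenuation_factor = 1000) {
  if (!length(jac$J)) stopf("empty Jacobian")
  if (attenuation_factor < 1) {
    stopf("attenuation_factor must be at least 1")
  }
  agg <- Reduce(`+`, lapply(jac$J, function(m) colSums(abs(m)))) / length(jac$J)
  mask <- agg >= max(agg) / attenuation_factor
  structure(list(mask = mask, aggregate = agg, voxel_index = jac$voxel_index,
                 attenuation_factor = attenuation_factor,
                 geometry_hash = jac$geometry_hash,
                 grid_shape = jac$grid_shape, voxel_size = jac$voxel_size),
            class = "sensitivity_mask")
}

#' @export
print.jacobian <- function(x, ...) {
  cat(sprintf("<jacobian> %d channels x %d voxels at %s nm (geometry %s)\n",
              nrow(x$J[[1L]]), ncol(x$J[[1L]]),
              paste(names(x$J), collapse = "/"), x$geometry_hash))
  invisible(x)
}
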