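#' Tomographic inversion of channel optical density
#'
#' Minimum-norm Tikhonov reconstruction of voxel absorption changes from
#' channel OD, per wavelength and time sample:
#' \deqn{x = J^T (J J^T + \alpha\,\mathrm{tr}(J J^T)/n_{ch}\, I)^{-1} y}
#' The dense factorization is computed once per wavelength and reused
#' across all time samples. Channels marked bad are excluded (their
#' Jacobian rows dropped); reconstruction is restricted to the sensitivity
#' mask, with voxels outside the mask identically zero.
#'
#' @param jac A \code{jacobian}.
#' @param od An \code{od_series} (typically motion-corrected, band-pass
#'   filtered and decimated).
#' @param alpha Dimensionless regularization weight (default 0.01).
#' @param mask A \code{sensitivity_mask}; computed from \code{jac} at the
#'   default 1000x attenuation when omitted.
#' @return Object of class \code{absorption_movie}: \code{delta_mu_a}
#'   (named list of masked-voxel x time matrices per wavelength, mm^-1),
#'   \code{mask}, \code{voxel_index} (full-grid indices of masked voxels),
#'   \code{alpha}, \code{sampling_rate}.
#' @export
invert_od <- function(jac, od, alpha = 0.01, mask = NULL) {
  stopifnot(inherits(jac, "jacobian"), inherits(od, "od_series"))
  if (alpha <= 0) stopf("alpha must be positive")
  if (is.null(mask)) mask <- sensitivity_mask(jac)
  if (mask$geometry_hash != jac$geometry_hash) {
    stopf("sensitivity mask geometry does not match the Jacobian")
  }
  keep_ch <- setdiff(seq_len(nrow(jac$channels)), od$bad_channels)
  if (!length(keep_ch)) stopf("all channels are marked bad")
  wls <- names(jac$J)
  out <- list()
  for (wl in wls) {
    jm <- jac$J[[wl]][keep_ch, mask$mask, drop = FALSE]
    nch <- nrow(jm)
    jjt <- tcrossprod(jm)
    lambda <- alpha * sum(diag(jjt)) / nch
    kern <- backsolve(chol(jjt + diag(lambda, nch)),
                      diag(nch), transpose = TRUE)
    # x = J^T (R^T R)^{-1} y computed as (J^T R^{-1}) (R^{-T} y)
    y <- matrix(od$od[match(wl, dimnames(od$od)[[1L]]), keep_ch, ,
                      drop = FALSE],
                length(keep_ch), dim(od$od)[3L])
    out[[wl]] <- crossprod(kern %*% jm, kern %*% y)
  }
  structure(list(delta_mu_a = out, mask = mask,
                 voxel_index = jac$voxel_index[mask$mask],
                 alpha = alpha, sampling_rate = od$sampling_rate,
                 events = od$events, grid_shape = jac$grid_shape,
                 voxel_size = jac$voxel_size,
                 geometry_hash = jac$geometry_hash),
            class = "absorption_movie")
}

#' Spectral unmixing of absorption changes into hemoglobin
#'
#' Inverts the modified Beer-Lambert spectral system per voxel and time
#' sample, \eqn{[\Delta\mu_a(690); \Delta\mu_a(830)] = E\,[\Delta O_2Hb;
#' \Delta HHb]}, with \eqn{E} the pinned extinction matrix.
#'
#' @param movie An \code{absorption_movie} with both wavelengths.
#' @param extinction 2x2 extinction matrix, mm^-1 per uM.
#' @return Object of class \code{hb_movie}: \code{o2hb}, \code{hhb}
#'   (masked-voxel x time, uM) plus the movie's geometry fields.
#' @export
unmix <- function(movie, extinction = extinction_coefficients()) {
  stopifnot(inherits(movie, "absorption_movie"))
  if (length(movie$delta_mu_a) != 2L) stopf("both wavelengths are required")
  if (abs(det(extinction)) < 1e-12) stopf("singular extinction matrix")
  einv <- solve(extinction)
  wl_order <- rownames(extinction)
  if (!all(wl_order %in% names(movie$delta_mu_a))) {
    stopf("movie wavelengths (%s) do not match the extinction table (%s)",
          paste(names(movie$delta_mu_a), collapse = ", "),
          paste(wl_order, collapse = ", "))
  }
  m1 <- movie$delta_mu_a[[wl_order[1L]]]
  m2 <- movie$delta_mu_a[[wl_order[2L]]]
  structure(list(o2hb = einv[1L, 1L] * m1 + einv[1L, 2L] * m2,
                 hhb = einv[2L, 1L] * m1 + einv[2L, 2L] * m2,
                 mask = movie$mask, voxel_index = movie$voxel_index,
                 sampling_rate = movie$sampling_rate, events = movie$events,
                 grid_shape = movie$grid_shape,
                 voxel_size = movie$voxel_size,
                 geometry_hash = movie$geometry_hash),
            class = "hb_movie")
}
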