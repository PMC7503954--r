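#' Construct a probe layout
#'
#' Bundles source and detector positions, fiducial landmarks and the derived
#' channel list. Channels are all source-detector pairs whose separation
#' falls inside \code{sd_range}; short separations carry mostly scalp
#' signal and very long ones carry too little light, so both are excluded.
#'
#' @param source_positions,detector_positions Numeric matrices (n x 3), mm.
#' @param fiducials Named list or 3 x 3 matrix with rows \code{nasion},
#'   \code{lpa}, \code{rpa} (left/right pre-auricular points), mm.
#' @param wavelengths Pair of operating wavelengths in nm.
#' @param sd_range Admissible source-detector distance range in mm.
#' @return An object of class \code{probe_layout} with a \code{channels}
#'   data frame (\code{source}, \code{detector}, \code{distance}).
#' @export
probe_layout <- function(source_positions, detector_positions, fiducials,
                         wavelengths = c(690, 830), sd_range = c(10, 45)) {
  src <- as.matrix(source_positions)
  det <- as.matrix(detector_positions)
  if (ncol(src) != 3L || ncol(det) != 3L) stopf("positions must be n x 3 matrices")
  fid <- if (is.matrix(fiducials)) fiducials else do.call(rbind, fiducials)
  if (!all(dim(fid) == c(3L, 3L))) {
    stopf("exactly three fiducials (nasion, lpa, rpa) required")
  }
  if (is.null(rownames(fid))) rownames(fid) <- c("nasion", "lpa", "rpa")
  if (any(wavelengths <= 0) || length(wavelengths) != 2L) {
    stopf("wavelengths must be two positive values")
  }
  d <- point_distances(src, det)
  keep <- which(d >= sd_range[1L] & d <= sd_range[2L], arr.ind = TRUE)
  if (nrow(keep) == 0L) stopf("no source-detector pair within %g-%g mm", sd_range[1L], sd_range[2L])
  channels <- data.frame(source = keep[, 1L], detector = keep[, 2L],
                         distance = d[keep])
  channels <- channels[order(channels$source, channels$detector), , drop = FALSE]
  rownames(channels) <- NULL
  structure(
    list(source_positions = src, detector_positions = det, fiducials = fid,
         channels = channels, wavelengths = wavelengths, sd_range = sd_range),
    class = "probe_layout"
  )
}

#' Default prefrontal optode array
#'
#' A 15-source, 15-detector interleaved rectangular array (two offset 5 x 3
#' lattices) laid flat in a z = const plane, emulating a prefrontal
#' high-density probe driven at 690/830 nm. The nominal 16th source of the
#' hardware cycle is not positioned, leaving 15 active sources.
#'
#' @param center Array center (x, y) in mm.
#' @param z Plane height in mm (place at the head surface, e.g. the top of a
#'   slab model).
#' @param spacing Lattice pitch in mm; nearest source-detector separation is
#'   \code{spacing / sqrt(2)}.
#' @param sd_range Admissible channel separation range, mm.
#' @return A \code{probe_layout}.
#' @export
default_prefrontal_layout <- function(center = c(0, 0), z = 0, spacing = 20,
                                      sd_range = c(10, 45)) {
  gx <- (seq_len(5L) - 3L) * spacing
  gy <- (seq_len(3L) - 2L) * spacing
  src <- as.matrix(expand.grid(x = gx + center[1L], y = gy + center[2L]))
  det <- cbind(src[, 1L] + spacing / 2, src[, 2L] + spacing / 2)
  src <- cbind(src, z)
  det <- cbind(det, z)
  fid <- rbind(
    nasion = c(center[1L], center[2L] + 90, z - 40),
    lpa = c(center[1L] - 80, center[2L], z - 60),
    rpa = c(center[1L] + 80, center[2L], z - 60)
  )
  probe_layout(src, det, fid, sd_range = sd_range)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d sources, %d detectors, %d channels (%g-%g mm), %g/%g nm\n",
              nrow(x$source_positions), nrow(x$detector_positions),
              nrow(x$channels), min(x$channels$distance), max(x$channels$distance),
              x$wavelengths[1L], x$wavelengths[2L]))
  invisible(x)
}
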