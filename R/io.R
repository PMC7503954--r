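#' Write / read an optical recording as a plain-text bundle
#'
#' The container is a directory holding \code{meta.json} (sampling rate,
#' wavelengths, probe geometry with named fiducials, channel list, events)
#' and one full-precision CSV intensity table per wavelength (channels as
#' rows, samples as columns). The round trip is lossless: intensities are
#' written with 17 significant digits, so arrays read back bit-identically.
#'
#' @param rec An \code{optical_recording}.
#' @param path Directory to create/overwrite.
#' @rdname recording_io
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "optical_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lay <- rec$layout
  meta <- list(
    format = "fnirsdot-recording", version = 1L,
    sampling_rate = rec$sampling_rate,
    wavelengths = as.numeric(dimnames(rec$intensities)[[1L]]),
    n_channels = dim(rec$intensities)[2L],
    n_samples = dim(rec$intensities)[3L],
    probe = list(
      source_positions = unname(lay$source_positions),
      detector_positions = unname(lay$detector_positions),
      fiducials = stats::setNames(
        lapply(seq_len(nrow(lay$fiducials)), function(i) unname(lay$fiducials[i, ])),
        rownames(lay$fiducials)),
      channels = lay$channels[, c("source", "detector")],
      sd_range = lay$sd_range
    ),
    events = if (!is.null(rec$events)) list(
      table = rec$events$events,
      total_duration = rec$events$total_duration
    ) else NULL
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (w in seq_len(dim(rec$intensities)[1L])) {
    wl <- dimnames(rec$intensities)[[1L]][w]
    m <- matrix(rec$intensities[w, , , drop = FALSE],
                dim(rec$intensities)[2L], dim(rec$intensities)[3L])
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(txt, file.path(path, sprintf("intensity_%s.csv", wl)))
  }
  invisible(path)
}

#' @param path Directory written by \code{write_recording}.
#' @rdname recording_io
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("not a recording bundle: missing %s", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  required <- c("sampling_rate", "wavelengths", "probe")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stopf("recording bundle lacks field(s): %s", paste(missing, collapse = ", "))
  }
  wls <- meta$wavelengths
  if (!all(c(690, 830) %in% wls)) {
    stopf("recording lacks wavelength entries for %s nm",
          paste(setdiff(c(690, 830), wls), collapse = ", "))
  }
  fid <- do.call(rbind, meta$probe$fiducials)
  layout <- probe_layout(meta$probe$source_positions,
                         meta$probe$detector_positions,
                         fid, wavelengths = wls,
                         sd_range = meta$probe$sd_range)
  # restore the stored channel list verbatim (e.g. surface snapping can
  # leave separations outside the nominal range used for rebuilding)
  ch <- as.data.frame(meta$probe$channels)
  dd <- point_distances(layout$source_positions, layout$detector_positions)
  ch$distance <- dd[cbind(ch$source, ch$detector)]
  layout$channels <- ch
  events <- NULL
  if (!is.null(meta$events)) {
    events <- event_table(meta$events$table, meta$events$total_duration,
                          meta$sampling_rate)
  }
  intens <- array(0, dim = c(length(wls), meta$n_channels, meta$n_samples),
                  dimnames = list(as.character(wls), NULL, NULL))
  for (w in seq_along(wls)) {
    f <- file.path(path, sprintf("intensity_%s.csv", wls[w]))
    if (!file.exists(f)) stopf("missing intensity table %s", f)
    rows <- strsplit(readLines(f), ",", fixed = TRUE)
    intens[w, , ] <- t(vapply(rows, as.numeric, numeric(meta$n_samples)))
  }
  optical_recording(intens, meta$sampling_rate, layout, events)
}

#' Export a voxel map to NIfTI
#'
#' Scatters per-voxel values back onto the full grid (zero elsewhere) and
#' writes a NIfTI-1 volume with the model's voxel size.
#'
#' @param values Numeric vector over \code{voxel_index}.
#' @param voxel_index Full-grid linear indices.
#' @param head The \code{head_model} defining the grid.
#' @param path Output file (\code{.nii}).
#' @export
write_nifti_map <- function(values, voxel_index, head, path) {
  vol <- array(0, dim = head$grid_shape)
  vol[voxel_index] <- values
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(head$voxel_size, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a thresholded statistical map bundle
#'
#' Writes one NIfTI t-score volume per chromophore, a JSON sidecar
#' (method, threshold, sidedness, geometry hash) and a CSV of
#' suprathreshold voxel coordinates.
#'
#' @param map A \code{stat_map}.
#' @param head The \code{head_model}.
#' @param prefix Output path prefix.
#' @param config_hash Optional provenance hash recorded in the sidecar.
#' @export
export_stat_map <- function(map, head, prefix, config_hash = NULL) {
  paths <- character()
  for (chrom in colnames(map$t_score)) {
    p <- sprintf("%s_t_%s.nii", prefix, chrom)
    write_nifti_map(map$t_score[, chrom], map$voxel_index, head, p)
    paths <- c(paths, p)
  }
  sidecar <- list(method = map$method, threshold = map$threshold,
                  two_sided = map$two_sided,
                  n_suprathreshold = colSums(map$suprathreshold),
                  config_hash = config_hash)
  jsonlite::write_json(sidecar, paste0(prefix, "_map.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  sel <- which(rowSums(map$suprathreshold) > 0)
  coords <- voxel_centers(head, map$voxel_index[sel])
  df <- data.frame(x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                   map$t_score[sel, , drop = FALSE])
  utils::write.csv(df, paste0(prefix, "_suprathreshold.csv"), row.names = FALSE)
  invisible(c(paths, paste0(prefix, "_map.json"),
              paste0(prefix, "_suprathreshold.csv")))
}
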