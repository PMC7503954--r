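#' Build a layered voxel head model
#'
#' Constructs a regular-grid head model with tissue layers ordered from the
#' outer surface inward: scalp/skull, cerebrospinal fluid, gray matter, and
#' white matter filling the remainder. Two geometries are supported: a
#' rectangular \code{"slab"} whose outer surface is the top (maximum-z) face,
#' and a \code{"hemisphere"} (dome resting on the z = 0 plane) for more
#' head-like end-to-end runs.
#'
#' Coordinates are right-handed millimetres; the grid origin is the corner
#' of voxel (1,1,1) and a voxel's position is its center, so voxel
#' \code{(i,j,k)} sits at \code{(i-0.5, j-0.5, k-0.5) * voxel_size}.
#'
#' @param grid_shape Integer triple: number of voxels along x, y, z.
#' @param voxel_size Isotropic voxel edge length in mm (default 2).
#' @param layer_thicknesses Named or positional numeric vector of the
#'   scalp/skull, CSF and gray-matter thicknesses in mm, measured inward
#'   from the surface; white matter fills whatever remains. A zero
#'   thickness removes that layer.
#' @param properties Optical property table as returned by
#'   \code{\link{tissue_optics}}; may be overridden, e.g. to build a
#'   homogeneous phantom.
#' @param shape \code{"slab"} or \code{"hemisphere"}.
#' @param radius Dome radius in mm for the hemispheric model; defaults to
#'   the largest dome fitting the grid.
#' @return An object of class \code{head_model}: a list with
#'   \code{grid_shape}, \code{voxel_size}, \code{tissue} (3-D integer array,
#'   0 = outside, 1 = scalp/skull, 2 = CSF, 3 = gray, 4 = white),
#'   \code{properties}, and \code{shape}.
#' @examples
#' head <- build_layered_head(c(30, 30, 20), voxel_size = 2)
#' table(head$tissue)
#' @export
build_layered_head <- function(grid_shape,
                               voxel_size = 2,
                               layer_thicknesses = c(scalp_skull = 10,
                                                     csf = 2,
                                                     gray = 6),
                               properties = tissue_optics(),
                               shape = c("slab", "hemisphere"),
                               radius = NULL) {
  shape <- match.arg(shape)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stopf("grid_shape must be three positive integers")
  }
  if (voxel_size <= 0) stopf("voxel_size must be positive")
  lt <- as.numeric(layer_thicknesses)
  if (length(lt) != 3L || any(lt < 0)) {
    stopf("layer_thicknesses must give nonnegative scalp/skull, CSF and gray thicknesses")
  }
  extent <- grid_shape * voxel_size
  cum <- cumsum(lt)

  if (shape == "slab") {
    if (cum[3L] >= extent[3L]) {
      stopf("grid too small: layers need more than the %g mm z-extent", extent[3L])
    }
    # depth of each voxel center below the top (z = extent[3]) surface
    zc <- (seq_len(grid_shape[3L]) - 0.5) * voxel_size
    depth <- extent[3L] - zc
    layer_of <- function(d) {
      ifelse(d < cum[1L], 1L, ifelse(d < cum[2L], 2L, ifelse(d < cum[3L], 3L, 4L)))
    }
    lab_z <- layer_of(depth)
    tissue <- array(rep(lab_z, each = grid_shape[1L] * grid_shape[2L]),
                    dim = grid_shape)
  } else {
    if (is.null(radius)) {
      radius <- min(extent[1L] / 2, extent[2L] / 2, extent[3L])
    }
    if (cum[3L] >= radius) {
      stopf("grid too small: layers need more than the %g mm dome radius", radius)
    }
    ctr <- c(extent[1L] / 2, extent[2L] / 2, 0)
    cx <- (seq_len(grid_shape[1L]) - 0.5) * voxel_size - ctr[1L]
    cy <- (seq_len(grid_shape[2L]) - 0.5) * voxel_size - ctr[2L]
    cz <- (seq_len(grid_shape[3L]) - 0.5) * voxel_size
    r2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    r <- sqrt(r2)
    depth <- radius - r
    tissue <- array(0L, dim = grid_shape)
    inside <- depth >= 0
    tissue[inside & depth < cum[1L]] <- 1L
    tissue[inside & depth >= cum[1L] & depth < cum[2L]] <- 2L
    tissue[inside & depth >= cum[2L] & depth < cum[3L]] <- 3L
    tissue[inside & depth >= cum[3L]] <- 4L
  }

  model <- structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         tissue = tissue, properties = properties, shape = shape,
         layer_thicknesses = lt, radius = if (shape == "hemisphere") radius else NULL),
    class = "head_model"
  )
  validate_head_model(model)
  model
}

validate_head_model <- function(model) {
  props <- model$properties
  present <- sort(setdiff(unique(as.vector(model$tissue)), 0L))
  names_of <- c("scalp_skull", "csf", "gray", "white")
  for (lab in present) {
    for (wl in c(690, 830)) {
      mua <- tissue_property(props, names_of[lab], wl, "mu_a")
      mus <- tissue_property(props, names_of[lab], wl, "mu_s_prime")
      if (mua <= 0 || mus <= 0) {
        stopf("optical coefficients must be strictly positive (%s at %d nm)",
              names_of[lab], wl)
      }
    }
  }
  invisible(model)
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %s, %d x %d x %d voxels at %g mm\n",
              x$shape, x$grid_shape[1L], x$grid_shape[2L], x$grid_shape[3L],
              x$voxel_size))
  tb <- table(factor(x$tissue, levels = 0:4,
                     labels = c("outside", "scalp/skull", "CSF", "gray", "white")))
  print(tb)
  invisible(x)
}

#' Voxel-center coordinates
#'
#' Positions (n x 3, mm) of the voxels with the given full-grid linear
#' indices; all voxels when \code{idx} is NULL.
#'
#' @param head A \code{head_model}.
#' @param idx Linear voxel indices (1-based, column-major).
#' @export
voxel_centers <- function(head, idx = NULL) {
  gs <- head$grid_shape
  if (is.null(idx)) idx <- seq_len(prod(gs))
  idx0 <- idx - 1L
  i <- idx0 %% gs[1L]
  j <- (idx0 %/% gs[1L]) %% gs[2L]
  k <- idx0 %/% (gs[1L] * gs[2L])
  cbind((i + 0.5) * head$voxel_size,
        (j + 0.5) * head$voxel_size,
        (k + 0.5) * head$voxel_size)
}

# Linear voxel index containing a point, or NA when outside the grid box.
point_to_voxel <- function(head, p) {
  gs <- head$grid_shape
  ijk <- floor(p / head$voxel_size)
  ijk <- pmin(pmax(ijk, 0), gs - 1L)  # clamp points on the boundary face
  if (any(p < 0) || any(p > gs * head$voxel_size)) return(NA_integer_)
  as.integer(1L + ijk[1L] + gs[1L] * (ijk[2L] + gs[2L] * ijk[3L]))
}

# Linear indices of surface voxels: tissue voxels with at least one
# face-neighbor that is outside tissue or outside the grid.
surface_voxels <- function(head) {
  gs <- head$grid_shape
  inside <- head$tissue > 0L
  pad <- array(FALSE, dim = gs + 2L)
  pad[2:(gs[1L] + 1L), 2:(gs[2L] + 1L), 3:(gs[3L] + 2L) - 1L] <- inside
  core <- pad[2:(gs[1L] + 1L), 2:(gs[2L] + 1L), 2:(gs[3L] + 1L)]
  nb_all <- pad[1:gs[1L], 2:(gs[2L] + 1L), 2:(gs[3L] + 1L)] &
    pad[3:(gs[1L] + 2L), 2:(gs[2L] + 1L), 2:(gs[3L] + 1L)] &
    pad[2:(gs[1L] + 1L), 1:gs[2L], 2:(gs[3L] + 1L)] &
    pad[2:(gs[1L] + 1L), 3:(gs[2L] + 2L), 2:(gs[3L] + 1L)] &
    pad[2:(gs[1L] + 1L), 2:(gs[2L] + 1L), 1:gs[3L]] &
    pad[2:(gs[1L] + 1L), 2:(gs[2L] + 1L), 3:(gs[3L] + 2L)]
  which(core & !nb_all)
}
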