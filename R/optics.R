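#' Baseline tissue optical properties
#'
#' Pinned per-tissue absorption, reduced scattering and refractive index at
#' the two operating wavelengths (690 and 830 nm). Values follow published
#' compilations of adult head optical properties commonly used for
#' continuous-wave diffuse optical tomography; the CSF reduced scattering is
#' the diffusion-adjusted effective value customary in diffusion-equation
#' solvers (true CSF scattering is too low for the diffusion approximation).
#'
#' @return A data frame with columns \code{tissue} (one of
#'   \code{"scalp_skull"}, \code{"csf"}, \code{"gray"}, \code{"white"}),
#'   \code{wavelength} (nm), \code{mu_a} (absorption, mm^-1),
#'   \code{mu_s_prime} (reduced scattering, mm^-1) and
#'   \code{refractive_index}.
#' @export
tissue_optics <- function() {
  data.frame(
    tissue = rep(c("scalp_skull", "csf", "gray", "white"), each = 2L),
    wavelength = rep(c(690, 830), times = 4L),
    mu_a = c(
      0.0159, 0.0177,   # scalp/skull
      0.0026, 0.0026,   # CSF
      0.0178, 0.0186,   # gray matter
      0.0167, 0.0208    # white matter
    ),
    mu_s_prime = c(
      0.80, 0.74,
      0.30, 0.30,
      1.25, 1.11,
      1.37, 1.19
    ),
    refractive_index = rep(1.4, 8L),
    stringsAsFactors = FALSE
  )
}

#' Hemoglobin extinction coefficients at 690 and 830 nm
#'
#' Specific absorption coefficients of oxy- and deoxyhemoglobin expressed on
#' the natural-log optical-density scale, i.e. the matrix \eqn{E} such that
#' \deqn{\Delta\mu_a(\lambda) = E[\lambda,] \cdot (\Delta O_2Hb, \Delta HHb)}
#' with \eqn{\Delta\mu_a} in mm^-1 and concentrations in micromolar. Derived
#' from standard decadic molar extinction tabulations (690 nm: 276 and
#' 2051.96 cm^-1 M^-1; 830 nm: 974 and 693.04 cm^-1 M^-1 for O2Hb and HHb)
#' times ln(10). This single table is the source of truth for both the
#' forward synthetic generator and the spectral unmixing, so round trips are
#' exact by construction.
#'
#' At 690 nm HHb dominates, at 830 nm O2Hb dominates; the matrix is well
#' conditioned (condition number about 3).
#'
#' @return A 2x2 numeric matrix, rows \code{"690"}/\code{"830"}, columns
#'   \code{"o2hb"}/\code{"hhb"}, units mm^-1 per micromolar.
#' @export
extinction_coefficients <- function() {
  decadic <- rbind(
    "690" = c(o2hb = 276.00, hhb = 2051.96),
    "830" = c(o2hb = 974.00, hhb = 693.04)
  )
  # cm^-1/M -> mm^-1/uM is a factor 1e-7; ln(10) converts decadic OD to
  # natural-log absorption.
  decadic * 1e-7 * log(10)
}

#' Default differential pathlength factors
#'
#' @return Named numeric vector of DPF values for the 690 and 830 nm
#'   wavelengths (dimensionless).
#' @export
dpf_defaults <- function() {
  c("690" = 6.0, "830" = 5.8)
}

# Look up one optical property for a tissue/wavelength pair.
tissue_property <- function(properties, tissue, wavelength, field) {
  row <- properties$tissue == tissue & properties$wavelength == wavelength
  if (!any(row)) {
    stop("no optical properties for tissue '", tissue, "' at ", wavelength,
         " nm", call. = FALSE)
  }
  properties[[field]][row][1L]
}
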