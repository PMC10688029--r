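#' Construct an emission spectrum
#'
#' An `emission_spectrum` holds one recorded fluorescence emission band:
#' a strictly increasing wavelength grid (nm) with intensities in arbitrary
#' units, plus the measurement metadata needed downstream (temperature,
#' crowder identity and concentration, replicate).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of intensities (AU), same length as
#'   `wavelengths`.
#' @param temperature Sample temperature in degrees Celsius.
#' @param crowder Crowder label, or `NA` for a crowder-free sample.
#' @param concentration Crowder mass concentration in mg/mL.
#' @param replicate Integer replicate identifier.
#' @return An object of class `emission_spectrum`.
#' @examples
#' s <- emission_spectrum(290:450, dnorm(290:450, 350, 25))
#' barycentric_mean(s)
#' @export
emission_spectrum <- function(wavelengths, intensities, temperature = 25,
                              crowder = NA_character_, concentration = 0,
                              replicate = 1L) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L)
    stop("an emission spectrum needs at least 2 grid points")
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (any(!is.finite(wavelengths)) || any(!is.finite(intensities)))
    stop("wavelengths and intensities must be finite")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         temperature = as.numeric(temperature),
         crowder = as.character(crowder),
         concentration = as.numeric(concentration),
         replicate = as.integer(replicate)),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "Emission spectrum: %d points, %.1f-%.1f nm, T = %g degC, crowder = %s (%g mg/mL), rep %d\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$temperature, ifelse(is.na(x$crowder), "none", x$crowder),
    x$concentration, x$replicate))
  invisible(x)
}

#' Blank-correct an emission spectrum
#'
#' Subtracts a blank (buffer-only) spectrum from a sample spectrum,
#' point by point. The two spectra must share an identical wavelength
#' grid; no interpolation is attempted. Metadata are copied from the
#' sample. Corrected intensities may dip slightly negative from noise;
#' they are kept (a warning is emitted) so that downstream weighted
#' averages remain unbiased.
#'
#' @param sample Sample `emission_spectrum`.
#' @param blank Blank `emission_spectrum` on the same grid.
#' @return The corrected `emission_spectrum`.
#' @export
blank_correct <- function(sample, blank) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(blank, "emission_spectrum"))
  if (length(sample$wavelengths) != length(blank$wavelengths) ||
      any(sample$wavelengths != blank$wavelengths))
    stop("sample and blank wavelength grids differ; ",
         "refusing to interpolate blank spectra")
  out <- sample
  out$intensities <- sample$intensities - blank$intensities
  if (any(out$intensities < 0))
    warning("blank-corrected intensities contain negative values; retained")
  out
}

#' Barycentric mean emission wavelength
#'
#' The intensity-weighted mean wavelength
#' \eqn{\lambda_{bcm} = \sum \lambda I(\lambda) / \sum I(\lambda)},
#' evaluated by discrete summation over the grid points falling inside
#' `range`. A red-shift of the barycentre signals increased solvent
#' exposure of the indole ring; a blue-shift the opposite.
#'
#' @param s An `emission_spectrum`.
#' @param range Length-2 numeric, integration window in nm. Default is the
#'   recorded emission window 290-450 nm.
#' @return The barycentric mean wavelength in nm.
#' @export
barycentric_mean <- function(s, range = c(290, 450)) {
  stopifnot(inherits(s, "emission_spectrum"), length(range) == 2)
  range <- sort(as.numeric(range))
  keep <- s$wavelengths >= range[1] & s$wavelengths <= range[2]
  if (!any(keep)) stop("no grid points inside the integration range")
  lam <- s$wavelengths[keep]
  ii <- s$intensities[keep]
  tot <- sum(ii)
  if (tot <= 0)
    stop("total intensity over the range is not positive; ",
         "barycentric mean is undefined")
  sum(lam * ii) / tot
}

#' Crowder-induced shift of the barycentric mean wavelength
#'
#' Computes the signed shift
#' `delta = lambda_bcm(with crowder) - lambda_bcm(without)`.
#' Positive values are red-shifts, negative blue-shifts. Shifts of
#' magnitude below 1 nm are flagged as not significant, matching the
#' reporting convention for instrument-limited shifts.
#'
#' @param with_crowder `emission_spectrum` measured in the presence of the
#'   crowder.
#' @param without `emission_spectrum` of the crowder-free reference.
#' @param range Integration window in nm passed to [barycentric_mean()].
#' @return A `bcm_shift` list with fields `lambda_bcm_with`,
#'   `lambda_bcm_without`, `delta` (nm) and `significant` (logical,
#'   `abs(delta) >= 1` nm).
#' @export
delta_bcm <- function(with_crowder, without, range = c(290, 450)) {
  lw <- barycentric_mean(with_crowder, range)
  lo <- barycentric_mean(without, range)
  structure(
    list(lambda_bcm_with = lw, lambda_bcm_without = lo,
         delta = lw - lo, significant = abs(lw - lo) >= 1),
    class = "bcm_shift")
}

#' @export
print.bcm_shift <- function(x, ...) {
  cat(sprintf("delta lambda_bcm = %+.2f nm (%s; %s)\n", x$delta,
              if (x$delta >= 0) "red-shift" else "blue-shift",
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Peak emission intensity within a wavelength window
#'
#' @param s An `emission_spectrum`.
#' @param range Length-2 numeric window in nm.
#' @return Maximum intensity (AU) over grid points inside `range`.
#' @export
peak_intensity <- function(s, range = c(290, 450)) {
  stopifnot(inherits(s, "emission_spectrum"), length(range) == 2)
  range <- sort(as.numeric(range))
  keep <- s$wavelengths >= range[1] & s$wavelengths <= range[2]
  if (!any(keep)) stop("no grid points inside the requested range")
  max(s$intensities[keep])
}

#' Percent decrease in emission intensity
#'
#' `100 * (F0 - F) / F0`. Negative output signals fluorescence
#' enhancement (intensity in the presence of cosolute exceeds the
#' reference), as observed for ethylene glycol.
#'
#' @param F0 Reference intensity (AU), must be > 0.
#' @param F Intensity in the presence of the cosolute (AU).
#' @return Percent decrease (may be negative).
#' @export
percent_decrease <- function(F0, F) {
  if (any(F0 <= 0)) stop("reference intensity F0 must be positive")
  100 * (F0 - F) / F0
}
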