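# CD spectra arithmetic: additive mixtures and the 222/209 nm diagnostic
# ratio with its coiled-coil call.

#' Combine CD spectra as a weighted mixture
#'
#' Pointwise weighted mean of component spectra on a shared wavelength
#' grid. With mean-residue-ellipticity inputs and molar-fraction weights
#' this is the simulated "sum of the parts" spectrum against which an
#' experimental mixture is compared; a mass-weighting toggle is available
#' for equal-mass mixtures of proteins of different size.
#'
#' @param components List of spectra (tibbles with `wavelength`,
#'   `ellipticity`).
#' @param weights Numeric weights summing to 1 (tolerance 1e-6).
#' @param n_residues Optional residue counts per component; when given,
#'   weights are converted from mass fractions to residue-molar fractions.
#' @return Tibble with `wavelength`, `ellipticity`.
#' @export
combine_spectra <- function(components, weights, n_residues = NULL) {
  if (length(components) != length(weights)) {
    abort("one weight per component spectrum is required")
  }
  if (abs(sum(weights) - 1) > 1e-6) abort("weights must sum to 1")
  grid <- components[[1]]$wavelength
  for (s in components[-1]) {
    if (length(s$wavelength) != length(grid) ||
        any(abs(s$wavelength - grid) > 1e-9)) {
      abort("component spectra must share an identical wavelength grid")
    }
  }
  if (!is.null(n_residues)) {
    w <- weights * n_residues
    weights <- w / sum(w)
  }
  ell <- Reduce(`+`, Map(function(s, w) w * s$ellipticity, components, weights))
  tibble(wavelength = grid, ellipticity = ell)
}

#' 222/209 nm ellipticity ratio and coiled-coil call
#'
#' Linearly interpolates the spectrum to exactly 222 and 209 nm and reports
#' their ellipticity ratio. Isolated helices sit near 0.8; a ratio above
#' 0.9 is called coiled coil. If either ellipticity is non-negative there
#' is no helical signal and the ratio is undefined.
#'
#' @param spectrum Tibble with `wavelength`, `ellipticity`; the grid must
#'   cover 205-225 nm.
#' @return One-row tibble: `ratio_222_209`, `e209`, `e222`, `coiled_coil`
#'   (logical; `NA` when undefined).
#' @export
ratio_222_209 <- function(spectrum) {
  wl <- spectrum$wavelength
  if (min(wl) > 205 || max(wl) < 225) {
    abort("spectrum grid must cover 205-225 nm")
  }
  e209 <- approx(wl, spectrum$ellipticity, xout = 209)$y
  e222 <- approx(wl, spectrum$ellipticity, xout = 222)$y
  if (e209 >= 0 && e222 >= 0) {
    warn("no negative helical signal at 209/222 nm; ratio undefined")
    return(tibble(ratio_222_209 = NA_real_, e209 = e209, e222 = e222,
                  coiled_coil = NA))
  }
  r <- e222 / e209
  tibble(ratio_222_209 = r, e209 = e209, e222 = e222, coiled_coil = r > 0.9)
}
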