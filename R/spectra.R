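#' Default sensor wavelength grid
#'
#' 272 evenly spaced bands spanning 395 to 997 nm (about 2.2 nm apart),
#' matching a visible/near-infrared imaging spectrometer.
#'
#' @param n_bands Number of bands.
#' @param from,to Wavelength range (nm).
#' @return Strictly increasing numeric vector of wavelengths (nm).
#' @export
default_wavelengths <- function(n_bands = 272, from = 395, to = 997) {
  seq(from, to, length.out = n_bands)
}

#' Construct a plot-level spectral cube
#'
#' @param pixels Numeric matrix, one row per pixel, one column per band;
#'   reflectance in `[0, 1.5]`.
#' @param wavelengths Band-centre wavelengths (nm), strictly increasing, one
#'   per column.
#' @param plot_id Plot identifier.
#' @param coords Optional data frame of pixel `(row, col)` coordinates.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(pixels, wavelengths = default_wavelengths(),
                          plot_id = NA, coords = NULL) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != length(wavelengths))
    stop("pixel matrix must have one column per wavelength")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(pixels < 0)) stop("negative reflectance in cube")
  structure(list(pixels = pixels, wavelengths = wavelengths,
                 plot_id = plot_id, coords = coords),
            class = "spectral_cube")
}

#' Index of the band nearest a nominal wavelength
#'
#' Vegetation-index formulas name nominal wavelengths (e.g. 800 nm); the
#' sensor samples a discrete grid. Returns the index of the band minimising
#' the absolute distance to the nominal wavelength; exact ties go to the
#' lower wavelength. No interpolation is performed.
#'
#' @param wavelengths Sorted ascending wavelength grid (nm).
#' @param nominal Nominal wavelength (nm); must lie within 5 nm of the grid
#'   range.
#' @return Integer band index.
#' @export
nearest_band <- function(wavelengths, nominal) {
  if (nominal < min(wavelengths) - 5 || nominal > max(wavelengths) + 5)
    stop("nominal wavelength ", nominal, " nm outside sensor range")
  which.min(abs(wavelengths - nominal))
}

#' Per-pixel NDVI
#'
#' `(p800 - p670) / (p800 + p670)` using the nearest sensor bands to 800 and
#' 670 nm. Pixels with a zero denominator get NDVI 0.
#'
#' @param cube A [spectral_cube()].
#' @return Numeric vector, one NDVI per pixel.
#' @export
pixel_ndvi <- function(cube) {
  p800 <- cube$pixels[, nearest_band(cube$wavelengths, 800)]
  p670 <- cube$pixels[, nearest_band(cube$wavelengths, 670)]
  den <- p800 + p670
  ifelse(den == 0, 0, (p800 - p670) / den)
}

#' NDVI-mask a cube and average the plant pixels
#'
#' Retains pixels with NDVI strictly greater than `threshold` (plant
#' pixels), and averages them per band to give the plot reflectance.
#' A plot with no retained pixels is flagged empty (its reflectance is NA
#' and it should be excluded downstream); a retained fraction below
#' `min_fraction` raises a low-cover warning flag.
#'
#' @param cube A [spectral_cube()].
#' @param threshold NDVI threshold; strict `>` is applied.
#' @param min_fraction Minimum acceptable retained fraction before the
#'   low-cover flag is set.
#' @return An object of class `plot_reflectance`: `wavelengths`,
#'   `reflectance` (band means over retained pixels), `n_plant_pixels`,
#'   `n_total_pixels`, `plot_id`, `empty`, `low_cover`.
#' @export
mask_and_average <- function(cube, threshold = 0.5, min_fraction = 0.01) {
  if (nrow(cube$pixels) == 0) stop("empty cube")
  keep <- pixel_ndvi(cube) > threshold
  n_keep <- sum(keep)
  refl <- if (n_keep > 0) {
    colMeans(cube$pixels[keep, , drop = FALSE])
  } else {
    rep(NA_real_, length(cube$wavelengths))
  }
  structure(list(wavelengths = cube$wavelengths, reflectance = refl,
                 n_plant_pixels = n_keep,
                 n_total_pixels = nrow(cube$pixels),
                 plot_id = cube$plot_id,
                 empty = n_keep == 0,
                 low_cover = n_keep / nrow(cube$pixels) < min_fraction),
            class = "plot_reflectance")
}

# nominal wavelengths used across the vegetation-index set
.index_bands <- c(531, 550, 570, 600, 655, 670, 675, 683, 685, 690, 700,
                  710, 740, 750, 760, 800)

#' Vegetation indices from a plot reflectance spectrum
#'
#' Computes the 15-index set associated with photosynthesis, canopy size
#' and pigment content, using nearest-band lookup for the nominal
#' wavelengths:
#' Curvature `p683^2/(p675*p690)`, CVI `(p750/p550)*(p670/p550)`,
#' NDRE `(p750-p710)/(p750+p710)`, NDVI `(p800-p670)/(p800+p670)`,
#' PRI `(p531-p570)/(p531+p570)`, the ratios `p685/p655`, `p690/p600`,
#' `p740/p700`, `p760/p750`, the normalised difference
#' `(p760-p750)/(p760+p750)`, Red_edge `p750/p710`,
#' OSAVI `(1+0.16)*(p800-p670)/(p800+p670+0.16)`, the raw bands `r750` and
#' `r760`, and TVI `0.5*(120*(p750-p550) - 200*(p670-p550))`.
#' An index whose denominator is zero is reported as `NA`.
#'
#' @param pr A [mask_and_average()] result (or any list with `wavelengths`
#'   and `reflectance`).
#' @return One-row data frame of the 15 indices (plus `plot_id`).
#' @export
compute_indices <- function(pr) {
  if (isTRUE(pr$empty)) stop("cannot compute indices for an empty plot")
  w <- pr$wavelengths
  r <- pr$reflectance
  p <- function(nm) r[nearest_band(w, nm)]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- data.frame(
    plot_id = if (is.null(pr$plot_id)) NA else pr$plot_id,
    Curvature = safe_div(p(683)^2, p(675) * p(690)),
    CVI = safe_div(p(750) * p(670), p(550)^2),
    NDRE = safe_div(p(750) - p(710), p(750) + p(710)),
    NDVI = safe_div(p(800) - p(670), p(800) + p(670)),
    PRI = safe_div(p(531) - p(570), p(531) + p(570)),
    r685_r655 = safe_div(p(685), p(655)),
    r690_r600 = safe_div(p(690), p(600)),
    r740_r700 = safe_div(p(740), p(700)),
    r760_r750 = safe_div(p(760), p(750)),
    r760_r750index = safe_div(p(760) - p(750), p(760) + p(750)),
    Red_edge = safe_div(p(750), p(710)),
    OSAVI = safe_div((1 + 0.16) * (p(800) - p(670)), p(800) + p(670) + 0.16),
    r750 = p(750),
    r760 = p(760),
    TVI = 0.5 * (120 * (p(750) - p(550)) - 200 * (p(670) - p(550))))
  out
}

#' Index table for many plots
#'
#' @param prs List of [mask_and_average()] results; empty plots are skipped.
#' @return Data frame with one row of indices per non-empty plot.
#' @export
index_table <- function(prs) {
  rows <- lapply(prs, function(pr) {
    if (isTRUE(pr$empty)) NULL else compute_indices(pr)
  })
  do.call(rbind, rows)
}
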