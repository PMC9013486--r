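#' Read and write gas-exchange curve tables
#'
#' Long CSV format: one row per measurement step with columns `plot_id`,
#' `genotype`, `kind` (`"ACi"`/`"Ai"`), `step`, `A_obs`, `Ca`, `Ci`,
#' `I_inc`, `Tleaf`.
#'
#' @param path CSV path.
#' @return `read_curves` returns the long data frame.
#' @export
read_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "kind", "step", "A_obs", "Ca", "I_inc")
  if (!all(need %in% names(d)))
    stop("curve CSV must have columns ", paste(need, collapse = ", "))
  d
}

#' @rdname read_curves
#' @param curves Long curve data frame.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' Read a pixel-spectra CSV plus wavelength sidecar into spectral cubes
#'
#' The CSV has columns `plot_id`, `pixel_row`, `pixel_col`, then one column
#' per band (`b001`...); the JSON sidecar holds
#' `{"wavelengths_nm": [...]}`.
#'
#' @param csv_path Pixel CSV path.
#' @param json_path Wavelength sidecar path (default: same name,
#'   `.json` extension).
#' @return Named list of [spectral_cube()] objects, one per plot.
#' @export
read_cubes <- function(csv_path, json_path = sub("\\.csv$", ".json",
                                                 csv_path)) {
  d <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  w <- jsonlite::fromJSON(json_path)$wavelengths_nm
  band_cols <- grep("^b[0-9]+$", names(d), value = TRUE)
  if (length(band_cols) != length(w))
    stop("band columns do not match wavelength sidecar")
  lapply(split(d, d$plot_id), function(p) {
    spectral_cube(as.matrix(p[, band_cols]), w, plot_id = p$plot_id[1],
                  coords = p[, c("pixel_row", "pixel_col")])
  })
}

#' @rdname read_cubes
#' @param cubes Named list of [spectral_cube()] objects.
#' @export
write_cubes <- function(cubes, csv_path,
                        json_path = sub("\\.csv$", ".json", csv_path)) {
  rows <- lapply(cubes, function(cb) {
    px <- as.data.frame(cb$pixels)
    names(px) <- sprintf("b%03d", seq_along(cb$wavelengths))
    coords <- if (is.null(cb$coords))
      data.frame(pixel_row = seq_len(nrow(px)), pixel_col = 1) else cb$coords
    cbind(data.frame(plot_id = cb$plot_id), coords, px)
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  jsonlite::write_json(list(wavelengths_nm = cubes[[1]]$wavelengths),
                       json_path, digits = NA)
  invisible(csv_path)
}

#' Serialise and restore a fitted PLSR model as JSON
#'
#' Stores the coefficients, centring vectors and metadata needed for
#' prediction (plus the cross-validation statistics for reporting).
#'
#' @param model A [fit_plsr()] model.
#' @param path JSON path.
#' @export
write_plsr_model <- function(model, path) {
  keep <- c("trait", "coefficients", "intercept", "x_mean", "x_sd",
            "y_mean", "n_latent", "scale", "cv_r2", "cv_rmse",
            "cv_rmse_pct", "n_obs")
  jsonlite::write_json(model[keep], path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsr_model
#' @return `read_plsr_model` returns a model usable by [predict_traits()].
#' @export
read_plsr_model <- function(path) {
  m <- jsonlite::fromJSON(path)
  m$coefficients <- as.numeric(m$coefficients)
  structure(m, class = "c4_plsr")
}
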