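#' Configuration of the synthetic field-trial generator
#'
#' Defines the study conditions the generator emulates. Trait means and
#' spreads are centred on the plot-level summaries of field-grown sorghum
#' training sets (Vcmax mean 51.1, range ~40-66; Vpmax mean ~408, range
#' ~105-950; Jmax mean ~400, range ~230-770 umol m-2 s-1; SLN mean 2.0,
#' range 1.3-2.5 g m-2; LMA range 36-63.5 g m-2). Genotype effects are
#' drawn from a correlated multivariate normal (defaults: Vcmax-SLN r=0.6,
#' Jmax-SLN r=0.5, all other pairs 0.2) and plot residuals are independent
#' normals; the genetic/residual split targets a plot-level repeatability
#' of about 0.85.
#'
#' @param n_genotypes Number of genotypes.
#' @param rep_fraction Fraction of genotypes grown in two plots (partial
#'   replication); remaining genotypes get one plot.
#' @param trait_means,genetic_sd,residual_sd Named vectors over
#'   `Vcmax`, `Vpmax`, `Jmax`, `SLN`, `LMA`.
#' @param trait_cor Genotype-level correlation matrix (5 x 5, same order).
#' @param curve_noise_cv Multiplicative coefficient of variation of
#'   gas-exchange noise.
#' @param curve_noise_floor Additive gas-exchange noise SD
#'   (umol m-2 s-1).
#' @param ci_jitter_sd SD of the per-step jitter on the Ci/Ca ratio.
#' @param pixels_per_plot Pixels in each simulated plot cube.
#' @param soil_fraction Fraction of soil pixels per cube.
#' @param spectral_noise_sd SD of the band-correlated (smooth) spectral
#'   noise per pixel.
#' @param seed Mandatory seed; every stochastic operation is deterministic
#'   given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genotypes = 100, rep_fraction = 0.35,
                             trait_means = c(Vcmax = 51.1, Vpmax = 408,
                                             Jmax = 400, SLN = 2.0,
                                             LMA = 50),
                             genetic_sd = c(Vcmax = 5.5, Vpmax = 140,
                                            Jmax = 85, SLN = 0.20,
                                            LMA = 5.5),
                             residual_sd = c(Vcmax = 2.2, Vpmax = 55,
                                             Jmax = 34, SLN = 0.08,
                                             LMA = 2.2),
                             trait_cor = NULL,
                             curve_noise_cv = 0.02,
                             curve_noise_floor = 0.2,
                             ci_jitter_sd = 0.02,
                             pixels_per_plot = 48,
                             soil_fraction = 0.3,
                             spectral_noise_sd = 0.004,
                             seed = 1) {
  traits <- c("Vcmax", "Vpmax", "Jmax", "SLN", "LMA")
  if (is.null(trait_cor)) {
    trait_cor <- matrix(0.2, 5, 5, dimnames = list(traits, traits))
    diag(trait_cor) <- 1
    trait_cor["Vcmax", "SLN"] <- trait_cor["SLN", "Vcmax"] <- 0.6
    trait_cor["Jmax", "SLN"] <- trait_cor["SLN", "Jmax"] <- 0.5
  }
  if (min(eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10)
    stop("trait correlation matrix is not positive semi-definite")
  structure(list(n_genotypes = n_genotypes, rep_fraction = rep_fraction,
                 trait_means = trait_means[traits],
                 genetic_sd = genetic_sd[traits],
                 residual_sd = residual_sd[traits],
                 trait_cor = trait_cor, curve_noise_cv = curve_noise_cv,
                 curve_noise_floor = curve_noise_floor,
                 ci_jitter_sd = ci_jitter_sd,
                 pixels_per_plot = pixels_per_plot,
                 soil_fraction = soil_fraction,
                 spectral_noise_sd = spectral_noise_sd, seed = seed,
                 traits = traits),
            class = "generator_config")
}

#' Draw genotype-level trait truth values
#'
#' Genotype means for the five traits from a correlated multivariate
#' normal, truncated to positive values by resampling. Percent leaf
#' nitrogen is derived so that `SLN = (%N / 100) * LMA` holds exactly.
#'
#' @param config A [generator_config()].
#' @return Data frame: `genotype`, the five traits, `percent_n`.
#' @export
gen_genotype_truth <- function(config = generator_config()) {
  n <- config$n_genotypes
  Sigma <- diag(config$genetic_sd) %*% config$trait_cor %*%
    diag(config$genetic_sd)
  draw <- withr::with_seed(config$seed, {
    X <- MASS::mvrnorm(n, mu = config$trait_means, Sigma = Sigma)
    bad <- which(apply(X, 1, function(r) any(r <= 0)))
    guard <- 0
    while (length(bad) > 0 && guard < 100) {
      X[bad, ] <- MASS::mvrnorm(length(bad), mu = config$trait_means,
                                Sigma = Sigma)
      bad <- which(apply(X, 1, function(r) any(r <= 0)))
      guard <- guard + 1
    }
    X
  })
  colnames(draw) <- config$traits
  out <- data.frame(genotype = sprintf("G%04d", seq_len(n)), draw)
  out$percent_n <- 100 * out$SLN / out$LMA
  out
}

#' Generate a partially replicated row-column field layout
#'
#' A fraction of genotypes (seeded sample) is duplicated; plots are laid on
#' a near-square row-column grid with randomised genotype positions.
#'
#' @param config A [generator_config()].
#' @return Data frame: `plot_id`, `genotype`, `row`, `col`, `replicate`.
#' @export
gen_field_layout <- function(config = generator_config()) {
  n_g <- config$n_genotypes
  n_rep <- round(config$rep_fraction * n_g)
  n_plots <- n_g + n_rep
  n_col <- ceiling(sqrt(n_plots))
  n_row <- ceiling(n_plots / n_col)
  if (n_row * n_col < n_plots) stop("grid too small")
  genos <- sprintf("G%04d", seq_len(n_g))
  withr::with_seed(config$seed + 1, {
    reps <- sample(genos, n_rep)
    assign <- sample(c(genos, reps))
    data.frame(plot_id = sprintf("P%04d", seq_len(n_plots)),
               genotype = assign,
               row = rep(seq_len(n_row), each = n_col)[seq_len(n_plots)],
               col = rep(seq_len(n_col), times = n_row)[seq_len(n_plots)],
               replicate = as.integer(stats::ave(assign, assign,
                                                 FUN = seq_along)))
  })
}

#' Plot-level realised trait values
#'
#' Genotype truth plus independent plot residuals (the non-genetic
#' variance); SLN/LMA consistency is restored by recomputing percent N.
#'
#' @param truth From [gen_genotype_truth()].
#' @param layout From [gen_field_layout()].
#' @param config A [generator_config()].
#' @return Data frame keyed by `plot_id` with the five realised traits.
#' @export
gen_plot_traits <- function(truth, layout, config = generator_config()) {
  tab <- merge(layout, truth, by = "genotype", sort = FALSE)
  tab <- tab[order(tab$plot_id), ]
  n <- nrow(tab)
  withr::with_seed(config$seed + 2, {
    for (tr in config$traits) {
      tab[[tr]] <- pmax(tab[[tr]] +
                          stats::rnorm(n, 0, config$residual_sd[[tr]]),
                        0.05 * config$trait_means[[tr]])
    }
  })
  tab$percent_n <- 100 * tab$SLN / tab$LMA
  rownames(tab) <- NULL
  tab
}

#' Simulate gas-exchange response curves from trait truth
#'
#' For each plot row, the forward C4 model predicts assimilation at the
#' protocol steps; observation noise is multiplicative Gaussian (CV
#' `curve_noise_cv`) plus an additive floor (SD `curve_noise_floor`).
#' Intercellular CO2 is generated from ambient CO2 via a Ci/Ca ratio of
#' 0.4 with per-step Gaussian jitter, and the noise-free assimilation is
#' computed at that jittered Ci so the recorded Ci is consistent with the
#' backbone.
#'
#' @param plot_traits Data frame with `plot_id`, `genotype` and the trait
#'   columns `Vcmax`, `Vpmax`, `Jmax` (e.g. from [gen_plot_traits()]).
#' @param protocol `"aci"`, `"ai"` or `"both"`.
#' @param config A [generator_config()]; `curve_noise_cv = 0` gives curves
#'   exactly reproducible by [predict_curve()].
#' @param consts A [c4_constants()] object.
#' @param Rd,theta,PSabs,gm Leaf parameters not carried by the truth table.
#' @return Long data frame: `plot_id`, `genotype`, `kind`, `step`,
#'   `A_obs`, `Ca`, `Ci`, `I_inc`, `Tleaf`.
#' @export
simulate_curves <- function(plot_traits, protocol = c("both", "aci", "ai"),
                            config = generator_config(),
                            consts = c4_constants(), Rd = 2, theta = 0.3,
                            PSabs = 0.35, gm = 1) {
  protocol <- match.arg(protocol)
  kinds <- switch(protocol, both = c("aci", "ai"), aci = "aci", ai = "ai")
  withr::with_seed(config$seed + 3, {
    out <- lapply(seq_len(nrow(plot_traits)), function(i) {
      r <- plot_traits[i, ]
      params <- leaf_params(Vcmax = r$Vcmax, Vpmax = r$Vpmax,
                            Jmax = r$Jmax, Rd = Rd, theta = theta,
                            PSabs = PSabs, gm = gm)
      rows <- lapply(kinds, function(k) {
        proto <- if (k == "aci") aci_protocol() else ai_protocol()
        ratio <- pmin(pmax(0.4 + stats::rnorm(length(proto$Ca), 0,
                                              config$ci_jitter_sd),
                           0.1), 0.9)
        proto$Ci <- proto$Ca * ratio
        pred <- predict_curve(proto, params)
        A_obs <- pred$A * (1 + stats::rnorm(10, 0, config$curve_noise_cv)) +
          if (config$curve_noise_cv > 0)
            stats::rnorm(10, 0, config$curve_noise_floor) else 0
        data.frame(plot_id = r$plot_id, genotype = r$genotype,
                   kind = pred$kind, step = pred$step, A_obs = A_obs,
                   Ca = pred$Ca, Ci = pred$Ci, I_inc = pred$I_inc,
                   Tleaf = 30)
      })
      do.call(rbind, rows)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# smooth gaussian bump on the wavelength grid
.bump <- function(w, centre, width) exp(-0.5 * ((w - centre) / width)^2)

# Plant endmember spectrum as a function of standardised trait values.
# Each trait carries a distinct spectral signature, placed where canopy
# reflectance is known to respond: chlorophyll/N absorption at the red
# trough and a red-edge shift (SLN), red-edge position and NIR level
# (Jmax), NIR plateau and the 955 nm structural dip (LMA), a red-edge
# position shift plus a ~940 nm NIR feature (Vcmax — photosynthetic
# capacity loads on the red edge and the 950-960 nm region, largely beyond
# the reach of the index set), and narrow features at 760/687 nm (Vpmax).
.plant_endmember <- function(w, z) {
  re_pos <- 715 + 2.5 * z[["SLN"]] + 2 * z[["Jmax"]] + 1.5 * z[["Vcmax"]]
  re_width <- 11
  plateau <- 0.42 + 0.030 * z[["LMA"]] + 0.010 * z[["Jmax"]]
  refl <- 0.04 +
    (0.06 + 0.006 * z[["SLN"]]) * .bump(w, 550, 25) +
    (plateau - 0.04) / (1 + exp(-(w - re_pos) / re_width)) -
    (0.012 * z[["SLN"]] + 0.006 * z[["Vcmax"]]) * .bump(w, 665, 28) -
    (0.050 + 0.012 * z[["LMA"]]) * .bump(w, 955, 18) +
    0.012 * z[["Vcmax"]] * .bump(w, 940, 12) +
    0.010 * z[["Vpmax"]] * .bump(w, 760, 7) +
    0.006 * z[["Vpmax"]] * .bump(w, 687, 6)
  pmax(refl, 0.005)
}

#' Simulate a plot's mixed plant/soil spectral cube
#'
#' Builds the plot's plant endmember from its trait values (see the
#' methods vignette for the trait-to-spectrum map), mixes plant pixels
#' (NDVI > 0.6 by construction) with spectrally flat soil pixels
#' (reflectance ~0.25, NDVI < 0.2) at the configured soil fraction, and
#' adds band-correlated plus independent Gaussian noise per pixel.
#'
#' @param truth_row One row of a plot-trait table (needs the five traits
#'   and `plot_id`).
#' @param config A [generator_config()].
#' @param seed Seed for this cube (defaults to a value derived from the
#'   config seed and the plot number).
#' @param wavelengths Sensor wavelength grid.
#' @return A [spectral_cube()].
#' @export
simulate_cube <- function(truth_row, config = generator_config(),
                          seed = NULL,
                          wavelengths = default_wavelengths()) {
  if (is.null(seed)) {
    seed <- config$seed + 1000 +
      (as.integer(sub("\\D*", "", truth_row$plot_id)) %% 100000)
  }
  z <- vapply(config$traits, function(tr) {
    (truth_row[[tr]] - config$trait_means[[tr]]) /
      sqrt(config$genetic_sd[[tr]]^2 + config$residual_sd[[tr]]^2)
  }, 0)
  z <- pmin(pmax(z, -3), 3)
  plant <- .plant_endmember(wavelengths, z)
  soil <- 0.25 + 0.00005 * (wavelengths - 395)
  n_px <- config$pixels_per_plot
  n_soil <- round(config$soil_fraction * n_px)
  n_plant <- n_px - n_soil
  p <- length(wavelengths)
  withr::with_seed(seed, {
    mk_noise <- function(n) {
      raw <- matrix(stats::rnorm(n * p), n, p)
      smooth <- t(apply(raw, 1, function(r)
        stats::filter(r, rep(1 / 7, 7), sides = 2, circular = TRUE)))
      smooth * config$spectral_noise_sd * sqrt(7) +
        matrix(stats::rnorm(n * p, 0, 0.002), n, p)
    }
    brightness <- exp(stats::rnorm(n_plant, 0, 0.05))
    plant_px <- outer(brightness, plant) + mk_noise(n_plant)
    soil_px <- if (n_soil > 0)
      matrix(soil, n_soil, p, byrow = TRUE) + mk_noise(n_soil) else
        matrix(0, 0, p)
    pixels <- pmax(rbind(plant_px, soil_px), 0)
  })
  spectral_cube(pixels, wavelengths, plot_id = truth_row$plot_id)
}

#' Simulate a complete trial: truth, layout, plot traits, reflectance
#'
#' Convenience wrapper that draws genotype truth, lays out the field,
#' realises plot-level traits, and (optionally) simulates and NDVI-masks a
#' cube per plot to give the plot reflectance matrix.
#'
#' @param config A [generator_config()].
#' @param reflectance If `TRUE`, simulate cubes and return the masked plot
#'   reflectance matrix.
#' @return List: `truth`, `layout`, `plot_traits`, and when requested
#'   `reflectance` (plots x bands matrix, rownames = plot_id) plus
#'   `wavelengths`.
#' @export
simulate_trial <- function(config = generator_config(),
                           reflectance = TRUE) {
  truth <- gen_genotype_truth(config)
  layout <- gen_field_layout(config)
  plot_traits <- gen_plot_traits(truth, layout, config)
  out <- list(truth = truth, layout = layout, plot_traits = plot_traits)
  if (reflectance) {
    w <- default_wavelengths()
    refl <- t(vapply(seq_len(nrow(plot_traits)), function(i) {
      cube <- simulate_cube(plot_traits[i, ], config, wavelengths = w)
      mask_and_average(cube)$reflectance
    }, numeric(length(w))))
    rownames(refl) <- plot_traits$plot_id
    out$reflectance <- refl
    out$wavelengths <- w
  }
  out
}
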