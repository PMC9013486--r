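#' Run configuration for the end-to-end pipeline
#'
#' @param seed Global seed; every stochastic stage derives from it.
#' @param n_training_plots Approximate number of training plots (the
#'   generator's genotype count is derived from it).
#' @param n_target_genotypes Genotypes in the target (extrapolation) trial.
#' @param max_latent,scale,r2_method PLSR settings (see [fit_plsr()]).
#' @param cor_threshold Index-subset correlation cap (see
#'   [pca_index_subset()]).
#' @param fit Curve-fitting settings, a [fit_config()].
#' @param vcmax_margin_min Minimum `Aj - Ac` gap (umol m-2 s-1) at the
#'   CO2-saturated step for a plot's fitted Vcmax to be considered
#'   identified (see [fit_curves()]); plots below it are excluded from
#'   Vcmax training only.
#' @param mask_threshold NDVI mask threshold.
#' @param mixed_model A [mixed_model_config()].
#' @param traits Traits carried through the pipeline.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_training_plots = 150,
                       n_target_genotypes = 445, max_latent = 25,
                       scale = FALSE, r2_method = "cor",
                       cor_threshold = 0.9,
                       fit = fit_config(seed = seed, fix_theta = 0.3),
                       vcmax_margin_min = 2,
                       mask_threshold = 0.5,
                       mixed_model = mixed_model_config(seed = seed),
                       traits = c("Vcmax", "Vpmax", "Jmax", "SLN", "LMA")) {
  structure(list(seed = seed, n_training_plots = n_training_plots,
                 n_target_genotypes = n_target_genotypes,
                 max_latent = max_latent, scale = scale,
                 r2_method = r2_method, cor_threshold = cor_threshold,
                 fit = fit, vcmax_margin_min = vcmax_margin_min,
                 mask_threshold = mask_threshold,
                 mixed_model = mixed_model, traits = traits),
            class = "run_config")
}

#' Train trait-prediction models on a (simulated or supplied) training set
#'
#' The training workflow: fit gas-exchange curves (Ai stage then ACi
#' stage), drop non-converged fits, flag extreme fitted parameters as
#' outliers per trait, NDVI-mask the plot cubes, build the vegetation-index
#' table, then per trait train both the PCA-guided stepwise index
#' regression and the full-spectrum PLSR. The plot is the observational
#' unit throughout. Outlier-flagged plots are excluded from that trait's
#' training rows.
#'
#' @param config A [run_config()].
#' @param data Optional list with `plot_traits`, `reflectance`,
#'   `wavelengths`, `curves` (as produced by [simulate_trial()] and
#'   [simulate_curves()]); when `NULL` a training trial is simulated under
#'   `config$seed`.
#' @return List of class `training_report`: `models` (per-trait
#'   [fit_plsr()] models), `stepwise` (per-trait `stepwise_model`),
#'   `metrics` (per trait and method: R2, RMSE, RMSE as percent of mean),
#'   `fits` (curve-fit table with outlier flags), `index_subset`,
#'   `attrition` (counts at each filter), `training_y` (trait table used).
#' @export
run_training <- function(config = run_config(), data = NULL) {
  if (is.null(data)) {
    n_g <- round(config$n_training_plots / 1.35)
    gcfg <- generator_config(n_genotypes = n_g, seed = config$seed)
    trial <- simulate_trial(gcfg)
    curves <- simulate_curves(trial$plot_traits, "both", gcfg)
    data <- list(plot_traits = trial$plot_traits,
                 reflectance = trial$reflectance,
                 wavelengths = trial$wavelengths, curves = curves)
  }
  fits <- fit_curves(data$curves, config = config$fit)
  n_fit <- nrow(fits)
  fits <- fits[fits$converged, , drop = FALSE]
  fits <- flag_outliers(fits)

  # ground-truth table per plot: fitted photosynthetic parameters plus the
  # directly measured leaf properties
  y_tab <- merge(fits[, c("plot_id", "Vcmax", "Vpmax", "Jmax",
                          "outlier_vcmax", "outlier_vpmax", "outlier_jmax",
                          "vcmax_margin")],
                 data$plot_traits[, c("plot_id", "SLN", "LMA")],
                 by = "plot_id")
  refl <- data$reflectance[y_tab$plot_id, , drop = FALSE]
  idx_tab <- as.data.frame(t(apply(refl, 1, function(r)
    unlist(compute_indices(list(wavelengths = data$wavelengths,
                                reflectance = r,
                                plot_id = NA))[-1]))))
  subset_names <- pca_index_subset(idx_tab, config$cor_threshold)

  models <- list(); stepwise <- list(); metrics <- list()
  for (tr in config$traits) {
    keep <- switch(tr,
                   Vcmax = !y_tab$outlier_vcmax &
                     y_tab$vcmax_margin > config$vcmax_margin_min,
                   Vpmax = !y_tab$outlier_vpmax,
                   Jmax = !y_tab$outlier_jmax,
                   rep(TRUE, nrow(y_tab)))
    y <- y_tab[[tr]][keep]
    if (sum(keep) < 10) {
      warning("fewer than 10 usable plots for ", tr, "; skipped")
      next
    }
    X <- refl[keep, , drop = FALSE]
    Xi <- idx_tab[keep, subset_names, drop = FALSE]
    pm <- fit_plsr(X, y, max_latent = config$max_latent,
                   scale = config$scale, r2_method = config$r2_method,
                   trait = tr)
    sw <- stepwise_aic(Xi, y)
    models[[tr]] <- pm
    stepwise[[tr]] <- sw
    in_r2_plsr <- stats::cor(predict(pm, X), y)^2
    metrics[[tr]] <- data.frame(
      trait = tr, n = sum(keep),
      plsr_cv_r2 = pm$cv_r2, plsr_cv_rmse = pm$cv_rmse,
      plsr_cv_rmse_pct = pm$cv_rmse_pct, plsr_n_latent = pm$n_latent,
      plsr_in_r2 = in_r2_plsr,
      stepwise_r2 = sw$r2, stepwise_rmse = sw$rmse,
      stepwise_rmse_pct = 100 * sw$rmse / mean(y),
      stepwise_p = sw$p_value)
  }
  structure(list(models = models, stepwise = stepwise,
                 metrics = do.call(rbind, c(metrics,
                                            list(make.row.names = FALSE))),
                 fits = fits, index_subset = subset_names,
                 attrition = c(curves_fitted = n_fit,
                               converged = sum(fits$converged),
                               outliers = sum(fits$outlier)),
                 training_y = y_tab, index_table = idx_tab),
            class = "training_report")
}

#' Extrapolate trained models to a target trial and score heritability
#'
#' Predicts each trait for every plot of the target trial from its masked
#' reflectance, then fits the row-column mixed model per trait and reports
#' the per-trait summary (min, max, mean, average BLUP standard error,
#' generalised H2).
#'
#' @param training A `training_report` from [run_training()].
#' @param target List with `reflectance` (plots x bands, rownames =
#'   plot_id) and `layout`; when `NULL` a target trial is simulated under
#'   `config$seed + 500`.
#' @param config A [run_config()].
#' @return List of class `extrapolation_report`: `predictions` (per-plot
#'   data frame), `blups` (the [blup_pipeline()] result), `summary`
#'   (Table-style per-trait summary with H2), and `target_truth` when the
#'   target was simulated (for scoring).
#' @export
run_extrapolation <- function(training, target = NULL,
                              config = run_config()) {
  target_truth <- NULL
  if (is.null(target)) {
    gcfg <- generator_config(n_genotypes = config$n_target_genotypes,
                             seed = config$seed + 500)
    trial <- simulate_trial(gcfg)
    target <- list(reflectance = trial$reflectance, layout = trial$layout)
    target_truth <- trial$plot_traits
  }
  preds <- data.frame(plot_id = rownames(target$reflectance))
  for (tr in names(training$models)) {
    preds[[tr]] <- predict(training$models[[tr]], target$reflectance)
  }
  bl <- blup_pipeline(preds, target$layout,
                      traits = setdiff(names(preds), "plot_id"),
                      config = config$mixed_model)
  structure(list(predictions = preds, blups = bl, summary = bl$summary,
                 target_truth = target_truth),
            class = "extrapolation_report")
}

#' One-command synthetic demonstration of the full pipeline
#'
#' Simulates a training trial (~150 plots) with gas-exchange curves and
#' canopy cubes, trains the stepwise and PLSR models, extrapolates the
#' PLSR models to a larger simulated target trial (~600 plots), fits BLUPs
#' and heritability, and scores the predictions against the generator's
#' true plot values.
#'
#' @param seed Global seed.
#' @param config Optional [run_config()] (its seed is overridden).
#' @return List of class `demo_report`: `training`, `extrapolation`,
#'   `recovery` (per-trait r-squared of target predictions vs generator
#'   truth), `heritability` (per-trait H2).
#' @export
run_demo <- function(seed = 1, config = NULL) {
  if (is.null(config)) config <- run_config(seed = seed)
  config$seed <- seed
  training <- run_training(config)
  extrap <- run_extrapolation(training, target = NULL, config = config)
  truth <- extrap$target_truth
  recovery <- vapply(names(training$models), function(tr) {
    stats::cor(extrap$predictions[[tr]],
               truth[[tr]][match(extrap$predictions$plot_id,
                                 truth$plot_id)])^2
  }, 0)
  h2 <- stats::setNames(extrap$summary$h2, extrap$summary$trait)
  structure(list(training = training, extrapolation = extrap,
                 recovery = recovery, heritability = h2, seed = seed),
            class = "demo_report")
}

#' @export
print.demo_report <- function(x, ...) {
  cat("End-to-end synthetic pipeline (seed", x$seed, ")\n\n")
  cat("Training metrics (per trait):\n")
  print(x$training$metrics, row.names = FALSE, digits = 3)
  cat("\nExtrapolation: r-squared of predictions vs generator truth:\n")
  print(round(x$recovery, 3))
  cat("\nGeneralised heritability of predicted traits:\n")
  print(round(x$heritability, 3))
  invisible(x)
}
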