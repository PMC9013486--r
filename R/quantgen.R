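#' Configuration for the field-trial mixed model
#'
#' The plot-level model is `y = Xb + Zu + e` fitted by REML: fixed effects
#' are an intercept plus (optionally) linear trends along rows and columns;
#' random effects are genotype plus (optionally) row and column factors;
#' residuals are independent. This is a simplified variance structure:
#' first-order autoregressive spatial residuals are not modelled, random
#' row/column effects and fixed linear trends stand in for field trend.
#'
#' @param fixed_trends Include fixed linear row/column trends.
#' @param random_row,random_col Include random row/column factor effects.
#' @param max_pairs Above this many genotypes, the average SED is computed
#'   over a seeded random sample of `n_pair_sample` genotype pairs rather
#'   than all pairs.
#' @param n_pair_sample Number of sampled pairs.
#' @param seed Seed for the pair sample.
#' @return An object of class `mixed_model_config`.
#' @export
mixed_model_config <- function(fixed_trends = TRUE, random_row = TRUE,
                               random_col = TRUE, max_pairs = 200,
                               n_pair_sample = 5000, seed = 1) {
  structure(list(fixed_trends = fixed_trends, random_row = random_row,
                 random_col = random_col, max_pairs = max_pairs,
                 n_pair_sample = n_pair_sample, seed = seed),
            class = "mixed_model_config")
}

# Prediction-error variance of the genotype effects from the mixed-model
# equations assembled at the REML variance-component estimates. Returns the
# genotype block of the inverse coefficient matrix (G x G). Random blocks
# with (near-)zero variance are dropped; the genotype block is kept with a
# variance floor so the PEV is defined at the boundary.
.genotype_pev <- function(X, Zg, Zr, Zc, s2g, s2r, s2c, s2e) {
  s2g <- max(s2g, 1e-10)
  Z_list <- list(Zg)
  ginv <- rep(1 / s2g, ncol(Zg))
  if (!is.null(Zr) && s2r > 1e-10) {
    Z_list <- c(Z_list, list(Zr)); ginv <- c(ginv, rep(1 / s2r, ncol(Zr)))
  }
  if (!is.null(Zc) && s2c > 1e-10) {
    Z_list <- c(Z_list, list(Zc)); ginv <- c(ginv, rep(1 / s2c, ncol(Zc)))
  }
  Z <- do.call(cbind, Z_list)
  M <- cbind(X, Z)
  C <- crossprod(M) / s2e
  ridx <- ncol(X) + seq_len(ncol(Z))
  C[cbind(ridx, ridx)] <- C[cbind(ridx, ridx)] + ginv
  Cinv <- solve(C)
  gidx <- ncol(X) + seq_len(ncol(Zg))
  Cinv[gidx, gidx, drop = FALSE]
}

#' Fit the row-column mixed model for one trait
#'
#' REML fit (via [lme4::lmer]) of the plot-level trait with genotype (and
#' optionally row and column) random effects and fixed linear row/column
#' trends. Genotype BLUPs, variance components, the average standard error
#' of a difference between genotype BLUPs (from the prediction-error
#' variance of all pairwise differences, or a seeded 5000-pair sample for
#' large trials) and the generalised heritability are returned.
#'
#' @param table Data frame with columns `plot_id`, `genotype`, `row`,
#'   `col` and the trait.
#' @param trait Name of the trait column.
#' @param config A [mixed_model_config()].
#' @return An object of class `blup_result`: `blups` (named vector),
#'   `pev` (named vector of per-genotype prediction error variances),
#'   `sigma2_g`, `sigma2_e`, `sigma2_row`, `sigma2_col`, `sed_bar`, `h2`,
#'   `boundary` (genetic variance at zero), `logLik`, `n_genotypes`,
#'   `n_plots`, `trait`.
#' @export
fit_mixed_model <- function(table, trait, config = mixed_model_config()) {
  need <- c("genotype", "row", "col", trait)
  if (!all(need %in% names(table)))
    stop("table must have columns genotype, row, col and '", trait, "'")
  if (anyDuplicated(table[, c("row", "col")]))
    stop("duplicate (row, col) positions in layout")
  d <- data.frame(y = table[[trait]],
                  genotype = factor(table$genotype),
                  row_f = factor(table$row), col_f = factor(table$col),
                  row_lin = as.numeric(scale(table$row)),
                  col_lin = as.numeric(scale(table$col)))
  d <- d[is.finite(d$y), ]
  if (!any(duplicated(d$genotype)))
    stop("no genotype is replicated: genetic variance is not estimable")
  fixed <- if (config$fixed_trends) "y ~ 1 + row_lin + col_lin" else "y ~ 1"
  rand <- c("(1 | genotype)",
            if (config$random_row && nlevels(d$row_f) > 1) "(1 | row_f)",
            if (config$random_col && nlevels(d$col_f) > 1) "(1 | col_f)")
  form <- stats::as.formula(paste(fixed, "+", paste(rand, collapse = " + ")))
  m <- lme4::lmer(form, data = d, REML = TRUE,
                  control = lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(m))
  get_vc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  s2g <- get_vc("genotype")
  s2r <- get_vc("row_f"); s2c <- get_vc("col_f")
  s2e <- stats::sigma(m)^2
  boundary <- s2g < 1e-8 * max(stats::var(d$y), 1e-12)

  blups <- lme4::ranef(m)$genotype[, 1]
  names(blups) <- rownames(lme4::ranef(m)$genotype)

  X <- stats::model.matrix(stats::as.formula(fixed), d)
  Zg <- stats::model.matrix(~ 0 + genotype, d)
  Zr <- if (config$random_row && nlevels(d$row_f) > 1)
    stats::model.matrix(~ 0 + row_f, d) else NULL
  Zc <- if (config$random_col && nlevels(d$col_f) > 1)
    stats::model.matrix(~ 0 + col_f, d) else NULL
  pev <- .genotype_pev(X, Zg, Zr, Zc, s2g, s2r, s2c, s2e)

  G <- ncol(Zg)
  pairs <- if (G <= config$max_pairs) {
    t(utils::combn(G, 2))
  } else {
    withr::with_seed(config$seed, {
      cbind(sample.int(G, config$n_pair_sample, replace = TRUE),
            sample.int(G, config$n_pair_sample, replace = TRUE))
    })
  }
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  sed <- sqrt(pmax(diag(pev)[pairs[, 1]] + diag(pev)[pairs[, 2]] -
                     2 * pev[pairs], 0))
  sed_bar <- mean(sed)

  h2 <- heritability(if (boundary) 0 else s2g, sed_bar)

  structure(list(blups = blups, pev = stats::setNames(diag(pev),
                                                      levels(d$genotype)),
                 sigma2_g = s2g, sigma2_e = s2e, sigma2_row = s2r,
                 sigma2_col = s2c, sed_bar = sed_bar, h2 = h2,
                 boundary = boundary, logLik = as.numeric(stats::logLik(m)),
                 n_genotypes = G, n_plots = nrow(d), trait = trait),
            class = "blup_result")
}

#' Generalised heritability
#'
#' `H2 = 1 - sed_bar^2 / (2 * sigma2_g)`: one minus the ratio of the mean
#' prediction-error variance of a genotype difference to twice the genetic
#' variance. Appropriate for unbalanced designs with complex variance
#' structure where the classical entry-mean formula does not apply. At
#' `sigma2_g = 0` the value is reported as 0 with a `boundary` attribute;
#' values are not clipped, so a negative value (possible when genotype
#' effects are barely estimable) is returned as-is with a `flagged`
#' attribute.
#'
#' @param sigma2_g Genetic variance (>= 0).
#' @param sed_bar Average standard error of a genotype difference (>= 0).
#' @return Heritability (dimensionless); attributes `boundary` and
#'   `flagged` mark degenerate or out-of-range values.
#' @export
#' @examples
#' heritability(4, 0.5)
heritability <- function(sigma2_g, sed_bar) {
  if (sigma2_g < 0 || sed_bar < 0)
    stop("sigma2_g and sed_bar must be non-negative")
  if (sigma2_g == 0)
    return(structure(0, boundary = TRUE))
  h2 <- 1 - sed_bar^2 / (2 * sigma2_g)
  if (h2 < 0) structure(h2, flagged = TRUE) else h2
}

#' BLUPs and heritability for every predicted trait
#'
#' Joins per-plot trait predictions to the trial layout and runs
#' [fit_mixed_model()] plus [heritability()] for each trait, emitting a
#' per-trait summary (min, max, mean, average BLUP standard error, H2).
#'
#' @param predictions Data frame with `plot_id` and one column per trait.
#' @param layout Data frame with `plot_id`, `genotype`, `row`, `col`.
#' @param traits Trait columns to analyse (default: all non-`plot_id`
#'   columns of `predictions`).
#' @param config A [mixed_model_config()].
#' @return List with `results` (named list of `blup_result`) and `summary`
#'   (data frame: trait, min, max, mean, std_error, h2).
#' @export
blup_pipeline <- function(predictions, layout, traits = NULL,
                          config = mixed_model_config()) {
  if (is.null(traits))
    traits <- setdiff(names(predictions), "plot_id")
  tab <- merge(layout, predictions, by = "plot_id")
  results <- list()
  rows <- list()
  for (tr in traits) {
    if (!tr %in% names(tab)) {
      warning("trait '", tr, "' missing from predictions; skipped")
      next
    }
    res <- fit_mixed_model(tab, tr, config)
    results[[tr]] <- res
    v <- tab[[tr]]
    rows[[tr]] <- data.frame(trait = tr, min = min(v), max = max(v),
                             mean = mean(v),
                             std_error = mean(sqrt(res$pev)),
                             h2 = as.numeric(res$h2))
  }
  list(results = results,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
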