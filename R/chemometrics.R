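#' PCA-guided reduction of a correlated vegetation-index set
#'
#' Vegetation indices are strongly collinear. The indices are standardised
#' (zero mean, unit variance) and a PCA is run; indices are then retained
#' greedily in decreasing order of their squared correlation-scale loading
#' sum on the first two components, dropping any candidate whose absolute
#' Pearson correlation with an already retained index exceeds
#' `cor_threshold`. Constant-valued indices are dropped with a warning.
#' Ties are broken lexicographically by index name.
#'
#' @param index_table Data frame or matrix of index values (plots x
#'   indices); a `plot_id` column is ignored.
#' @param cor_threshold Maximum absolute pairwise correlation among
#'   retained indices.
#' @return Character vector of retained index names, with attributes
#'   `var_explained` (percent variance of PCs 1-2) and `scores` (the
#'   ranking criterion per index).
#' @export
pca_index_subset <- function(index_table, cor_threshold = 0.9) {
  X <- as.data.frame(index_table)
  X$plot_id <- NULL
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 plots for PCA")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning("dropping constant-valued indices: ",
            paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", "))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(2, ncol(pca$rotation))
  # correlation-scale loadings: rotation scaled by component sd
  load2 <- sweep(pca$rotation[, 1:k, drop = FALSE], 2, pca$sdev[1:k], `*`)
  score <- rowSums(load2^2)
  var_explained <- 100 * sum(pca$sdev[1:k]^2) / sum(pca$sdev^2)
  cmat <- abs(stats::cor(X))
  ord <- order(-score, colnames(X))
  retained <- character(0)
  for (nm in colnames(X)[ord]) {
    if (length(retained) == 0 ||
        all(cmat[nm, retained] <= cor_threshold)) {
      retained <- c(retained, nm)
    }
  }
  structure(retained, var_explained = var_explained, scores = score)
}

#' Bidirectional stepwise multilinear regression by AIC
#'
#' Starting from the intercept-only ordinary-least-squares model, candidate
#' predictors are added and removed one at a time, each step taking the
#' single move with the largest AIC decrease, until no move decreases AIC
#' (Gaussian likelihood, penalty k = 2). Columns are offered in
#' lexicographic order so the search is deterministic.
#'
#' @param X Data frame or matrix of candidate predictors (e.g. a reduced
#'   vegetation-index set).
#' @param y Numeric response (one trait, one value per plot).
#' @return An object of class `stepwise_model`: `selected` (predictor
#'   names), `coefficients`, `aic`, `r2`, `rmse`, `p_value` (overall F
#'   test; NA for the intercept-only model), and the underlying `lm` fit.
#' @export
stepwise_aic <- function(X, y) {
  X <- as.data.frame(X)
  X$plot_id <- NULL
  X <- X[, order(colnames(X)), drop = FALSE]
  if (nrow(X) <= ncol(X) + 2)
    stop("need more plots than candidate indices + 2")
  d <- cbind(data.frame(.y = y), X)
  null_fit <- stats::lm(.y ~ 1, data = d)
  scope <- stats::as.formula(paste("~", paste(colnames(X), collapse = " + ")))
  fit <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                     direction = "both", k = 2, trace = 0)
  selected <- setdiff(names(stats::coef(fit)), "(Intercept)")
  sm <- summary(fit)
  p_value <- if (length(selected) == 0) NA_real_ else {
    f <- sm$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }
  structure(list(selected = selected, coefficients = stats::coef(fit),
                 aic = stats::AIC(fit), r2 = sm$r.squared,
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 p_value = unname(p_value), fit = fit),
            class = "stepwise_model")
}

#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  stats::predict(object$fit, newdata = newdata)
}

# PLS1 (univariate-response partial least squares) on centred data.
# Returns weights W, X-loadings P, y-loadings q, score norms and the
# fraction of X variance captured by each component. Stops early if the
# predictor matrix is exhausted (rank deficiency).
.pls1 <- function(X0, y0, K) {
  n <- nrow(X0); p <- ncol(X0)
  W <- matrix(0, p, K); P <- matrix(0, p, K)
  q <- numeric(K); ssx <- numeric(K)
  total_ss <- sum(X0^2)
  k_eff <- 0
  for (k in seq_len(K)) {
    w <- crossprod(X0, y0)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- X0 %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pk <- crossprod(X0, t) / tt
    qk <- sum(y0 * t) / tt
    X0 <- X0 - t %*% t(pk)
    y0 <- y0 - qk * t
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
    ssx[k] <- tt * sum(pk^2) / total_ss
    k_eff <- k
  }
  list(W = W[, seq_len(k_eff), drop = FALSE],
       P = P[, seq_len(k_eff), drop = FALSE],
       q = q[seq_len(k_eff)], ssx = ssx[seq_len(k_eff)], k_eff = k_eff)
}

# Regression coefficients (on the centred/scaled scale) for components 1..k
.pls1_coef <- function(core, k) {
  W <- core$W[, seq_len(k), drop = FALSE]
  P <- core$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), core$q[seq_len(k)]))
}

#' Full-spectrum partial least squares regression with LOOCV
#'
#' Fits PLS components 1..`max_latent` on the mean-centred spectra
#' (optionally unit-variance scaled) with a univariate trait response, and
#' selects the number of latent variables by the one-standard-error rule on
#' the leave-one-out cross-validated squared prediction error: the smallest
#' component count whose LOOCV MSEP is within one standard error of the
#' global minimum. Cross-validation treats the plot as the observational
#' unit: each plot is predicted from a model refit on all other plots.
#'
#' @param X Spectra matrix (plots x bands).
#' @param y Trait vector (one value per plot).
#' @param max_latent Cap on the number of latent variables considered.
#' @param scale If `TRUE`, scale bands to unit variance as well as centring.
#' @param r2_method `"cor"` (squared Pearson correlation of cross-validated
#'   predictions with observations) or `"ss"` (1 - SSE/SST).
#' @param trait Optional trait name stored in the model.
#' @return An object of class `c4_plsr`: centring/scaling vectors,
#'   coefficients and intercept at the selected `n_latent`, per-component
#'   LOOCV RMSEP, `cv_r2`, `cv_rmse`, `cv_rmse_pct`, cross-validated
#'   predictions, loadings of components 1-2 with percent X variance
#'   explained.
#' @export
fit_plsr <- function(X, y, max_latent = 25, scale = FALSE,
                     r2_method = c("cor", "ss"), trait = NULL) {
  r2_method <- match.arg(r2_method)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 plots to train a PLSR model")
  if (stats::sd(y) < 1e-12) stop("response is constant")
  K <- min(max_latent, n - 1, p)
  xbar <- colMeans(X)
  xsd <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(xsd == 0)) stop("constant band cannot be scaled")
  Xs <- sweep(sweep(X, 2, xbar), 2, xsd, `/`)
  ybar <- mean(y)

  # LOOCV prediction matrix: row i = plot i predicted at each component count
  cv_pred <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    xbar_i <- colMeans(Xi)
    xsd_i <- if (scale) apply(Xi, 2, stats::sd) else rep(1, p)
    if (any(xsd_i == 0)) xsd_i[xsd_i == 0] <- 1
    Xsi <- sweep(sweep(Xi, 2, xbar_i), 2, xsd_i, `/`)
    yi <- y[-i]
    core_i <- .pls1(Xsi, yi - mean(yi), K)
    x_new <- (X[i, ] - xbar_i) / xsd_i
    for (k in seq_len(core_i$k_eff)) {
      cv_pred[i, k] <- mean(yi) + sum(x_new * .pls1_coef(core_i, k))
    }
  }
  err2 <- (cv_pred - y)^2
  msep <- colMeans(err2)
  ok <- which(is.finite(msep))
  k_min <- ok[which.min(msep[ok])]
  se_min <- stats::sd(err2[, k_min]) / sqrt(n)
  n_latent <- min(ok[msep[ok] <= msep[k_min] + se_min])

  core <- .pls1(Xs, y - ybar, K)
  coefs <- .pls1_coef(core, min(n_latent, core$k_eff)) / xsd
  intercept <- ybar - sum(xbar * coefs)
  pred_cv <- cv_pred[, n_latent]
  cv_r2 <- if (r2_method == "cor") stats::cor(pred_cv, y)^2 else
    1 - sum((pred_cv - y)^2) / sum((y - ybar)^2)
  cv_rmse <- sqrt(mean((pred_cv - y)^2))

  structure(list(trait = trait, coefficients = coefs, intercept = intercept,
                 x_mean = xbar, x_sd = xsd, y_mean = ybar,
                 n_latent = n_latent, max_latent = K, scale = scale,
                 rmsep = sqrt(msep), cv_pred = pred_cv,
                 cv_r2 = cv_r2, cv_rmse = cv_rmse,
                 cv_rmse_pct = 100 * cv_rmse / ybar,
                 weights = core$W, loadings = core$P, y_loadings = core$q,
                 loadings_pc12 = core$P[, seq_len(min(2, core$k_eff)),
                                        drop = FALSE],
                 var_explained_pc12 = 100 * core$ssx[seq_len(min(2,
                                                                 core$k_eff))],
                 n_obs = n),
            class = "c4_plsr")
}

#' Coefficients of a fitted PLSR model at an arbitrary component count
#'
#' Returns the intercept and band coefficients (on the original reflectance
#' scale) of the model truncated to `ncomp` latent variables, without
#' refitting.
#'
#' @param model A [fit_plsr()] model.
#' @param ncomp Number of components (default: the selected `n_latent`).
#' @return Numeric vector: intercept followed by one coefficient per band.
#' @export
plsr_coefficients <- function(model, ncomp = model$n_latent) {
  if (ncomp < 1 || ncomp > ncol(model$weights))
    stop("ncomp out of range")
  core <- list(W = model$weights, P = model$loadings, q = model$y_loadings)
  coefs <- .pls1_coef(core, ncomp) / model$x_sd
  c(intercept = model$y_mean - sum(model$x_mean * coefs), coefs)
}

#' Predict traits from spectra with a fitted PLSR model
#'
#' Affine prediction using the stored centring and coefficients; no
#' refitting.
#'
#' @param object A [fit_plsr()] model.
#' @param newdata Spectra matrix with the model's bands in order.
#' @param ... Unused.
#' @return Numeric vector of trait predictions.
#' @export
predict.c4_plsr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("band count mismatch: model has ", length(object$coefficients),
         " bands, newdata has ", ncol(newdata))
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @rdname predict.c4_plsr
#' @param model A [fit_plsr()] model.
#' @param X_new Spectra matrix with the model's bands in order.
#' @export
predict_traits <- function(model, X_new) predict(model, X_new)

#' Leave-one-out cross-validation of an arbitrary estimator
#'
#' For each observation (plot) i, the estimator is fitted on all other
#' plots and used to predict plot i. Reported R2 is the squared Pearson
#' correlation between cross-validated predictions and observations (or
#' 1 - SSE/SST with `r2_method = "ss"`); RMSE is also expressed as a
#' percent of the response mean.
#'
#' @param X Predictor matrix or data frame (plots in rows).
#' @param y Response vector.
#' @param fit Function `(X, y) -> model`.
#' @param predict_fun Function `(model, X) -> predictions`.
#' @param r2_method See [fit_plsr()].
#' @return List with `predictions` (length `n`, input order), `r2`, `rmse`,
#'   `rmse_pct`, and `incomplete` (TRUE if any fold failed; failed folds
#'   are NA).
#' @export
loocv <- function(X, y, fit, predict_fun = stats::predict,
                  r2_method = c("cor", "ss")) {
  r2_method <- match.arg(r2_method)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations for leave-one-out")
  idx <- function(M, i) if (is.data.frame(M)) M[i, , drop = FALSE] else
    M[i, , drop = FALSE]
  preds <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- try(fit(idx(X, -i), y[-i]), silent = TRUE)
    if (inherits(m, "try-error")) next
    pr <- try(predict_fun(m, idx(X, i)), silent = TRUE)
    if (!inherits(pr, "try-error")) preds[i] <- as.numeric(pr)[1]
  }
  ok <- !is.na(preds)
  r2 <- if (r2_method == "cor") stats::cor(preds[ok], y[ok])^2 else
    1 - sum((preds[ok] - y[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
  rmse <- sqrt(mean((preds[ok] - y[ok])^2))
  list(predictions = preds, r2 = unname(r2), rmse = rmse,
       rmse_pct = 100 * rmse / mean(y[ok]), incomplete = any(!ok))
}
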