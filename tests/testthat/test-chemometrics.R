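test_that("PCA subsetting keeps one member per correlated cluster", {
  set.seed(5)
  # two perfect copies -> one retained
  a <- rnorm(50)
  tab <- data.frame(alpha = a, beta = a, gamma = rnorm(50))
  keep <- pca_index_subset(tab)
  expect_length(keep, 2)
  expect_true("gamma" %in% keep)
  expect_equal(sum(c("alpha", "beta") %in% keep), 1)

  # mutually orthogonal indices are all retained
  ortho <- as.data.frame(qr.Q(qr(matrix(rnorm(200 * 4), 200, 4))))
  names(ortho) <- c("a", "b", "c", "d")
  expect_setequal(as.character(pca_index_subset(ortho)), names(ortho))

  # three independent factors each driving a cluster of five indices
  f <- matrix(rnorm(300 * 3), 300, 3)
  cl <- do.call(cbind, lapply(1:3, function(k)
    sapply(1:5, function(j) f[, k] * (0.8 + 0.1 * j) + rnorm(300, 0, 0.01))))
  colnames(cl) <- paste0("i", sprintf("%02d", 1:15))
  keep3 <- pca_index_subset(as.data.frame(cl))
  expect_length(keep3, 3)
  cluster_of <- rep(1:3, each = 5)[match(keep3, colnames(cl))]
  expect_setequal(cluster_of, 1:3)

  # constant index dropped with warning
  expect_warning(pca_index_subset(data.frame(x = rnorm(30), k = 1)),
                 "constant")
})

test_that("stepwise AIC search recovers a planted predictor", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  names(X) <- c("cvi", "osavi", "pri", "red_edge", "tvi")
  y <- 3 + 2 * X$osavi + rnorm(200, 0, 1e-7)
  # step warns that the fit is essentially perfect, which is the point
  m <- suppressWarnings(stepwise_aic(X, y))
  expect_equal(m$selected, "osavi")
  expect_equal(unname(m$coefficients["osavi"]), 2, tolerance = 1e-3)
  expect_lt(m$p_value, 1e-10)
  # AIC of the chosen model never exceeds the intercept-only AIC
  null_aic <- stats::AIC(stats::lm(y ~ 1))
  expect_lte(m$aic, null_aic)
})

test_that("stepwise prediction matches the underlying linear model", {
  set.seed(16)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- 1 + 2 * X$a + rnorm(60, 0, 0.1)
  m <- stepwise_aic(X, y)
  newd <- data.frame(a = c(0, 1), b = c(5, -5))
  pred <- predict(m, newd)
  beta <- m$coefficients
  manual <- beta[["(Intercept)"]] +
    rowSums(vapply(m$selected, function(v) beta[[v]] * newd[[v]],
                   numeric(2)))
  expect_equal(unname(pred), unname(manual), tolerance = 1e-10)
})

test_that("PLSR equals OLS at full rank and nails an exact low-rank response", {
  set.seed(9)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% c(1, 2, -1, 0.5, 3)) + rnorm(30, 0, 0.1)
  m <- fit_plsr(X, y, max_latent = 5)
  ols <- stats::coef(stats::lm(y ~ X))
  expect_lt(max(abs(plsr_coefficients(m, 5) - ols)), 1e-8)

  # spectra and response generated by the same 3 latent factors
  scores <- matrix(rnorm(40 * 3), 40, 3)
  load3 <- matrix(rnorm(272 * 3), 272, 3)
  X3 <- scores %*% t(load3)
  y3 <- drop(scores %*% c(2, -1, 0.5))
  m3 <- fit_plsr(X3, y3)
  expect_lte(m3$n_latent, 3)
  expect_gte(m3$cv_r2, 0.999)
})

test_that("PLSR prediction is affine and centring-consistent", {
  set.seed(10)
  X <- random_spectra(25)
  y <- 50 + 10 * rowMeans(X[, 100:150]) + rnorm(25, 0, 0.01)
  m <- fit_plsr(X, y)
  # the training-mean spectrum predicts the training-mean response
  expect_equal(unname(predict(m, rbind(colMeans(X)))), mean(y),
               tolerance = 1e-8)
  # adding a band-wise constant to training and test leaves predictions
  # unchanged (centring removes it)
  m_shift <- fit_plsr(X + 0.7, y)
  expect_equal(predict(m_shift, X[1:5, ] + 0.7), predict(m, X[1:5, ]),
               tolerance = 1e-6)
  expect_error(predict(m, X[, 1:100]), "band count mismatch")
  expect_error(fit_plsr(X, rep(1, 25)), "constant")
})

test_that("leave-one-out matches a hand-computed three-point fit", {
  # mean-only estimator on three points: each prediction is the mean of the
  # other two
  X <- matrix(1, 3, 1)
  y <- c(1, 4, 10)
  res <- loocv(X, y,
               fit = function(X, y) mean(y),
               predict_fun = function(m, X) rep(m, nrow(X)))
  expect_equal(res$predictions, c(7, 5.5, 2.5), tolerance = 1e-10)
  expect_equal(res$rmse,
               sqrt(mean((c(7, 5.5, 2.5) - y)^2)), tolerance = 1e-10)
  expect_length(res$predictions, 3)
  expect_false(res$incomplete)
})

test_that("leave-one-out is exact on perfectly linear data", {
  X <- matrix(seq(1, 20), ncol = 1)
  y <- 2 + 3 * X[, 1]
  res <- loocv(as.data.frame(X), y,
               fit = function(X, y) stats::lm(y ~ V1,
                                              data = cbind(X, y = y)),
               predict_fun = function(m, X) stats::predict(m, X))
  expect_equal(res$r2, 1, tolerance = 1e-10)
  expect_lt(res$rmse, 1e-10)
})

test_that("PLSR agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- random_spectra(30)
  colnames(X) <- paste0("w", seq_len(ncol(X)))
  y <- 40 + 20 * rowMeans(X[, 140:160]) + rnorm(30, 0, 0.05)
  k <- 4
  m <- fit_plsr(X, y, max_latent = k)
  ref <- mixOmics::pls(X, y, ncomp = k, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, X[1:8, ])$predict[, 1, k]
  pred_own <- drop(X[1:8, ] %*% plsr_coefficients(m, k)[-1]) +
    plsr_coefficients(m, k)[1]
  expect_equal(unname(pred_own), unname(pred_ref), tolerance = 1e-6)
})
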