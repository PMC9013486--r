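test_that("nearest band lookup is exact, tied low, and range-checked", {
  w <- c(780, 799.1, 801.3, 810)
  expect_equal(nearest_band(w, 800), 2)
  expect_equal(nearest_band(w, 799.1), 2)
  expect_equal(nearest_band(c(798, 802), 800), 1)  # equidistant tie -> lower
  expect_error(nearest_band(w, 900), "outside")
})

test_that("pixel NDVI matches the direct formula", {
  w <- default_wavelengths()
  px <- matrix(0.2, 3, length(w))
  px[1, ] <- 0.1; px[1, nearest_band(w, 800)] <- 0.5
  px[2, ] <- 0.25; px[2, nearest_band(w, 800)] <- 0.3
  cube <- spectral_cube(px, w)
  nd <- pixel_ndvi(cube)
  expect_equal(nd[1], (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-4)
  expect_equal(nd[2], (0.3 - 0.25) / (0.3 + 0.25), tolerance = 1e-4)
  expect_equal(nd[3], 0)  # p800 == p670
  # all-zero pixel: denominator 0 -> NDVI defined as 0
  cube0 <- spectral_cube(matrix(0, 1, length(w)), w)
  expect_equal(pixel_ndvi(cube0), 0)
})

test_that("NDVI masking keeps exactly the constructed plant pixels", {
  w <- default_wavelengths()
  plant <- rep(0.1, length(w)); plant[w > 750] <- 0.5     # NDVI ~ 0.67
  soil <- rep(0.25, length(w)); soil[w > 750] <- 0.30     # NDVI ~ 0.09
  cube <- spectral_cube(rbind(t(replicate(10, plant)),
                              t(replicate(10, soil))), w, plot_id = "A")
  pr <- mask_and_average(cube, threshold = 0.5)
  expect_equal(pr$n_plant_pixels, 10)
  expect_equal(pr$n_total_pixels, 20)
  expect_equal(pr$reflectance, plant)
  expect_false(pr$empty)

  # all-soil cube is flagged empty
  soil_cube <- spectral_cube(t(replicate(5, soil)), w)
  expect_true(mask_and_average(soil_cube)$empty)

  # a pixel at exactly the threshold is excluded (strict >)
  half <- rep(0.2, length(w)); half[w >= 799] <- 0.6
  b670 <- nearest_band(w, 670); b800 <- nearest_band(w, 800)
  half[b670] <- 0.2; half[b800] <- 0.6  # NDVI = 0.5 exactly
  cube_half <- spectral_cube(rbind(half), w)
  expect_equal((half[b800] - half[b670]) / (half[b800] + half[b670]), 0.5)
  expect_true(mask_and_average(cube_half, threshold = 0.5)$empty)
})

test_that("masking is idempotent and order-invariant", {
  cfg <- generator_config(n_genotypes = 5, seed = 11)
  pt <- gen_plot_traits(gen_genotype_truth(cfg), gen_field_layout(cfg), cfg)
  cube <- simulate_cube(pt[1, ], cfg)
  pr1 <- mask_and_average(cube)
  keep <- pixel_ndvi(cube) > 0.5
  masked_cube <- spectral_cube(cube$pixels[keep, , drop = FALSE],
                               cube$wavelengths)
  pr2 <- mask_and_average(masked_cube)
  expect_equal(pr2$reflectance, pr1$reflectance)
  expect_equal(pr2$n_plant_pixels, pr1$n_plant_pixels)
  # permuting pixel order leaves the plot mean unchanged
  set.seed(1)
  perm <- sample(nrow(cube$pixels))
  pr3 <- mask_and_average(spectral_cube(cube$pixels[perm, ],
                                        cube$wavelengths))
  expect_equal(pr3$reflectance, pr1$reflectance)
})

test_that("vegetation indices match direct arithmetic on random spectra", {
  w <- default_wavelengths()
  band <- function(r, nm) r[which.min(abs(w - nm))]
  set.seed(8)
  X <- random_spectra(100, w)
  for (i in seq_len(nrow(X))) {
    r <- X[i, ]
    idx <- compute_indices(list(wavelengths = w, reflectance = r))
    expect_lt(abs(idx$Curvature -
                    band(r, 683)^2 / (band(r, 675) * band(r, 690))), 1e-10)
    expect_lt(abs(idx$CVI -
                    (band(r, 750) / band(r, 550)) *
                      (band(r, 670) / band(r, 550))), 1e-10)
    expect_lt(abs(idx$NDRE - (band(r, 750) - band(r, 710)) /
                    (band(r, 750) + band(r, 710))), 1e-10)
    expect_lt(abs(idx$NDVI - (band(r, 800) - band(r, 670)) /
                    (band(r, 800) + band(r, 670))), 1e-10)
    expect_lt(abs(idx$PRI - (band(r, 531) - band(r, 570)) /
                    (band(r, 531) + band(r, 570))), 1e-10)
    expect_lt(abs(idx$r685_r655 - band(r, 685) / band(r, 655)), 1e-10)
    expect_lt(abs(idx$r690_r600 - band(r, 690) / band(r, 600)), 1e-10)
    expect_lt(abs(idx$r740_r700 - band(r, 740) / band(r, 700)), 1e-10)
    expect_lt(abs(idx$r760_r750 - band(r, 760) / band(r, 750)), 1e-10)
    expect_lt(abs(idx$r760_r750index - (band(r, 760) - band(r, 750)) /
                    (band(r, 760) + band(r, 750))), 1e-10)
    expect_lt(abs(idx$Red_edge - band(r, 750) / band(r, 710)), 1e-10)
    expect_lt(abs(idx$OSAVI - 1.16 * (band(r, 800) - band(r, 670)) /
                    (band(r, 800) + band(r, 670) + 0.16)), 1e-10)
    expect_lt(abs(idx$r750 - band(r, 750)), 1e-10)
    expect_lt(abs(idx$r760 - band(r, 760)), 1e-10)
    expect_lt(abs(idx$TVI - 0.5 * (120 * (band(r, 750) - band(r, 550)) -
                                     200 * (band(r, 670) - band(r, 550)))),
              1e-10)
  }
})

test_that("flat spectra give the constant-spectrum index identities", {
  w <- default_wavelengths()
  idx <- compute_indices(list(wavelengths = w,
                              reflectance = rep(0.2, length(w))))
  expect_equal(idx$Curvature, 1)
  expect_equal(idx$CVI, 1)
  expect_equal(idx$NDRE, 0)
  expect_equal(idx$NDVI, 0)
  expect_equal(idx$PRI, 0)
  expect_equal(idx$Red_edge, 1)
  expect_equal(idx$r750, 0.2)
  expect_equal(idx$r760, 0.2)
  expect_equal(idx$TVI, 0)
})

test_that("PRI is antisymmetric under swapping its two bands", {
  w <- default_wavelengths()
  r <- rep(0.2, length(w))
  b531 <- nearest_band(w, 531); b570 <- nearest_band(w, 570)
  r[b531] <- 0.3; r[b570] <- 0.1
  pri1 <- compute_indices(list(wavelengths = w, reflectance = r))$PRI
  r[c(b531, b570)] <- r[c(b570, b531)]
  pri2 <- compute_indices(list(wavelengths = w, reflectance = r))$PRI
  expect_equal(pri1, -pri2)
})

test_that("zero denominators report the index as missing", {
  w <- default_wavelengths()
  r <- rep(0.2, length(w))
  r[nearest_band(w, 550)] <- 0
  idx <- compute_indices(list(wavelengths = w, reflectance = r))
  expect_true(is.na(idx$CVI))
  expect_false(is.na(idx$NDVI))
})
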