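test_that("genotype truth is deterministic, consistent and calibrated", {
  cfg <- generator_config(n_genotypes = 1000, seed = 4)
  t1 <- gen_genotype_truth(cfg)
  t2 <- gen_genotype_truth(cfg)
  expect_identical(t1, t2)
  # bookkeeping identity SLN = (%N/100) * LMA holds exactly
  expect_equal(t1$SLN, t1$percent_n / 100 * t1$LMA, tolerance = 1e-12)
  expect_true(all(t1[c("Vcmax", "Vpmax", "Jmax", "SLN", "LMA")] > 0))
  # configured means are matched at large n (z-test scale)
  expect_lt(abs(mean(t1$Vcmax) - 51.1), 2)
  expect_lt(abs(mean(t1$SLN) - 2.0), 3 * 0.2 / sqrt(1000))
  expect_lt(abs(sd(t1$Vcmax) - 5.5), 0.8)
  # zero genetic variance makes all genotypes identical
  cfg0 <- generator_config(n_genotypes = 10,
                           genetic_sd = c(Vcmax = 1e-12, Vpmax = 1e-12,
                                          Jmax = 1e-12, SLN = 1e-12,
                                          LMA = 1e-12), seed = 4)
  t0 <- gen_genotype_truth(cfg0)
  expect_lt(max(t0$Vcmax) - min(t0$Vcmax), 1e-6)
})

test_that("a non positive semi-definite trait correlation is rejected", {
  bad <- diag(5)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  traits <- c("Vcmax", "Vpmax", "Jmax", "SLN", "LMA")
  dimnames(bad) <- list(traits, traits)
  expect_error(generator_config(trait_cor = bad), "positive semi-definite")
})

test_that("field layouts have unique positions and the requested replication", {
  cfg <- generator_config(n_genotypes = 650, rep_fraction = 875 / 650 - 1,
                          seed = 2)
  lay <- gen_field_layout(cfg)
  expect_equal(nrow(lay), 875)
  expect_equal(length(unique(lay$genotype)), 650)
  expect_false(anyDuplicated(lay[, c("row", "col")]) > 0)
  expect_true(all(nchar(lay$genotype) > 0))
  # replication fraction 0 gives one plot per genotype
  lay0 <- gen_field_layout(generator_config(n_genotypes = 30,
                                            rep_fraction = 0, seed = 2))
  expect_equal(nrow(lay0), 30)
  expect_equal(anyDuplicated(lay0$genotype), 0)
})

test_that("noise-free simulated curves reproduce the forward model exactly", {
  cfg <- generator_config(n_genotypes = 3, curve_noise_cv = 0,
                          ci_jitter_sd = 0, seed = 6)
  pt <- gen_plot_traits(gen_genotype_truth(cfg), gen_field_layout(cfg), cfg)
  curves <- simulate_curves(pt, "both", cfg)
  one <- curves[curves$plot_id == pt$plot_id[1] & curves$kind == "ACi", ]
  expect_equal(one$Ca, c(200, 100, 50, 250, 400, 650, 800, 1000, 1200,
                         1400))
  p <- leaf_params(Vcmax = pt$Vcmax[1], Vpmax = pt$Vpmax[1],
                   Jmax = pt$Jmax[1], Rd = 2, theta = 0.3, PSabs = 0.35)
  expect_equal(one$A_obs, predict_curve(aci_protocol(), p)$A,
               tolerance = 1e-10)
  ai <- curves[curves$plot_id == pt$plot_id[1] & curves$kind == "Ai", ]
  expect_equal(ai$I_inc, ai_protocol()$I_inc)
  expect_equal(ai$A_obs[ai$I_inc == 0], -2, tolerance = 1e-8)
})

test_that("two seeds share the noise-free backbone but differ in noise", {
  cfg1 <- generator_config(n_genotypes = 2, seed = 8)
  pt <- gen_plot_traits(gen_genotype_truth(cfg1), gen_field_layout(cfg1),
                        cfg1)
  cfg2 <- cfg1; cfg2$seed <- 9
  c1 <- simulate_curves(pt, "aci", cfg1)
  c2 <- simulate_curves(pt, "aci", cfg2)
  expect_false(isTRUE(all.equal(c1$A_obs, c2$A_obs)))
  cfg1$curve_noise_cv <- 0; cfg1$ci_jitter_sd <- 0
  cfg2$curve_noise_cv <- 0; cfg2$ci_jitter_sd <- 0
  expect_equal(simulate_curves(pt, "aci", cfg1)$A_obs,
               simulate_curves(pt, "aci", cfg2)$A_obs)
})

test_that("simulated cubes separate plant and soil exactly at the mask", {
  cfg <- generator_config(n_genotypes = 4, pixels_per_plot = 40,
                          soil_fraction = 0.25, seed = 10)
  pt <- gen_plot_traits(gen_genotype_truth(cfg), gen_field_layout(cfg), cfg)
  cube <- simulate_cube(pt[1, ], cfg)
  pr <- mask_and_average(cube)
  expect_equal(pr$n_total_pixels, 40)
  expect_equal(pr$n_plant_pixels, 30)   # constructed membership recovered
  # soil fraction 0 keeps every pixel
  cfg0 <- cfg; cfg0$soil_fraction <- 0
  expect_equal(mask_and_average(simulate_cube(pt[1, ],
                                              cfg0))$n_plant_pixels, 40)
  # determinism per seed
  cube2 <- simulate_cube(pt[1, ], cfg)
  expect_identical(cube$pixels, cube2$pixels)
})

test_that("higher leaf nitrogen deepens the red trough of the endmember", {
  w <- default_wavelengths()
  z_lo <- c(Vcmax = 0, Vpmax = 0, Jmax = 0, SLN = -2, LMA = 0)
  z_hi <- c(Vcmax = 0, Vpmax = 0, Jmax = 0, SLN = 2, LMA = 0)
  b670 <- nearest_band(w, 670)
  lo <- c4spectra:::.plant_endmember(w, z_lo)
  hi <- c4spectra:::.plant_endmember(w, z_hi)
  expect_lt(hi[b670], lo[b670])
  # and LMA raises the NIR plateau
  z_lma <- c(Vcmax = 0, Vpmax = 0, Jmax = 0, SLN = 0, LMA = 2)
  b850 <- nearest_band(w, 850)
  expect_gt(c4spectra:::.plant_endmember(w, z_lma)[b850],
            c4spectra:::.plant_endmember(w, z_lo * 0)[b850])
})

test_that("curve and cube round trips are reproducible under one config", {
  cfg <- generator_config(n_genotypes = 6, seed = 123)
  tr1 <- simulate_trial(cfg)
  tr2 <- simulate_trial(cfg)
  expect_identical(tr1$reflectance, tr2$reflectance)
  expect_identical(tr1$plot_traits, tr2$plot_traits)
})
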