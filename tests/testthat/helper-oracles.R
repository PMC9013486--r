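# Independent brute-force oracle for the self-consistent assimilation rate:
# the residual arithmetic is written directly from the model equations
# (deliberately not calling the package internals) and the root is located
# by a dense grid scan for the first sign change followed by plain interval
# halving.
oracle_limited_A <- function(Ci, I_inc, params, consts, regime,
                             n_grid = 2001, n_halve = 60) {
  gamma_os <- consts$gamma_star * consts$Os * 1000
  k_co2 <- consts$Kc * (1 + consts$Os / consts$Ko)
  Rm <- consts$rm_ratio * params$Rd
  if (regime == "light") {
    I2 <- params$PSabs * I_inc
    bb <- I2 + params$Jmax
    Jt <- (bb - sqrt(bb^2 - 4 * params$theta * I2 * params$Jmax)) /
      (2 * params$theta)
  }
  f <- function(A) {
    Cm <- max(Ci - A / params$gm, 0)
    pump <- if (regime == "enzyme")
      Cm * params$Vpmax / (Cm + consts$Kp) else
        consts$x * Jt / consts$phi
    Cs <- max(Cm + (pump - A - Rm) / consts$gbs, 1e-9)
    demand <- if (regime == "enzyme")
      (Cs - gamma_os) * params$Vcmax / (Cs + k_co2) - params$Rd else
        ((1 - consts$x) * Jt / 3) * (1 - gamma_os / Cs) /
          (1 + 7 * gamma_os / (3 * Cs)) - params$Rd
    A - demand
  }
  lo <- -params$Rd - 1
  hi <- if (regime == "enzyme") params$Vcmax + 1 else Jt + 1
  grid <- seq(lo, hi, length.out = n_grid)
  fg <- vapply(grid, f, 0)
  i <- which(fg[-1] >= 0 & fg[-n_grid] < 0)[1]
  if (is.na(i)) return(if (fg[1] >= 0) grid[1] else grid[n_grid])
  a <- grid[i]; b <- grid[i + 1]
  for (k in seq_len(n_halve)) {
    m <- (a + b) / 2
    if (f(m) >= 0) b <- m else a <- m
  }
  (a + b) / 2
}

random_leaf_draw <- function() {
  list(params = leaf_params(Vcmax = runif(1, 20, 100),
                            Vpmax = runif(1, 50, 900),
                            Jmax = runif(1, 100, 800),
                            Rd = runif(1, 0.5, 4),
                            theta = runif(1, 0.1, 0.9),
                            PSabs = runif(1, 0.2, 0.5),
                            gm = runif(1, 0.5, 3)),
       Ca = runif(1, 50, 1400),
       ci_ratio = runif(1, 0.2, 0.9),
       I_inc = runif(1, 50, 2000))
}

# Simulate a plot's Ai + ACi curve pair directly from the forward model
make_curve_pair <- function(params, noise_cv = 0, noise_floor = 0.2) {
  ai <- predict_curve(ai_protocol(), params)
  aci <- predict_curve(aci_protocol(), params)
  d <- rbind(
    data.frame(plot_id = "p1", genotype = "g1", kind = "Ai",
               step = ai$step, A_obs = ai$A, Ca = ai$Ca, Ci = ai$Ci,
               I_inc = ai$I_inc),
    data.frame(plot_id = "p1", genotype = "g1", kind = "ACi",
               step = aci$step, A_obs = aci$A, Ca = aci$Ca, Ci = aci$Ci,
               I_inc = aci$I_inc))
  if (noise_cv > 0)
    d$A_obs <- d$A_obs * (1 + stats::rnorm(nrow(d), 0, noise_cv)) +
      stats::rnorm(nrow(d), 0, noise_floor)
  d
}

# Smooth random canopy-like spectra for chemometrics fixtures
random_spectra <- function(n, wavelengths = default_wavelengths()) {
  p <- length(wavelengths)
  t(vapply(seq_len(n), function(i) {
    base <- 0.05 + 0.4 / (1 + exp(-(wavelengths - 715) / 12))
    k <- stats::rnorm(6, 0, 0.02)
    centres <- c(450, 550, 670, 720, 800, 950)
    base + colSums(k * t(vapply(centres, function(cc)
      exp(-0.5 * ((wavelengths - cc) / 30)^2), numeric(p))))
  }, numeric(p)))
}

rel_err <- function(est, true) abs(est - true) / abs(true)
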