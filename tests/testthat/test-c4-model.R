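test_that("electron transport rate is the smaller quadratic root with the right limits", {
  # zero light and saturating light
  expect_equal(electron_transport_rate(0, 400, 0.3), 0)
  expect_equal(electron_transport_rate(1e9, 400, 0.3), 400, tolerance = 1e-4)

  # returned root satisfies the quadratic and respects the envelope
  Jt <- electron_transport_rate(500, 400, 0.3)
  expect_lt(abs(0.3 * Jt^2 - (500 + 400) * Jt + 500 * 400), 1e-9)
  expect_lte(Jt, min(500, 400))

  # strictly increasing in I2, bounded by min(I2, Jmax)
  I2 <- seq(10, 2000, by = 10)
  jt <- electron_transport_rate(I2, 400, 0.3)
  expect_true(all(diff(jt) > 0))
  expect_true(all(jt <= pmin(I2, 400) + 1e-12))
  expect_true(all(jt >= 0))

  # theta -> 0 limit is the rectangular hyperbola
  jt0 <- electron_transport_rate(I2, 400, 1e-4)
  hyp <- I2 * 400 / (I2 + 400)
  expect_lt(max(abs(jt0 - hyp) / hyp), 1e-3)

  expect_error(electron_transport_rate(-1, 400, 0.3), "non-negative")
  expect_error(electron_transport_rate(100, 400, 1.2), "theta")
})

test_that("limited-rate solvers agree with the brute-force oracle", {
  consts <- c4_constants()
  set.seed(42)
  for (i in 1:60) {
    d <- random_leaf_draw()
    env <- leaf_env(d$Ca, d$I_inc, ci_over_ca = d$ci_ratio)
    for (regime in c("enzyme", "light")) {
      got <- if (regime == "enzyme")
        enzyme_limited_A(env, d$params, consts) else
          light_limited_A(env, d$params, consts)
      want <- oracle_limited_A(env$Ci, d$I_inc, d$params, consts, regime)
      expect_equal(got, want, tolerance = 1e-6,
                   label = paste(regime, "draw", i))
    }
  }
})

test_that("degenerate parameter values collapse to -Rd", {
  consts <- c4_constants()
  p0 <- leaf_params(Vcmax = 0, Rd = 2)
  env <- leaf_env(400, 1800)
  expect_equal(enzyme_limited_A(env, p0, consts), -2, tolerance = 1e-7)
  nd <- net_assimilation(env, p0, consts, details = TRUE)
  expect_equal(nd$A, -2, tolerance = 1e-7)
  expect_equal(nd$regime, "enzyme")

  # darkness: light-limited rate equals -Rd
  p <- leaf_params(Rd = 1.7)
  expect_equal(light_limited_A(leaf_env(400, 0), p, consts), -1.7,
               tolerance = 1e-7)
})

test_that("assimilation is monotone in its driving variable", {
  consts <- c4_constants()
  p <- leaf_params(Vcmax = 51, Vpmax = 410, Jmax = 400)
  a_co2 <- enzyme_limited_A(leaf_env(seq(50, 1400, by = 50), 1800), p,
                            consts)
  expect_true(all(diff(a_co2) >= -1e-8))
  a_light <- light_limited_A(leaf_env(400, seq(0, 2000, by = 50)), p,
                             consts)
  expect_true(all(diff(a_light) >= -1e-8))
})

test_that("net assimilation is the minimum of the components and >= -Rd", {
  consts <- c4_constants()
  set.seed(7)
  for (i in 1:200) {
    d <- random_leaf_draw()
    env <- leaf_env(d$Ca, d$I_inc, ci_over_ca = d$ci_ratio)
    a <- net_assimilation(env, d$params, consts, details = TRUE)
    expect_lte(a$A, a$Ac + 1e-10)
    expect_lte(a$A, a$Aj + 1e-10)
    expect_equal(a$A, min(a$Ac, a$Aj))
    expect_gte(a$A, -d$params$Rd - 1e-6)
  }
})

test_that("solutions are self-consistent through the supply chain", {
  consts <- c4_constants()
  p <- leaf_params(Vcmax = 51, Vpmax = 410, Jmax = 400)
  env <- leaf_env(c(50, 200, 400, 1400), 1800)
  de <- enzyme_limited_A(env, p, consts, details = TRUE)
  expect_true(all(abs(de$residual) < 1e-8))
  # conservation: Cs rebuilt from the solution state matches
  Rm <- consts$rm_ratio * p$Rd
  cs_check <- pmax(de$Cm, 0) + (de$Vp - de$A - Rm) / consts$gbs
  expect_true(all(abs(de$Cs - cs_check) < 1e-8))
  dl <- light_limited_A(env, p, consts, details = TRUE)
  expect_true(all(abs(dl$residual) < 1e-8))
})

test_that("protocol prediction follows the measurement sequences", {
  p <- leaf_params(Vcmax = 51, Vpmax = 410, Jmax = 400, Rd = 2)
  aci <- predict_curve(aci_protocol(), p)
  expect_equal(nrow(aci), 10)
  expect_equal(aci$Ca, c(200, 100, 50, 250, 400, 650, 800, 1000, 1200,
                         1400))
  expect_true(all(aci$I_inc == 1800))
  # re-sorted ascending in CO2, the curve is non-decreasing
  expect_true(all(diff(aci$A[order(aci$Ca)]) >= -1e-8))

  ai <- predict_curve(ai_protocol(), p)
  expect_equal(ai$I_inc, c(2000, 1500, 1000, 500, 250, 120, 60, 30, 15, 0))
  expect_true(all(ai$Ca == 400))
  expect_equal(ai$A[10], -p$Rd, tolerance = 1e-7)

  expect_error(predict_curve(list(Ca = numeric(0)), p), "empty")
})

test_that("constants and parameter constructors validate their domains", {
  expect_error(c4_constants(Kc = -1), "positive")
  expect_error(c4_constants(x = 1.5), "x must")
  expect_error(leaf_params(theta = 1.2), "theta")
  expect_error(leaf_params(Vcmax = -5), "non-negative")
  expect_error(leaf_env(400, 1800, ci_over_ca = 1.5), "ci_over_ca")
})
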