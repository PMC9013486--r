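#' Configuration for response-curve fitting
#'
#' Bounds, multi-start behaviour and options of the two-stage inversion.
#' Stage one fits the light response (Ai) for `Jmax`, `theta`, `PSabs` and
#' `Rd`; stage two fits the CO2 response (ACi) for `Vcmax` and `Vpmax` with
#' the stage-one parameters held fixed. Optimisation is bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]) from `n_starts`
#' start points: the first is deterministic (defaults, with `Rd` anchored at
#' the dark step when present), the rest are drawn log-uniformly within the
#' bounds under `seed`. The best sum of squared errors wins; ties go to the
#' smaller parameter-vector norm.
#'
#' @param bounds Named list of `c(lower, upper)` for `Jmax`, `theta`,
#'   `PSabs`, `Rd`, `Vcmax`, `Vpmax`.
#' @param n_starts Number of optimiser starts (>= 1).
#' @param seed Seed for the start-point generator; fits are deterministic
#'   given (curve, config).
#' @param fix_theta `NULL` to fit the curvature factor, or a number (e.g.
#'   0.3) to hold it fixed at its conventional assumed value.
#' @param gm Mesophyll conductance held fixed during fitting
#'   (mol m-2 s-1 bar-1).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(Jmax = c(50, 1000), theta = c(0.05, 0.95),
                                     PSabs = c(0.05, 0.9), Rd = c(0, 10),
                                     Vcmax = c(5, 150), Vpmax = c(10, 1500)),
                       n_starts = 5, seed = 1, fix_theta = NULL, gm = 1,
                       maxiter = 60) {
  structure(list(bounds = bounds, n_starts = n_starts, seed = seed,
                 fix_theta = fix_theta, gm = gm, maxiter = maxiter),
            class = "fit_config")
}

.validate_curve <- function(curve, kind) {
  need <- c("A_obs", "Ca", "I_inc")
  if (!all(need %in% names(curve)))
    stop("curve must have columns A_obs, Ca, I_inc")
  if (nrow(curve) < 5) stop("need at least 5 steps to fit a curve")
  if (stats::sd(curve$A_obs) < 1e-8)
    stop("non-identifiable: observed assimilation is constant")
  if (is.null(curve$Ci) || all(is.na(curve$Ci)))
    curve$Ci <- curve$Ca * 0.4
  curve
}

# Multi-start bounded Levenberg-Marquardt on the residual vector
# A_obs - predicted(par). Returns the best fit across starts.
.multistart_lm <- function(residual_fun, start0, lower, upper, config) {
  n_par <- length(start0)
  starts <- matrix(NA_real_, config$n_starts, n_par,
                   dimnames = list(NULL, names(start0)))
  starts[1, ] <- pmin(pmax(start0, lower), upper)
  if (config$n_starts > 1) {
    rnd <- withr::with_seed(config$seed, {
      matrix(stats::runif((config$n_starts - 1) * n_par), ncol = n_par)
    })
    lo <- pmax(lower, 1e-3)
    starts[-1, ] <- t(exp(log(lo) + t(rnd) * (log(upper) - log(lo))))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], lower = lower, upper = upper, fn = residual_fun,
      control = minpack.lm::nls.lm.control(maxiter = config$maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 &&
         sum(unlist(fit$par)^2) < sum(unlist(best$par)^2))) {
      best <- list(par = fit$par, sse = sse, info = fit$info,
                   niter = fit$niter)
    }
  }
  if (is.null(best)) stop("optimiser failed on every start")
  best
}

#' Fit the light-response (Ai) stage
#'
#' Estimates `Jmax`, `theta` (unless fixed), `PSabs` and `Rd` by minimising
#' the sum of squared errors between observed assimilation and
#' [light_limited_A()] across the light steps. `Rd` is anchored by the dark
#' step (I = 0), where the model reduces to `A = -Rd`.
#'
#' When `enzyme_params` is supplied (Vcmax and Vpmax from a prior or from a
#' previous CO2-stage fit), the Ai stage instead minimises against the full
#' model `min(Ac, Aj)`: at saturating light the leaf can become
#' enzyme-limited, and ignoring that arm biases `Jmax` downward. The batch
#' fitter [fit_curves()] exploits this by alternating the two stages.
#'
#' @param curve Data frame of one Ai curve with columns `A_obs`, `Ca`,
#'   `I_inc` and optionally `Ci` (ubar).
#' @param consts A [c4_constants()] object.
#' @param config A [fit_config()] object.
#' @param enzyme_params Optional [leaf_params()] carrying `Vcmax`, `Vpmax`
#'   used to evaluate the enzyme-limited arm during the light fit; `NULL`
#'   fits the light-limited rate alone.
#' @return An object of class `fit_result` with elements `params`
#'   (a full [leaf_params()]), `sse`, `n_points`, `converged`, `outlier`
#'   (NA until [flag_outliers()]), `source_stage = "ai"`.
#' @export
fit_ai <- function(curve, consts = c4_constants(), config = fit_config(),
                   enzyme_params = NULL) {
  curve <- .validate_curve(curve, "Ai")
  fit_theta <- is.null(config$fix_theta)
  b <- config$bounds
  env <- leaf_env(curve$Ca, curve$I_inc, Ci = curve$Ci)
  vc <- if (is.null(enzyme_params)) 50 else enzyme_params$Vcmax
  vp <- if (is.null(enzyme_params)) 400 else enzyme_params$Vpmax

  make_params <- function(jmax, th, ps, rd) {
    leaf_params(Vcmax = vc, Vpmax = vp, Jmax = jmax, Rd = rd, theta = th,
                PSabs = ps, gm = config$gm)
  }
  resid_at <- function(jmax, th, ps, rd) {
    p <- make_params(jmax, th, ps, rd)
    pred <- if (is.null(enzyme_params)) light_limited_A(env, p, consts) else
      net_assimilation(env, p, consts)
    curve$A_obs - pred
  }
  # dark-step anchor for Rd, and a protocol anchor for Jmax: invert the
  # non-rectangular hyperbola at the brightest step, taking the gross
  # light-limited rate there as (1-x)/3 of Jt scaled by a typical
  # bundle-sheath oxygenation factor
  dark <- which(curve$I_inc == 0)
  rd0 <- if (length(dark)) max(0.1, -mean(curve$A_obs[dark])) else 1.5
  rd0 <- min(max(rd0, b$Rd[1]), b$Rd[2])
  anchor_jmax <- function(th) {
    I2_top <- 0.35 * max(curve$I_inc)
    jt_top <- 3 * (max(curve$A_obs) + rd0) / ((1 - consts$x) * 0.93)
    j0 <- if (jt_top < 0.95 * I2_top)
      jt_top * (I2_top - th * jt_top) / (I2_top - jt_top) else 400
    min(max(j0, b$Jmax[1]), b$Jmax[2])
  }
  run_lm <- function(start, lower, upper, fn) {
    fit <- try(minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
      fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = config$maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(par = unlist(fit$par), sse = sum(fit$fvec^2), info = fit$info)
  }
  pick <- function(a, b) {
    if (is.null(b)) return(a)
    if (is.null(a) || b$sse < a$sse - 1e-12 ||
        (abs(b$sse - a$sse) <= 1e-12 && sum(b$par^2) < sum(a$par^2))) b else a
  }
  lower3 <- c(b$Jmax[1], b$PSabs[1], b$Rd[1])
  upper3 <- c(b$Jmax[2], b$PSabs[2], b$Rd[2])
  fit3 <- function(th, start = NULL) {
    if (is.null(start))
      start <- c(Jmax = anchor_jmax(th), PSabs = 0.35, Rd = rd0)
    run_lm(start, lower3, upper3,
           function(par) resid_at(par[[1]], th, par[[2]], par[[3]]))
  }

  if (!fit_theta) {
    # fixed curvature: anchored start plus seeded random restarts
    th <- config$fix_theta
    best <- fit3(th)
    if (config$n_starts > 1) {
      rnd <- withr::with_seed(config$seed,
        matrix(stats::runif((config$n_starts - 1) * 3), ncol = 3))
      lo <- pmax(lower3, 1e-3)
      for (i in seq_len(nrow(rnd))) {
        st <- exp(log(lo) + rnd[i, ] * (log(upper3) - log(lo)))
        names(st) <- c("Jmax", "PSabs", "Rd")
        best <- pick(best, fit3(th, st))
      }
    }
    best_par <- c(best$par[["Jmax"]], th, best$par[["PSabs"]],
                  best$par[["Rd"]])
    best_info <- best$info; best_sse <- best$sse
  } else {
    # free curvature is weakly identified and multi-modal: profile over a
    # theta grid with the 3-parameter fit, then polish all four jointly
    thetas <- unique(pmin(pmax(c(0.1, 0.2, 0.3, 0.45, 0.6, 0.8),
                               b$theta[1]), b$theta[2]))
    prof <- NULL; prof_theta <- 0.3
    for (th in thetas) {
      cand <- fit3(th)
      if (!is.null(cand) && (is.null(prof) || cand$sse < prof$sse)) {
        prof <- cand; prof_theta <- th
      }
    }
    if (is.null(prof)) stop("optimiser failed on every start")
    lower4 <- c(b$Jmax[1], b$theta[1], b$PSabs[1], b$Rd[1])
    upper4 <- c(b$Jmax[2], b$theta[2], b$PSabs[2], b$Rd[2])
    start4 <- c(Jmax = prof$par[["Jmax"]], theta = prof_theta,
                PSabs = prof$par[["PSabs"]], Rd = prof$par[["Rd"]])
    fn4 <- function(par) resid_at(par[[1]], par[[2]], par[[3]], par[[4]])
    best <- run_lm(start4, lower4, upper4, fn4)
    if (is.null(best)) best <- list(par = start4, sse = prof$sse, info = 0)
    if (config$n_starts > 1) {
      rnd <- withr::with_seed(config$seed,
        matrix(stats::runif((config$n_starts - 1) * 4), ncol = 4))
      lo <- pmax(lower4, 1e-3)
      for (i in seq_len(nrow(rnd))) {
        st <- exp(log(lo) + rnd[i, ] * (log(upper4) - log(lo)))
        names(st) <- c("Jmax", "theta", "PSabs", "Rd")
        best <- pick(best, run_lm(st, lower4, upper4, fn4))
      }
    }
    best_par <- best$par
    best_info <- best$info; best_sse <- best$sse
  }

  # best_par is (Jmax, theta, PSabs, Rd) in both branches
  structure(list(params = make_params(best_par[[1]], best_par[[2]],
                                      best_par[[3]], best_par[[4]]),
                 sse = best_sse, n_points = nrow(curve),
                 converged = best_info %in% 1:3,
                 outlier = NA, source_stage = "ai",
                 plot_id = curve$plot_id[1], genotype = curve$genotype[1]),
            class = "fit_result")
}

#' Fit the CO2-response (ACi) stage
#'
#' Estimates `Vcmax` and `Vpmax` by minimising the sum of squared errors
#' between observed assimilation and [net_assimilation()] (the minimum of
#' both regimes) across the CO2 steps, with `Jmax`, `theta`, `PSabs` and
#' `Rd` fed forward from the Ai-stage fit and held fixed. Low-CO2 steps
#' carry the `Vpmax` signal (the initial-slope region); saturating steps
#' carry `Vcmax`.
#'
#' @param curve Data frame of one ACi curve (columns as in [fit_ai()]).
#' @param ai_fit The `fit_result` from [fit_ai()] for the same plot.
#' @param consts A [c4_constants()] object.
#' @param config A [fit_config()] object.
#' @return A `fit_result` with `source_stage = "aci"`; its `params` carry
#'   the fitted `Vcmax`, `Vpmax` together with the fixed stage-one values.
#' @export
fit_aci <- function(curve, ai_fit, consts = c4_constants(),
                    config = fit_config()) {
  curve <- .validate_curve(curve, "ACi")
  if (sum(curve$Ci < 150) < 2)
    warning("fewer than 2 steps below 150 ubar: Vpmax weakly identified")
  b <- config$bounds
  lower <- c(b$Vcmax[1], b$Vpmax[1])
  upper <- c(b$Vcmax[2], b$Vpmax[2])
  env <- leaf_env(curve$Ca, curve$I_inc, Ci = curve$Ci)
  fixed <- ai_fit$params

  make_params <- function(par) {
    leaf_params(Vcmax = par[["Vcmax"]], Vpmax = par[["Vpmax"]],
                Jmax = fixed$Jmax, Rd = fixed$Rd, theta = fixed$theta,
                PSabs = fixed$PSabs, gm = config$gm)
  }
  residual_fun <- function(par) {
    curve$A_obs - net_assimilation(env, make_params(par), consts)
  }
  start0 <- c(Vcmax = 50, Vpmax = 400)
  best <- .multistart_lm(residual_fun, start0, lower, upper, config)

  structure(list(params = make_params(best$par), sse = best$sse,
                 n_points = nrow(curve), converged = best$info %in% 1:3,
                 outlier = NA, source_stage = "aci",
                 plot_id = curve$plot_id[1], genotype = curve$genotype[1]),
            class = "fit_result")
}

#' Two-stage fit of all curves in a long table
#'
#' Splits a long curve table (one row per measurement step) by plot and
#' runs the two-stage inversion per plot: the light (Ai) stage for `Jmax`,
#' `theta`, `PSabs`, `Rd` ([fit_ai()], with the enzyme arm evaluated at
#' prior values Vcmax 50, Vpmax 400), then the CO2 (ACi) stage for
#' `Vcmax`, `Vpmax` ([fit_aci()]). Because the light parameters also shape
#' the CO2 curve (its plateau can be electron-transport limited) and the
#' enzyme parameters can clip the brightest light steps, the two parameter
#' blocks are then refined by block coordinate descent on the joint sum of
#' squares over both curves: the light block and the enzyme block are
#' re-optimised in turn, each against all 20 points, until the joint SSE
#' stops improving or `n_cycles` is reached. The blocks are never merged
#' into a single six-parameter fit.
#'
#' @param curves Long data frame with columns `plot_id`, `genotype`, `kind`
#'   (`"ACi"`/`"Ai"`), `step`, `A_obs`, `Ca`, `Ci`, `I_inc`.
#' @param consts A [c4_constants()] object.
#' @param config A [fit_config()] object.
#' @param n_cycles Maximum number of refinement cycles after the initial
#'   two-stage pass.
#' @return Data frame with one row per plot: fitted `Vcmax`, `Vpmax`,
#'   `Jmax`, `Rd`, `theta`, `PSabs`, per-curve SSEs and a convergence
#'   flag.
#' @export
fit_curves <- function(curves, consts = c4_constants(),
                       config = fit_config(), n_cycles = 6) {
  out <- lapply(split(curves, curves$plot_id), function(d) {
    ai <- d[d$kind == "Ai", , drop = FALSE]
    aci <- d[d$kind == "ACi", , drop = FALSE]
    if (nrow(ai) == 0 || nrow(aci) == 0) return(NULL)
    fa <- try(fit_ai(ai, consts, config,
                     enzyme_params = .enzyme_prior(ai, aci, consts, config)),
              silent = TRUE)
    if (inherits(fa, "try-error")) return(NULL)
    fc <- try(fit_aci(aci, fa, consts, config), silent = TRUE)
    if (inherits(fc, "try-error")) return(NULL)
    p <- .refine_joint(ai, aci, fc$params, consts, config, n_cycles)

    env_ai <- leaf_env(ai$Ca, ai$I_inc, Ci = ai$Ci)
    env_aci <- leaf_env(aci$Ca, aci$I_inc, Ci = aci$Ci)
    sse_ai <- sum((ai$A_obs - net_assimilation(env_ai, p, consts))^2)
    sse_aci <- sum((aci$A_obs - net_assimilation(env_aci, p, consts))^2)
    # Vcmax identifiability diagnostic: the gap Aj - Ac at the most
    # CO2-saturated step. If the electron-transport arm caps the whole CO2
    # curve (margin <= 0) the data never express Vcmax.
    i_top <- which.max(env_aci$Ca)
    top <- net_assimilation(env_aci[i_top, , drop = FALSE], p, consts,
                            details = TRUE)
    data.frame(plot_id = d$plot_id[1], genotype = d$genotype[1],
               Vcmax = p$Vcmax, Vpmax = p$Vpmax, Jmax = p$Jmax, Rd = p$Rd,
               theta = p$theta, PSabs = p$PSabs,
               sse_ai = sse_ai, sse_aci = sse_aci,
               vcmax_margin = top$Aj - top$Ac,
               converged = fa$converged && fc$converged)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Closed-form enzyme prior from the CO2 curve, used so the first light-stage
# fit evaluates the enzyme-limited arm near its true level: the CO2-saturated
# plateau approximates Vcmax - Rd (bundle-sheath CO2 is large there), and the
# lowest-Ci step approximates the PEP-limited rate Vp - Rm.
.enzyme_prior <- function(ai, aci, consts, config) {
  b <- config$bounds
  dark <- which(ai$I_inc == 0)
  rd0 <- if (length(dark)) max(0.1, -mean(ai$A_obs[dark])) else 1.5
  vc0 <- (max(aci$A_obs) + rd0) / 0.95
  ci <- if (!is.null(aci$Ci) && !all(is.na(aci$Ci))) aci$Ci else
    0.4 * aci$Ca
  i_lo <- which.min(ci)
  a_lo <- aci$A_obs[i_lo]
  cm_lo <- max(ci[i_lo] - a_lo / config$gm, 2)
  vp_lo <- max(a_lo + consts$rm_ratio * rd0, 1)
  vp0 <- vp_lo * (cm_lo + consts$Kp) / cm_lo
  leaf_params(Vcmax = min(max(vc0, b$Vcmax[1]), b$Vcmax[2]),
              Vpmax = min(max(vp0, b$Vpmax[1]), b$Vpmax[2]))
}

# Block coordinate descent on the joint (Ai + ACi) sum of squares: light
# block (Jmax, theta unless fixed, PSabs, Rd) then enzyme block
# (Vcmax, Vpmax), each bounded Levenberg-Marquardt from the current point.
.refine_joint <- function(ai, aci, params, consts, config, n_cycles) {
  env_ai <- leaf_env(ai$Ca, ai$I_inc, Ci = ai$Ci)
  env_aci <- leaf_env(aci$Ca, aci$I_inc, Ci = aci$Ci)
  obs <- c(ai$A_obs, aci$A_obs)
  fit_theta <- is.null(config$fix_theta)
  b <- config$bounds
  joint_resid <- function(p) {
    obs - c(net_assimilation(env_ai, p, consts),
            net_assimilation(env_aci, p, consts))
  }
  set_light <- function(p, lp) {
    p$Jmax <- lp[[1]]
    if (fit_theta) p$theta <- lp[[2]]
    p$PSabs <- lp[[if (fit_theta) 3 else 2]]
    p$Rd <- lp[[if (fit_theta) 4 else 3]]
    p
  }
  l_lower <- c(b$Jmax[1], if (fit_theta) b$theta[1], b$PSabs[1], b$Rd[1])
  l_upper <- c(b$Jmax[2], if (fit_theta) b$theta[2], b$PSabs[2], b$Rd[2])
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(config$maxiter, 20))
  par_vec <- function(p) c(p$Vcmax, p$Vpmax, p$Jmax, p$Rd, p$theta, p$PSabs)
  set_par_vec <- function(p, v) {
    p$Vcmax <- v[1]; p$Vpmax <- v[2]; p$Jmax <- v[3]; p$Rd <- v[4]
    p$theta <- v[5]; p$PSabs <- v[6]
    p
  }
  v_lower <- c(b$Vcmax[1], b$Vpmax[1], b$Jmax[1], b$Rd[1], b$theta[1],
               b$PSabs[1])
  v_upper <- c(b$Vcmax[2], b$Vpmax[2], b$Jmax[2], b$Rd[2], b$theta[2],
               b$PSabs[2])
  sse <- sum(joint_resid(params)^2)
  prev_vec <- NULL
  for (cy in seq_len(n_cycles)) {
    # the curvature factor is multi-modal: on early cycles profile it over
    # a grid, re-optimising (Jmax, PSabs, Rd) at each value, before the
    # full light-block polish
    if (fit_theta && cy <= 2) {
      for (th in c(0.1, 0.2, 0.3, 0.45, 0.6, 0.8)) {
        f3 <- try(minpack.lm::nls.lm(
          c(params$Jmax, params$PSabs, params$Rd),
          lower = c(b$Jmax[1], b$PSabs[1], b$Rd[1]),
          upper = c(b$Jmax[2], b$PSabs[2], b$Rd[2]),
          fn = function(lp3) {
            p2 <- params
            p2$Jmax <- lp3[[1]]; p2$theta <- th
            p2$PSabs <- lp3[[2]]; p2$Rd <- lp3[[3]]
            joint_resid(p2)
          }, control = ctrl), silent = TRUE)
        if (!inherits(f3, "try-error") && sum(f3$fvec^2) < sse) {
          lp3 <- unlist(f3$par)
          params$Jmax <- lp3[1]; params$theta <- th
          params$PSabs <- lp3[2]; params$Rd <- lp3[3]
          sse <- sum(f3$fvec^2)
        }
      }
    }
    lp0 <- c(params$Jmax, if (fit_theta) params$theta, params$PSabs,
             params$Rd)
    fl <- try(minpack.lm::nls.lm(lp0, lower = l_lower, upper = l_upper,
      fn = function(lp) joint_resid(set_light(params, lp)), control = ctrl),
      silent = TRUE)
    if (!inherits(fl, "try-error") && sum(fl$fvec^2) < sse) {
      params <- set_light(params, unlist(fl$par))
      sse <- sum(fl$fvec^2)
    }
    fe <- try(minpack.lm::nls.lm(c(params$Vcmax, params$Vpmax),
      lower = c(b$Vcmax[1], b$Vpmax[1]), upper = c(b$Vcmax[2], b$Vpmax[2]),
      fn = function(ep) {
        p2 <- params; p2$Vcmax <- ep[[1]]; p2$Vpmax <- ep[[2]]
        joint_resid(p2)
      }, control = ctrl), silent = TRUE)
    sse_new <- sse
    if (!inherits(fe, "try-error") && sum(fe$fvec^2) < sse) {
      params$Vcmax <- unlist(fe$par)[1]
      params$Vpmax <- unlist(fe$par)[2]
      sse_new <- sum(fe$fvec^2)
    }
    # the block updates zigzag slowly along the (Rd, Vcmax) valley;
    # geometric extrapolation along the last cycle's step accelerates the
    # linear-rate tail
    cur_vec <- par_vec(params)
    if (!is.null(prev_vec)) {
      step <- cur_vec - prev_vec
      for (w in c(2, 4, 8, 16)) {
        cand <- pmin(pmax(cur_vec + w * step, v_lower), v_upper)
        if (!fit_theta) cand[5] <- params$theta
        sse_cand <- sum(joint_resid(set_par_vec(params, cand))^2)
        if (sse_cand < sse_new) {
          params <- set_par_vec(params, cand)
          sse_new <- sse_cand
          cur_vec <- cand
        } else break
      }
    }
    prev_vec <- cur_vec
    if ((sse - sse_new) < 1e-12 * (1 + sse_new) && cy > 1) break
    sse <- sse_new
  }
  params
}

#' Flag extreme fitted parameters as outliers
#'
#' Applies the per-trait exclusion rules `Vcmax > 65`, `Vpmax > 750` and
#' `Jmax > 700` umol m-2 s-1 (strict inequalities). Each trait keeps its own
#' valid set: the per-trait flags mark which trait's analyses must drop the
#' plot, and `outlier` is their union.
#'
#' @param fits Data frame of fitted parameters (e.g. from [fit_curves()])
#'   with columns `Vcmax`, `Vpmax`, `Jmax`.
#' @param thresholds Named vector of strict upper thresholds.
#' @return `fits` with added logical columns `outlier_vcmax`,
#'   `outlier_vpmax`, `outlier_jmax` and `outlier`.
#' @export
#' @examples
#' flag_outliers(data.frame(Vcmax = c(60, 66), Vpmax = c(700, 200),
#'                          Jmax = c(650, 710)))
flag_outliers <- function(fits,
                          thresholds = c(Vcmax = 65, Vpmax = 750,
                                         Jmax = 700)) {
  if (nrow(fits) == 0) {
    fits$outlier_vcmax <- logical(0)
    fits$outlier_vpmax <- logical(0)
    fits$outlier_jmax <- logical(0)
    fits$outlier <- logical(0)
    return(fits)
  }
  fits$outlier_vcmax <- fits$Vcmax > thresholds[["Vcmax"]]
  fits$outlier_vpmax <- fits$Vpmax > thresholds[["Vpmax"]]
  fits$outlier_jmax <- fits$Jmax > thresholds[["Jmax"]]
  fits$outlier <- fits$outlier_vcmax | fits$outlier_vpmax | fits$outlier_jmax
  fits
}
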