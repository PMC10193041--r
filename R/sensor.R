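# The online tracker: a stimulation-blind model fitted to an initial block
# of RTs, then run as a trial-by-trial filter whose expected-RT output is
# the outcome the optimizers consume.

#' Fit a sensor to an initial block of trials
#'
#' Fits the reduced model `(alpha_offset, v, b0)` by [em_fit()] under the
#' sensor constraints: no stimulation input, state-noise SDs drawn from the
#' grid scales `[7, 12]` / `[13, 27]` and then inflated by adding 0.0625
#' (the scale-8 SD) so the blind filter adapts faster when stimulation
#' pushes a state away from its AR(1) habit, and the RT offset bounded below
#' at 0.1 s to accommodate a wide range of generators.
#'
#' @param initial_trials Trial-log `data.frame` used for fitting (typically
#'   one 64-trial task block).
#' @param scale1_range,scale2_range Scale ranges for the noise draw.
#' @param noise_inflation SD added to both drawn sigmas.
#' @param alpha_lb,alpha_ub Bounds on the fitted RT offset, seconds.
#'   Population-plausible limits: without them the EM can absorb a
#'   participant's overall speed into the offset, which distorts the state
#'   estimate's scale.
#' @param b0_anchor Population-typical value of `b0` used to initialize the
#'   fit. The latent level is identified only jointly with `b0`; anchoring
#'   `b0` at the population value makes the sensor's state estimate land on
#'   the same scale as the generating states rather than an arbitrary
#'   per-fit offset (the same kind of cross-participant calibration as the
#'   fixed noise ranges and the 0.1 s offset bound).
#' @param max_iter EM iteration cap.
#' @return An object of class `"sensor_state"`: fitted parameters, the drawn
#'   and inflated sigmas, and the current filtered mean/covariance of the
#'   two latent states (initialized from the fit's end-of-block filter).
#' @export
fit_sensor <- function(initial_trials,
                       scale1_range = c(7, 12), scale2_range = c(13, 27),
                       noise_inflation = 0.0625, alpha_lb = 0.1,
                       alpha_ub = 0.3, b0_anchor = mean(log(c(0.4, 0.8))),
                       max_iter = 25) {
  s1_drawn <- scale_to_sigma(stats::runif(1, scale1_range[1], scale1_range[2]))
  s2_drawn <- scale_to_sigma(stats::runif(1, scale2_range[1], scale2_range[2]))
  spec <- fit_spec(sigma1 = s1_drawn + noise_inflation,
                   sigma2 = s2_drawn + noise_inflation,
                   alpha_lb = alpha_lb, alpha_ub = alpha_ub,
                   max_iter = max_iter,
                   x0 = stats::rnorm(2), b0_init = b0_anchor)
  fit <- suppressWarnings(em_fit(initial_trials, spec))
  fl <- fit$trajectory$filtered
  last <- nrow(fl)
  structure(list(params = fit$params,
                 sigma_drawn = c(s1_drawn, s2_drawn),
                 sigma_inflated = c(fit$params$sigma1, fit$params$sigma2),
                 m = c(fl$x_base[last], fl$x_conflict[last]),
                 P = matrix(c(fl$var_base[last], fl$cov[last],
                              fl$cov[last], fl$var_conflict[last]), 2, 2),
                 n_seen = nrow(initial_trials),
                 n_clipped = 0L,
                 fit = fit),
            class = "sensor_state")
}

#' @export
print.sensor_state <- function(x, ...) {
  cat(sprintf("<sensor_state> alpha = %.3f, v = %.2f, b0 = %.3f; %d trials seen\n",
              x$params$alpha_offset, x$params$v, x$params$b0, x$n_seen))
  invisible(x)
}

#' One online filtering step of the sensor
#'
#' Predict-update step for a single observed trial (no stimulation input;
#' the sensor is stimulation-blind). An RT at or below the fitted offset
#' cannot occur under the model; its update is skipped (innovation clipped)
#' and counted in `n_clipped`.
#'
#' @param sensor A [fit_sensor()] result.
#' @param rt Observed reaction time, seconds.
#' @param I_conflict Conflict indicator for the trial, 0 or 1.
#' @return List with the updated `sensor` and `estimate`: the smoothed
#'   expected RT for the trial (`rt_pred`, using its conflict indicator),
#'   the conflict-free expected RT (`rt_base`, the outcome fed to the
#'   optimizers), and the filtered state means `x_base`, `x_conflict`.
#' @export
sensor_step <- function(sensor, rt, I_conflict) {
  p <- sensor$params
  a1 <- p$a1; a2 <- p$a2
  m <- sensor$m; P <- sensor$P
  pm1 <- a1 * m[1]; pm2 <- a2 * m[2]
  pP11 <- a1 * a1 * P[1, 1] + p$sigma1^2
  pP12 <- a1 * a2 * P[1, 2]
  pP22 <- a2 * a2 * P[2, 2] + p$sigma2^2
  y <- rt - p$alpha_offset
  clipped <- !(is.finite(y) && y > 0)
  if (!clipped) {
    c1 <- p$b1; c2 <- p$b2 * I_conflict
    eta0 <- p$b0 + c1 * pm1 + c2 * pm2
    q <- c1 * c1 * pP11 + 2 * c1 * c2 * pP12 + c2 * c2 * pP22
    eu <- .eta_update(eta0, q, y, p$v)
    t_sc <- eu[1]; f <- (1 - eu[2]) / q
    Pc1 <- pP11 * c1 + pP12 * c2
    Pc2 <- pP12 * c1 + pP22 * c2
    m1 <- pm1 + Pc1 * t_sc; m2 <- pm2 + Pc2 * t_sc
    P11 <- pP11 - f * Pc1 * Pc1
    P12 <- pP12 - f * Pc1 * Pc2
    P22 <- pP22 - f * Pc2 * Pc2
  } else {
    m1 <- pm1; m2 <- pm2; P11 <- pP11; P12 <- pP12; P22 <- pP22
  }
  sensor$m <- c(m1, m2)
  sensor$P <- matrix(c(P11, P12, P12, P22), 2, 2)
  sensor$n_seen <- sensor$n_seen + 1L
  sensor$n_clipped <- sensor$n_clipped + as.integer(clipped)
  mu_base <- exp(p$b0 + p$b1 * m1)
  mu_trial <- exp(p$b0 + p$b1 * m1 + p$b2 * I_conflict * m2)
  list(sensor = sensor,
       estimate = c(rt_pred = p$alpha_offset + mu_trial,
                    rt_base = p$alpha_offset + mu_base,
                    x_base = m1, x_conflict = m2))
}

#' Track a whole session with a sensor
#'
#' Convenience wrapper: the trials the sensor was fitted on are covered by
#' the fit's own smoothed trajectory (the fitting block is processed offline
#' by EM, so full-block smoothing is available there); every later trial is
#' pushed through the online [sensor_step()] filter. Returns the per-trial
#' estimate series used in tracking validation.
#'
#' @param sensor A [fit_sensor()] result.
#' @param trials Full-session trial log whose first `n_fitted` rows are the
#'   fitting block.
#' @param n_fitted Number of leading trials already consumed by the fit
#'   (defaults to the sensor's count at fit time).
#' @return `data.frame` with per-trial `x_base`, `x_conflict`, `rt_pred`,
#'   `rt_base` estimates.
#' @export
sensor_track <- function(sensor, trials, n_fitted = sensor$n_seen) {
  n <- nrow(trials)
  stopifnot(n_fitted <= n)
  p <- sensor$params
  fl <- sensor$fit$trajectory$smoothed
  out <- data.frame(x_base = numeric(n), x_conflict = numeric(n),
                    rt_pred = numeric(n), rt_base = numeric(n))
  idx <- seq_len(n_fitted)
  out$x_base[idx] <- fl$x_base
  out$x_conflict[idx] <- fl$x_conflict
  out$rt_pred[idx] <- fl$rt_pred
  out$rt_base[idx] <- p$alpha_offset + exp(p$b0 + p$b1 * fl$x_base)
  if (n > n_fitted) for (k in (n_fitted + 1):n) {
    stp <- sensor_step(sensor, trials$rt_s[k], trials$conflict[k])
    sensor <- stp$sensor
    out$x_base[k] <- stp$estimate[["x_base"]]
    out$x_conflict[k] <- stp$estimate[["x_conflict"]]
    out$rt_pred[k] <- stp$estimate[["rt_pred"]]
    out$rt_base[k] <- stp$estimate[["rt_base"]]
  }
  out
}

#' Normalized root-mean-square tracking error
#'
#' Each series is rescaled multiplicatively to the `[-1, 1]` interval
#' (divided by its own maximum absolute value), then the RMSE of the
#' difference is taken. The rescale makes the metric invariant to pure gain
#' differences: it scores whether the estimate moves in the same direction
#' and relative scale as the truth.
#'
#' @param truth,estimate Equal-length numeric series (length >= 2).
#' @return Scalar NRMSE, >= 0.
#' @export
#' @examples
#' nrmse(c(1, 2, 3), c(2, 4, 6))  # 0: pure gain error
nrmse <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 2)
  mt <- max(abs(truth)); me <- max(abs(estimate))
  if (mt == 0 || me == 0)
    stop("nrmse: all-zero series; multiplicative rescale undefined")
  sqrt(mean((truth / mt - estimate / me)^2))
}
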