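#' stimbandit: closed-loop bandit optimization of stimulation sites
#'
#' A simulation testbed for selecting the best deep-brain-stimulation contact
#' from its effect on cognitive-control behavior. Reaction times (RTs) on a
#' conflict task are modeled as an offset-gamma observation of two latent
#' AR(1) "cognitive states"; a stimulation-blind state-space sensor tracks
#' those states online, and multi-armed-bandit algorithms allocate stimulation
#' blocks to sites to find the one that most lowers the baseline state.
#'
#' @section Main entry points:
#' * [generator_params()], [simulate_session()] -- synthetic participants
#' * [fit_sensor()], [sensor_step()] -- the online tracker
#' * [em_fit()], [grid_search_w()] -- model estimation
#' * [run_closed_loop()], [run_sweep()], [run_ensemble()] -- experiments
#'
#' @keywords internal
#' @aliases stimbandit-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# Observation model: RT ~ alpha + Gamma(shape = v, rate = v / mu), so that
# E[RT] = alpha + mu, Var[RT] = mu^2 / v (1/v is the dispersion), and
# log(mu) = b0 + b1 * x_base + b2 * I_conflict * x_conflict.
# ---------------------------------------------------------------------------

#' Parameter set for one simulated participant
#'
#' Bundles the observation parameters (offset `alpha_offset`, dispersion
#' parameter `v`, link coefficients `b0`, `b1`, `b2`), the AR(1) state
#' dynamics (`a1`, `a2`, state-noise SDs `sigma1`, `sigma2`), the per-site
#' stimulation effects and the initial latent states.
#'
#' Stimulation effects are steady-state shifts of the baseline state
#' `x_base`, in log-seconds; the effect on the conflict state is ten-fold
#' smaller (`b_in_conflict = b_in_base / 10` when built from a response
#' surface). The approach to steady state is first-order with retention
#' `rho` per trial, so a constant input settles within roughly
#' 5--10 trials at the default `rho = 0.7`.
#'
#' @param alpha_offset RT lower bound, seconds (>= 0).
#' @param v Dispersion parameter (> 0); `1/v` is the squared coefficient of
#'   variation of the gamma part.
#' @param b0,b1,b2 Link coefficients on the log-seconds scale.
#' @param a1,a2 AR(1) coefficients for `x_base` and `x_conflict`, in `[0, 1]`.
#' @param sigma1,sigma2 State-noise standard deviations (>= 0).
#' @param b_in_base Numeric vector of per-site steady-state effects on
#'   `x_base` (log-seconds); length = number of stimulation sites. May be
#'   empty for a stimulation-free participant.
#' @param b_in_conflict Per-site effects on `x_conflict`; defaults to
#'   `b_in_base / 10`.
#' @param x0_base,x0_conflict Initial latent states.
#' @param rho Per-trial retention of the stimulation component (first-order
#'   approach to the steady-state effect).
#' @return An object of class `"generator_params"`.
#' @export
#' @examples
#' gp <- generator_params(alpha_offset = 0.2, v = 20, b0 = log(0.6),
#'                        b_in_base = c(0, -0.04))
#' gp$b_in_conflict
generator_params <- function(alpha_offset, v, b0, b1 = 1, b2 = 1,
                             a1 = 0.9999, a2 = 0.9999,
                             sigma1 = 0, sigma2 = 0,
                             b_in_base = numeric(0),
                             b_in_conflict = b_in_base / 10,
                             x0_base = 0, x0_conflict = 0,
                             rho = 0.7) {
  stopifnot(is.numeric(alpha_offset), alpha_offset >= 0,
            is.numeric(v), v > 0,
            is.finite(b0), is.finite(b1), is.finite(b2),
            a1 >= 0, a1 <= 1, a2 >= 0, a2 <= 1,
            sigma1 >= 0, sigma2 >= 0,
            rho >= 0, rho < 1,
            length(b_in_conflict) == length(b_in_base))
  structure(list(alpha_offset = alpha_offset, v = v,
                 b0 = b0, b1 = b1, b2 = b2,
                 a1 = a1, a2 = a2, sigma1 = sigma1, sigma2 = sigma2,
                 b_in_base = as.numeric(b_in_base),
                 b_in_conflict = as.numeric(b_in_conflict),
                 x0_base = x0_base, x0_conflict = x0_conflict,
                 rho = rho),
            class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>\n")
  cat(sprintf("  observation: alpha = %.4g s, v = %.4g, b0 = %.4g (b1 = %g, b2 = %g)\n",
              x$alpha_offset, x$v, x$b0, x$b1, x$b2))
  cat(sprintf("  dynamics:    a = (%g, %g), sigma = (%.4g, %.4g), rho = %g\n",
              x$a1, x$a2, x$sigma1, x$sigma2, x$rho))
  if (length(x$b_in_base))
    cat("  sites:      ", paste(format(x$b_in_base), collapse = " "), "\n")
  cat(sprintf("  x0:          (%.3g, %.3g)\n", x$x0_base, x$x0_conflict))
  invisible(x)
}

#' Latent cognitive state
#'
#' The generator's state splits each latent variable into an endogenous AR(1)
#' component and a stimulation component that relaxes toward the active
#' site's steady-state effect. The observable state is their sum:
#' `x_base = base_endo + base_stim` (and likewise for the conflict state).
#'
#' @param x_base,x_conflict Initial endogenous state values (log-seconds).
#' @return An object of class `"latent_state"` with components
#'   `base_endo`, `conflict_endo`, `base_stim`, `conflict_stim`.
#' @export
latent_state <- function(x_base = 0, x_conflict = 0) {
  stopifnot(is.finite(x_base), is.finite(x_conflict))
  structure(list(base_endo = x_base, conflict_endo = x_conflict,
                 base_stim = 0, conflict_stim = 0),
            class = "latent_state")
}

#' Observable latent-state values
#'
#' @param state A [latent_state()].
#' @return Named numeric vector `c(x_base, x_conflict)`.
#' @export
state_values <- function(state) {
  c(x_base = state$base_endo + state$base_stim,
    x_conflict = state$conflict_endo + state$conflict_stim)
}

#' Mean reaction time implied by the latent states
#'
#' Evaluates the log link `ln(mu) = b0 + b1 * x_base +
#' b2 * I_conflict * x_conflict`.
#'
#' @param x_base,x_conflict Latent state values (log-seconds).
#' @param I_conflict Conflict indicator, 0 or 1.
#' @param b0,b1,b2 Link coefficients.
#' @return Positive mean RT `mu`, seconds (excluding the offset).
#' @export
#' @examples
#' mean_rt(0, 0, 0, b0 = log(0.5))  # 0.5
mean_rt <- function(x_base, x_conflict, I_conflict, b0, b1 = 1, b2 = 1) {
  stopifnot(all(I_conflict %in% c(0, 1)))
  exp(b0 + b1 * x_base + b2 * I_conflict * x_conflict)
}

#' Draw reaction times from the offset-gamma observation model
#'
#' @param mu Mean of the gamma part (seconds), may be a vector.
#' @param v Dispersion parameter (shape of the gamma).
#' @param alpha_offset Additive RT lower bound, seconds.
#' @return RT draw(s), seconds; always `> alpha_offset`.
#' @export
sample_rt <- function(mu, v, alpha_offset = 0) {
  if (any(mu <= 0) || v <= 0)
    stop("sample_rt: 'mu' and 'v' must be positive")
  stopifnot(alpha_offset >= 0)
  alpha_offset + stats::rgamma(length(mu), shape = v, rate = v / mu)
}

#' Advance the latent states one trial
#'
#' Endogenous components follow `x' = a * x + w`, `w ~ N(0, sigma)`; the
#' stimulation components relax toward the active site's steady-state effect
#' with retention `rho`: `x_stim' = rho * x_stim + (1 - rho) * s_site`.
#' With no active site the stimulation target is 0 (washout).
#'
#' @param state A [latent_state()].
#' @param params A [generator_params()].
#' @param site Active site index (1-based) or `NA`/`NULL` for none. Exactly
#'   one site may be active per trial.
#' @return The next [latent_state()].
#' @export
step_states <- function(state, params, site = NA) {
  s_base <- 0; s_conf <- 0
  if (!is.null(site) && !is.na(site)) {
    if (site < 1 || site > length(params$b_in_base))
      stop("step_states: site index out of range")
    s_base <- params$b_in_base[site]
    s_conf <- params$b_in_conflict[site]
  }
  w1 <- if (params$sigma1 > 0) stats::rnorm(1, 0, params$sigma1) else 0
  w2 <- if (params$sigma2 > 0) stats::rnorm(1, 0, params$sigma2) else 0
  structure(list(
    base_endo     = params$a1 * state$base_endo + w1,
    conflict_endo = params$a2 * state$conflict_endo + w2,
    base_stim     = params$rho * state$base_stim + (1 - params$rho) * s_base,
    conflict_stim = params$rho * state$conflict_stim + (1 - params$rho) * s_conf),
    class = "latent_state")
}

#' Log-density of an observed RT under the offset-gamma model
#'
#' @param rt Observed reaction time(s), seconds.
#' @param mu Gamma-part mean(s), seconds.
#' @param v Dispersion parameter.
#' @param alpha_offset RT lower bound, seconds.
#' @return Log-density; `-Inf` where `rt <= alpha_offset` (outside support).
#' @export
rt_loglik <- function(rt, mu, v, alpha_offset = 0) {
  if (any(mu <= 0) || v <= 0)
    stop("rt_loglik: 'mu' and 'v' must be positive")
  out <- rep(-Inf, length(rt))
  ok <- rt > alpha_offset
  if (any(ok)) {
    mu_ok <- if (length(mu) > 1) mu[ok] else mu
    out[ok] <- stats::dgamma(rt[ok] - alpha_offset, shape = v,
                             rate = v / mu_ok, log = TRUE)
  }
  out
}
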