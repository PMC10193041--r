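# State-space inference for the offset-gamma / log-link RT model.
#
# The observation is RT_k = alpha + g_k, g_k ~ Gamma(shape v, rate v/mu_k),
# log(mu_k) = b0 + b1 x_base,k + b2 I_k x_conflict,k, with AR(1) latent
# states. The filter is a Gaussian approximate (Laplace / mode-matching)
# recursion: because the log-likelihood depends on the 2-d state only through
# the scalar linear predictor eta, the per-trial posterior mode reduces to a
# 1-d monotone root-finding problem solved by Newton iteration, and the
# posterior covariance follows by a rank-one (Sherman-Morrison) downdate.

#' Map a logarithmic noise-grid scale to a state-noise SD
#'
#' The state-noise grid is logarithmic: `sigma = (1/sqrt(2))^scale`. Scale 1
#' maps to 0.707 and scale 40 to 9.5367e-7; the operational ranges used for
#' the baseline and conflict states are scales `[7, 16]` (sigma in
#' `[0.0039, 0.0884]`) and `[13, 27]`.
#'
#' @param scale Numeric scale value(s), >= 0.
#' @return Standard deviation(s) `(1/sqrt(2))^scale`.
#' @export
#' @examples
#' scale_to_sigma(8)   # 0.0625
#' scale_to_sigma(40)  # 9.5367e-07
scale_to_sigma <- function(scale) {
  stopifnot(all(scale >= 0))
  (1 / sqrt(2))^scale
}

#' Specification of the reduced estimation problem
#'
#' The free parameters are `(alpha_offset, v, b0)`; everything else is held
#' fixed (`a1 = a2 = 0.9999`, `b1 = b2 = 1`, no stimulation input) with the
#' state-noise SDs supplied via their grid scales or directly.
#'
#' @param sigma1,sigma2 State-noise SDs; alternatively give `scale1`/`scale2`.
#' @param scale1,scale2 Noise-grid scales (used when sigmas are missing).
#' @param a1,a2,b1,b2 Fixed dynamics/link coefficients.
#' @param alpha_lb,alpha_ub Bounds for the RT offset in the M-step
#'   (seconds). The upper bound is additionally capped at the smallest
#'   observed RT.
#' @param em_tol Relative change in the tracked likelihood below which EM
#'   stops.
#' @param max_iter EM iteration cap.
#' @param x0 Initial latent state `c(x_base, x_conflict)`, or `NULL` to draw
#'   from N(0, 1) at fit time.
#' @param P0 Initial state variance (diagonal value).
#' @param b0_init Optional fixed starting value for `b0`. The level of the
#'   latent baseline state is only identified jointly with `b0`, so the EM
#'   keeps `b0` near its start while the state path absorbs the residual
#'   level; anchoring `b0` at a population-typical value puts the fitted
#'   states on a common scale across participants. `NULL` (default)
#'   initializes from the early conflict-free trials instead, which anchors
#'   the state path at the supplied `x0`.
#' @return An object of class `"fit_spec"`.
#' @export
fit_spec <- function(sigma1 = NULL, sigma2 = NULL,
                     scale1 = 8, scale2 = 16,
                     a1 = 0.9999, a2 = 0.9999, b1 = 1, b2 = 1,
                     alpha_lb = 0, alpha_ub = Inf,
                     em_tol = 0.001, max_iter = 50,
                     x0 = NULL, P0 = 0.5, b0_init = NULL) {
  if (is.null(sigma1)) sigma1 <- scale_to_sigma(scale1)
  if (is.null(sigma2)) sigma2 <- scale_to_sigma(scale2)
  stopifnot(em_tol > 0, max_iter >= 1, alpha_lb >= 0, alpha_ub > alpha_lb,
            P0 > 0)
  structure(list(sigma1 = sigma1, sigma2 = sigma2,
                 a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 alpha_lb = alpha_lb, alpha_ub = alpha_ub,
                 em_tol = em_tol, max_iter = max_iter,
                 x0 = x0, P0 = P0, b0_init = b0_init),
            class = "fit_spec")
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix);
# cached at first use.
.gh_cache <- new.env(parent = emptyenv())
.gh_rule <- function(n = 20) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  J <- diag(0, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  rule <- list(x = e$values, logw_adj = log(sqrt(pi) * e$vectors[1, ]^2) +
                 e$values^2)   # adaptive-GH weights: w_j * exp(x_j^2)
  .gh_cache[[key]] <- rule
  rule
}

# Observation update in the scalar linear predictor eta = b0 + c'z:
# posterior of eta is proportional to exp(l(eta)) * N(eta; eta0, q) with
# l(eta) = const - v*eta - v*y*exp(-eta). Newton locates the mode; adaptive
# Gauss-Hermite quadrature centered there gives exact (to quadrature
# accuracy) posterior mean, variance, and marginal likelihood.
# Returns c(mean_shift t = (E[eta]-eta0)/q, var_ratio = Var(eta)/q,
#           log marginal likelihood of y including the gamma constants).
.eta_update <- function(eta0, q, y, v) {
  eta <- eta0
  for (i in 1:60) {
    e <- v * (y * exp(-eta) - 1)
    f <- eta - eta0 - q * e
    fp <- 1 + q * v * y * exp(-eta)
    d <- f / fp
    eta <- eta - d
    if (abs(d) < 1e-12) break
  }
  h <- 1 / q + v * y * exp(-eta)          # curvature at the mode
  gh <- .gh_rule(20L)
  s <- sqrt(2 / h)
  nodes <- eta + s * gh$x
  L <- -v * nodes - v * y * exp(-nodes) - (nodes - eta0)^2 / (2 * q) +
    gh$logw_adj
  Lm <- max(L)
  w <- exp(L - Lm)
  sw <- sum(w)
  m_eta <- sum(w * nodes) / sw
  v_eta <- sum(w * (nodes - m_eta)^2) / sw
  ll <- v * log(v) - lgamma(v) + (v - 1) * log(y) +
    Lm + log(sw) + log(s) - 0.5 * log(2 * pi * q)
  c((m_eta - eta0) / q, v_eta / q, ll)
}

#' Filter (and smooth) latent states from a trial log
#'
#' Runs the Gaussian-approximate forward filter for the offset-gamma /
#' log-link state-space model, optionally followed by fixed-interval (RTS)
#' smoothing. Trials with missing RT (`NA`) get a pure prediction step.
#' The filter is stimulation-blind: no input term is applied (the sensor's
#' operating condition); stimulation-driven drift is absorbed by the state
#' noise.
#'
#' @param params A [generator_params()] (or fitted parameter set) providing
#'   `alpha_offset`, `v`, `b0`, `b1`, `b2`, `a1`, `a2`, `sigma1`, `sigma2`.
#' @param trials Trial-log `data.frame` with columns `conflict` and `rt_s`
#'   (see [simulate_session()] / [read_trial_log()]).
#' @param x0 Initial state mean `c(x_base, x_conflict)`; defaults to the
#'   params' initial states.
#' @param P0 Initial state variance (diagonal value).
#' @param smooth Run the backward smoothing pass as well?
#' @param on_invalid What to do with `rt <= alpha_offset`: `"error"` or
#'   `"skip"` (treat as missing, count in `n_skipped`).
#' @return An object of class `"state_trajectory"`: a list with
#'   `filtered` / `smoothed` data frames (per-trial means and variances of
#'   both states, predicted RT), the total approximate log-likelihood
#'   `loglik`, and `n_skipped`.
#' @export
filter_states <- function(params, trials,
                          x0 = c(params$x0_base, params$x0_conflict),
                          P0 = 0.5, smooth = TRUE,
                          on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  n <- nrow(trials)
  if (n < 1) stop("filter_states: empty trial log")
  alpha <- params$alpha_offset; v <- params$v
  b0 <- params$b0; b1 <- params$b1; b2 <- params$b2
  a1 <- params$a1; a2 <- params$a2
  q1 <- params$sigma1^2; q2 <- params$sigma2^2
  I <- as.numeric(trials$conflict)
  rt <- as.numeric(trials$rt_s)

  m1 <- numeric(n); m2 <- numeric(n)
  P11 <- numeric(n); P12 <- numeric(n); P22 <- numeric(n)
  mp1 <- numeric(n); mp2 <- numeric(n)
  Pp11 <- numeric(n); Pp12 <- numeric(n); Pp22 <- numeric(n)
  loglik <- 0; n_skipped <- 0L

  cm1 <- x0[1]; cm2 <- x0[2]
  cP11 <- P0; cP12 <- 0; cP22 <- P0
  for (k in seq_len(n)) {
    # predict
    pm1 <- a1 * cm1; pm2 <- a2 * cm2
    pP11 <- a1 * a1 * cP11 + q1
    pP12 <- a1 * a2 * cP12
    pP22 <- a2 * a2 * cP22 + q2
    mp1[k] <- pm1; mp2[k] <- pm2
    Pp11[k] <- pP11; Pp12[k] <- pP12; Pp22[k] <- pP22

    y <- rt[k] - alpha
    ok <- is.finite(y) && y > 0
    if (!ok && is.finite(rt[k])) {
      if (on_invalid == "error")
        stop("filter_states: rt <= alpha_offset at trial ", k,
             " (inconsistent offset)")
      n_skipped <- n_skipped + 1L
    }
    if (ok) {
      c1 <- b1; c2 <- b2 * I[k]
      eta0 <- b0 + c1 * pm1 + c2 * pm2
      q <- c1 * c1 * pP11 + 2 * c1 * c2 * pP12 + c2 * c2 * pP22
      if (q > 1e-14) {
        eu <- .eta_update(eta0, q, y, v)
        t_sc <- eu[1]; f <- (1 - eu[2]) / q
        Pc1 <- pP11 * c1 + pP12 * c2
        Pc2 <- pP12 * c1 + pP22 * c2
        cm1 <- pm1 + Pc1 * t_sc
        cm2 <- pm2 + Pc2 * t_sc
        cP11 <- pP11 - f * Pc1 * Pc1
        cP12 <- pP12 - f * Pc1 * Pc2
        cP22 <- pP22 - f * Pc2 * Pc2
        loglik <- loglik + eu[3]
      } else {
        cm1 <- pm1; cm2 <- pm2
        cP11 <- pP11; cP12 <- pP12; cP22 <- pP22
        loglik <- loglik + stats::dgamma(y, shape = v, rate = v / exp(eta0),
                                         log = TRUE)
      }
    } else {
      cm1 <- pm1; cm2 <- pm2
      cP11 <- pP11; cP12 <- pP12; cP22 <- pP22
    }
    m1[k] <- cm1; m2[k] <- cm2
    P11[k] <- cP11; P12[k] <- cP12; P22[k] <- cP22
  }

  filtered <- data.frame(
    trial = seq_len(n) - 1L, conflict = I,
    x_base = m1, x_conflict = m2,
    var_base = P11, cov = P12, var_conflict = P22,
    mu_pred = exp(b0 + b1 * m1 + b2 * I * m2),
    mu_onestep = exp(b0 + b1 * mp1 + b2 * I * mp2))
  filtered$rt_pred <- alpha + filtered$mu_pred

  smoothed <- NULL
  if (smooth) {
    s1 <- m1; s2 <- m2
    S11 <- P11; S12 <- P12; S22 <- P22
    if (n > 1) for (k in (n - 1):1) {
      # G = P_k A' Ppred_{k+1}^{-1}
      dp <- Pp11[k + 1] * Pp22[k + 1] - Pp12[k + 1]^2
      i11 <- Pp22[k + 1] / dp; i22 <- Pp11[k + 1] / dp
      i12 <- -Pp12[k + 1] / dp
      B11 <- P11[k] * a1; B12 <- P12[k] * a2
      B21 <- P12[k] * a1; B22 <- P22[k] * a2
      G11 <- B11 * i11 + B12 * i12; G12 <- B11 * i12 + B12 * i22
      G21 <- B21 * i11 + B22 * i12; G22 <- B21 * i12 + B22 * i22
      d1 <- s1[k + 1] - mp1[k + 1]; d2 <- s2[k + 1] - mp2[k + 1]
      s1[k] <- m1[k] + G11 * d1 + G12 * d2
      s2[k] <- m2[k] + G21 * d1 + G22 * d2
      D11 <- S11[k + 1] - Pp11[k + 1]
      D12 <- S12[k + 1] - Pp12[k + 1]
      D22 <- S22[k + 1] - Pp22[k + 1]
      # G D G'
      T11 <- G11 * D11 + G12 * D12; T12 <- G11 * D12 + G12 * D22
      T21 <- G21 * D11 + G22 * D12; T22 <- G21 * D12 + G22 * D22
      S11[k] <- P11[k] + T11 * G11 + T12 * G12
      S12[k] <- P12[k] + T11 * G21 + T12 * G22
      S22[k] <- P22[k] + T21 * G21 + T22 * G22
    }
    smoothed <- data.frame(
      trial = seq_len(n) - 1L, conflict = I,
      x_base = s1, x_conflict = s2,
      var_base = S11, cov = S12, var_conflict = S22,
      mu_pred = exp(b0 + b1 * s1 + b2 * I * s2))
    smoothed$rt_pred <- alpha + smoothed$mu_pred
  }

  structure(list(filtered = filtered, smoothed = smoothed,
                 loglik = loglik, n_skipped = n_skipped,
                 params = params),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d trials, loglik = %.3f\n",
              nrow(x$filtered), x$loglik))
  invisible(x)
}

# M-step profile: for a candidate alpha, the optimal b0 is closed-form and v
# solves a 1-d digamma score equation; returns the maximized expected
# log-likelihood and the maximizers.
.mstep_profile <- function(alpha, rt, r, qs, b1b2_part_only = TRUE) {
  y <- rt - alpha
  if (any(y <= 0)) return(list(Q = -Inf))
  n <- length(y)
  # E[exp(-eta)] correction: exp(-eta + q_s/2) with eta at smoothed mean
  w_part <- exp(-r + qs / 2)
  b0 <- log(mean(y * w_part))
  eta <- b0 + r
  S_log_y <- sum(log(y))
  S_ee <- sum(eta + y * exp(-eta + qs / 2))   # = sum(eta) + n at optimal b0
  h <- function(v) log(v) - digamma(v) + 1 + (S_log_y - S_ee) / n
  # h is decreasing in v; bracket and solve
  lo <- 1e-3; hi <- 1e6
  if (h(lo) < 0) v <- lo
  else if (h(hi) > 0) v <- hi
  else v <- stats::uniroot(h, c(lo, hi), tol = 1e-9)$root
  Q <- n * (v * log(v) - lgamma(v)) + (v - 1) * S_log_y - v * S_ee
  list(Q = Q, b0 = b0, v = v, alpha = alpha)
}

#' Fit the reduced model by expectation-maximization
#'
#' Alternates a Gaussian-approximate E-step ([filter_states()] with
#' smoothing) with closed-form/1-d M-step updates of the free parameters
#' `(alpha_offset, v, b0)`. Iteration stops when the relative change in the
#' tracked marginal log-likelihood falls below `spec$em_tol`
#' (`|ML_t - ML_{t-1}| / |ML_{t-1}| < em_tol`) or at `spec$max_iter`.
#'
#' @param trials Trial-log `data.frame` (columns `conflict`, `rt_s`).
#' @param spec A [fit_spec()].
#' @return An object of class `"em_fit"`: fitted `params`
#'   (a [generator_params()] with `b_in` empty), final `trajectory`,
#'   the likelihood trace `ml_trace`, `converged`, and `iterations`.
#'   Non-convergence within `max_iter` is reported via a warning and the
#'   `converged` flag.
#' @export
em_fit <- function(trials, spec = fit_spec()) {
  rt <- as.numeric(trials$rt_s)
  stopifnot(length(rt) >= 2, all(is.finite(rt)))
  x0 <- spec$x0
  if (is.null(x0)) x0 <- stats::rnorm(2)
  alpha_hi <- min(min(rt) - 1e-6, spec$alpha_ub)
  if (alpha_hi <= spec$alpha_lb) alpha_hi <- spec$alpha_lb + 1e-9
  alpha <- min(max(spec$alpha_lb, 0.5 * min(rt)), alpha_hi)
  y0 <- pmax(rt - alpha, 1e-6)
  if (is.null(spec$b0_init)) {
    # initialize the level from early conflict-free trials: the initial
    # state anchors the b0/x_base split, and late trials have drifted away
    I0 <- as.numeric(trials$conflict)
    early <- which(I0 == 0)[seq_len(min(50, sum(I0 == 0)))]
    if (!length(early)) early <- seq_len(min(50, length(y0)))
    b0 <- log(mean(y0[early])) - x0[1]
  } else {
    b0 <- spec$b0_init
  }
  vv <- max(1, mean(y0)^2 / max(stats::var(y0), 1e-8))
  cur <- generator_params(alpha_offset = alpha, v = vv, b0 = b0,
                          b1 = spec$b1, b2 = spec$b2,
                          a1 = spec$a1, a2 = spec$a2,
                          sigma1 = spec$sigma1, sigma2 = spec$sigma2,
                          x0_base = x0[1], x0_conflict = x0[2])
  ml_trace <- numeric(0)
  converged <- FALSE
  traj <- NULL
  for (it in seq_len(spec$max_iter)) {
    traj <- filter_states(cur, trials, x0 = x0, P0 = spec$P0, smooth = TRUE)
    ml <- traj$loglik
    ml_trace <- c(ml_trace, ml)
    if (it > 1) {
      rel <- abs(ml - ml_trace[it - 1]) / abs(ml_trace[it - 1])
      if (rel < spec$em_tol) { converged <- TRUE; break }
    }
    sm <- traj$smoothed
    I <- as.numeric(trials$conflict)
    c2 <- spec$b2 * I
    r <- spec$b1 * sm$x_base + c2 * sm$x_conflict
    qs <- spec$b1^2 * sm$var_base + 2 * spec$b1 * c2 * sm$cov +
      c2^2 * sm$var_conflict
    prof <- function(a) .mstep_profile(a, rt, r, qs)$Q
    opt <- stats::optimize(prof, c(spec$alpha_lb, alpha_hi),
                           maximum = TRUE, tol = 1e-6)
    best <- .mstep_profile(opt$maximum, rt, r, qs)
    # guard against a degenerate profile at the bracket edge
    if (is.finite(best$Q)) {
      cur <- generator_params(alpha_offset = best$alpha, v = best$v,
                              b0 = best$b0,
                              b1 = spec$b1, b2 = spec$b2,
                              a1 = spec$a1, a2 = spec$a2,
                              sigma1 = spec$sigma1, sigma2 = spec$sigma2,
                              x0_base = x0[1], x0_conflict = x0[2])
    }
  }
  if (!converged)
    warning("em_fit: EM did not reach the relative-likelihood criterion in ",
            spec$max_iter, " iterations")
  structure(list(params = cur, trajectory = traj, ml_trace = ml_trace,
                 converged = converged, iterations = length(ml_trace),
                 spec = spec, x0 = x0),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> alpha = %.4f, v = %.3f, b0 = %.4f (%d iterations%s)\n",
              x$params$alpha_offset, x$params$v, x$params$b0,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Gamma deviance between observed and model-predicted RTs
#'
#' Twice the gap between the saturated log-likelihood (each trial's gamma
#' mean equal to its own observed offset-corrected RT) and the model
#' log-likelihood at the one-step-ahead predicted means from the filter:
#' `D = 2 v * sum(log(mu_i / y_i) + (y_i - mu_i) / mu_i)`. Prediction (not
#' smoothing) makes the deviance an honest out-of-sample criterion: a
#' too-large state noise produces noisy predictions and a too-small one
#' cannot track, so the deviance surface has a basin near the generating
#' noise scale. Lower is better; a model predicting every RT exactly has
#' deviance 0.
#'
#' @param params Parameter set (as from [em_fit()]`$params`).
#' @param trials Trial-log `data.frame`.
#' @param trajectory Optional precomputed [filter_states()] result.
#' @return Scalar deviance.
#' @export
rt_deviance <- function(params, trials, trajectory = NULL) {
  y <- as.numeric(trials$rt_s) - params$alpha_offset
  if (any(y <= 0)) stop("rt_deviance: rt <= alpha_offset; undefined")
  if (is.null(trajectory))
    trajectory <- filter_states(params, trials, smooth = FALSE)
  mu <- trajectory$filtered$mu_onestep
  2 * params$v * sum(log(mu / y) + (y - mu) / mu)
}

#' Logarithmic grid search for the state-noise covariance
#'
#' For every cell of a `scale1` x `scale2` grid, sets the state-noise SDs
#' via [scale_to_sigma()], fits the reduced model by [em_fit()] from several
#' random initial states (plus one run from `x0 = 0`), and records the
#' minimum deviance across restarts. Per-cell failures are recorded as `NA`
#' cells rather than aborting the search.
#'
#' @param trials Trial-log `data.frame`.
#' @param scale1,scale2 Integer grid vectors within `[1, 40]`.
#' @param spec Base [fit_spec()] (its sigmas are overridden per cell).
#' @param n_restarts Number of random-`x0` EM restarts per cell.
#' @param include_zero_x0 Add one extra restart from `x0 = c(0, 0)`?
#' @return An object of class `"deviance_surface"`: grids, the deviance
#'   matrix (`length(scale1)` x `length(scale2)`), and per-cell fitted
#'   `(alpha, v, b0)` matrices. Convert with `as.data.frame()`.
#' @export
grid_search_w <- function(trials, scale1 = 1:40, scale2 = 1:40,
                          spec = fit_spec(), n_restarts = 5,
                          include_zero_x0 = TRUE) {
  stopifnot(all(scale1 >= 1 & scale1 <= 40), all(scale2 >= 1 & scale2 <= 40))
  n1 <- length(scale1); n2 <- length(scale2)
  dev <- matrix(NA_real_, n1, n2, dimnames = list(scale1, scale2))
  a_m <- v_m <- b_m <- dev
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    sp <- spec
    sp$sigma1 <- scale_to_sigma(scale1[i])
    sp$sigma2 <- scale_to_sigma(scale2[j])
    x0s <- replicate(n_restarts, stats::rnorm(2), simplify = FALSE)
    if (include_zero_x0) x0s <- c(x0s, list(c(0, 0)))
    best <- Inf; best_fit <- NULL
    for (x0 in x0s) {
      sp$x0 <- x0
      fit <- tryCatch(suppressWarnings(em_fit(trials, sp)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      d <- tryCatch(rt_deviance(fit$params, trials, fit$trajectory),
                    error = function(e) NA_real_)
      if (is.finite(d) && d < best) { best <- d; best_fit <- fit }
    }
    if (!is.null(best_fit)) {
      dev[i, j] <- best
      a_m[i, j] <- best_fit$params$alpha_offset
      v_m[i, j] <- best_fit$params$v
      b_m[i, j] <- best_fit$params$b0
    }
  }
  structure(list(scale1 = scale1, scale2 = scale2, deviance = dev,
                 alpha = a_m, v = v_m, b0 = b_m),
            class = "deviance_surface")
}

#' @export
as.data.frame.deviance_surface <- function(x, ...) {
  g <- expand.grid(scale1 = x$scale1, scale2 = x$scale2)
  g$deviance <- as.vector(x$deviance)
  g$alpha <- as.vector(x$alpha)
  g$v <- as.vector(x$v)
  g$b0 <- as.vector(x$b0)
  g
}

#' @export
print.deviance_surface <- function(x, ...) {
  cat(sprintf("<deviance_surface> %d x %d grid; min deviance %.3f at scale (%s, %s)\n",
              length(x$scale1), length(x$scale2),
              min(x$deviance, na.rm = TRUE),
              x$scale1[which(x$deviance == min(x$deviance, na.rm = TRUE),
                             arr.ind = TRUE)[1, 1]],
              x$scale2[which(x$deviance == min(x$deviance, na.rm = TRUE),
                             arr.ind = TRUE)[1, 2]]))
  invisible(x)
}
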