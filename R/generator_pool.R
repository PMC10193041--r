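# Synthetic participants: archetype sampling, stimulation response surfaces,
# full-session simulation, and gamma-consistency (KS) validation.

#' Archetype describing the synthetic-participant population
#'
#' Parameter ranges for drawing new simulated participants. Defaults emulate
#' conflict-task behavior: mean RTs for a typical draw in roughly the
#' 0.3--1.5 s band, a conflict cost of about 200 ms, near-unit AR
#' coefficients so the baseline state drifts slowly, and state-noise SDs
#' drawn on the logarithmic grid (scales `[7, 16]` for the baseline state,
#' `[13, 27]` for the conflict state). Initial baseline state is drawn from
#' N(0, 1); the initial conflict state is set so the implied conflict cost
#' matches `conflict_cost_s` at the drawn baseline.
#'
#' @param alpha_range RT offset range, seconds.
#' @param v_range Dispersion-parameter range.
#' @param b0_range Range of `b0` (log-seconds).
#' @param scale1_range,scale2_range Noise-grid scale ranges (continuous
#'   uniform draws).
#' @param a1,a2 AR coefficients.
#' @param conflict_cost_s Target conflict-induced RT increase, seconds.
#' @param rho Stimulation-settling retention (see [generator_params()]).
#' @return An object of class `"participant_archetype"`.
#' @export
participant_archetype <- function(alpha_range = c(0.1, 0.3),
                                  v_range = c(10, 40),
                                  b0_range = log(c(0.4, 0.8)),
                                  scale1_range = c(7, 16),
                                  scale2_range = c(13, 27),
                                  a1 = 0.9999, a2 = 0.9999,
                                  conflict_cost_s = 0.2,
                                  rho = 0.7) {
  stopifnot(all(scale1_range >= 1 & scale1_range <= 40),
            all(scale2_range >= 1 & scale2_range <= 40),
            alpha_range[1] >= 0, v_range[1] > 0, conflict_cost_s >= 0)
  structure(list(alpha_range = alpha_range, v_range = v_range,
                 b0_range = b0_range,
                 scale1_range = scale1_range, scale2_range = scale2_range,
                 a1 = a1, a2 = a2, conflict_cost_s = conflict_cost_s,
                 rho = rho),
            class = "participant_archetype")
}

#' Stimulation response surface (the bandit problem)
#'
#' Per-site steady-state effects on the baseline state, in log-seconds.
#' Negative values speed the participant up; the optimal site is the argmin.
#' Named surfaces cover the monopolar-survey problems of increasing size
#' (`"sites2"`, `"sites4"`, `"sites6"`, `"sites8"`) and the two-site
#' discriminability ladder `"b1"`..`"b7"` (down to the degenerate `"b7"`
#' with identical sites) plus the high-contrast `"bss"` used for
#' settling-time demonstrations.
#'
#' @param effects Numeric vector of per-site effects on `x_base`
#'   (log-seconds), or a surface label.
#' @param label Optional label stored on the object.
#' @return An object of class `"stim_problem"` with fields `effects`,
#'   `optimal` (argmin index, ties broken by lowest index), `label`.
#' @export
#' @examples
#' stim_problem("sites8")$effects
#' stim_problem(c(0, -0.04))$optimal  # 2
stim_problem <- function(effects, label = NULL) {
  surfaces <- list(
    sites8 = c(0, -0.005, -0.01, -0.02, -0.03, -0.031, -0.04, -0.07),
    sites6 = c(0, -0.005, -0.01, -0.02, -0.04, -0.07),
    sites4 = c(0, -0.005, -0.01, -0.04),
    sites2 = c(-0.01, -0.04),
    b1 = c(0.05, -0.05), b2 = c(0, -0.10), b3 = c(0, -0.05),
    b4 = c(0, -0.03), b5 = c(0, -0.02), b6 = c(0, -0.01),
    b7 = c(0, 0), bss = c(0.25, -0.25))
  if (is.character(effects)) {
    if (!effects %in% names(surfaces))
      stop("stim_problem: unknown surface label '", effects, "'")
    if (is.null(label)) label <- effects
    effects <- surfaces[[effects]]
  }
  stopifnot(is.numeric(effects), length(effects) >= 1, all(is.finite(effects)))
  structure(list(effects = as.numeric(effects),
                 optimal = which.min(effects),
                 label = if (is.null(label)) "custom" else label),
            class = "stim_problem")
}

#' @export
print.stim_problem <- function(x, ...) {
  cat(sprintf("<stim_problem '%s'> %d sites: %s (optimal: site %d)\n",
              x$label, length(x$effects),
              paste(format(x$effects), collapse = " "), x$optimal))
  invisible(x)
}

#' Shuffle the site order of a response surface
#'
#' Each experiment replicate randomizes where the optimal site sits, so
#' algorithms cannot benefit from a fixed position.
#'
#' @param problem A [stim_problem()].
#' @return A new `stim_problem` with permuted effects.
#' @export
shuffle_problem <- function(problem) {
  perm <- sample.int(length(problem$effects))
  stim_problem(problem$effects[perm], label = problem$label)
}

#' Draw one synthetic participant from an archetype
#'
#' Observation parameters are uniform draws from the archetype ranges;
#' state-noise SDs come from uniformly drawn grid scales via
#' [scale_to_sigma()]; the initial baseline state is N(0, 1) and the initial
#' conflict state solves `exp(b0 + x0_base) * (exp(x_conflict) - 1) =
#' conflict_cost_s` so conflict slows the participant by about the target
#' amount.
#'
#' @param archetype A [participant_archetype()].
#' @param problem Optional [stim_problem()]; its effects become the
#'   participant's `b_in_base` (conflict effects ten-fold smaller).
#' @return A [generator_params()].
#' @export
sample_participant <- function(archetype = participant_archetype(),
                               problem = NULL) {
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  alpha <- runif1(archetype$alpha_range)
  v <- runif1(archetype$v_range)
  b0 <- runif1(archetype$b0_range)
  sigma1 <- scale_to_sigma(runif1(archetype$scale1_range))
  sigma2 <- scale_to_sigma(runif1(archetype$scale2_range))
  x0b <- stats::rnorm(1)
  x0c <- log1p(archetype$conflict_cost_s / exp(b0 + x0b))
  eff <- if (is.null(problem)) numeric(0) else problem$effects
  generator_params(alpha_offset = alpha, v = v, b0 = b0,
                   a1 = archetype$a1, a2 = archetype$a2,
                   sigma1 = sigma1, sigma2 = sigma2,
                   b_in_base = eff,
                   x0_base = x0b, x0_conflict = x0c,
                   rho = archetype$rho)
}

#' Build a pool of synthetic participants
#'
#' @param n Pool size (default 1000).
#' @param archetype A [participant_archetype()].
#' @param problem Optional [stim_problem()] shared by the pool.
#' @return A list of [generator_params()], class `"generator_pool"`.
#' @export
build_pool <- function(n = 1000, archetype = participant_archetype(),
                       problem = NULL) {
  stopifnot(n >= 1)
  structure(lapply(seq_len(n), function(i)
    sample_participant(archetype, problem)),
    class = "generator_pool")
}

#' @export
print.generator_pool <- function(x, ...) {
  cat(sprintf("<generator_pool> %d participants\n", length(x)))
  invisible(x)
}

#' Simulate a full task session from a generator
#'
#' Steps the latent states and samples one RT per trial. Conflict trials are
#' Bernoulli(0.5) unless a fixed indicator sequence is supplied. The
#' stimulation `schedule` gives the active site per trial (`NA` = none).
#' Ground-truth states are recorded alongside each RT.
#'
#' @param gen A [generator_params()].
#' @param n_trials Number of trials.
#' @param schedule Integer vector of per-trial site indices (length
#'   `n_trials`), or `NULL` for no stimulation.
#' @param conflict Optional 0/1 vector overriding the random conflict
#'   indicators.
#' @return Trial-log `data.frame` with columns `trial` (0-based),
#'   `conflict`, `site`, `rt_s`, `x_base_true`, `x_conflict_true`.
#' @export
simulate_session <- function(gen, n_trials, schedule = NULL, conflict = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(schedule)) schedule <- rep(NA_integer_, n_trials)
  stopifnot(length(schedule) == n_trials)
  ok <- is.na(schedule) | (schedule >= 1 & schedule <= length(gen$b_in_base))
  if (!all(ok)) stop("simulate_session: invalid site in schedule")
  if (is.null(conflict)) conflict <- stats::rbinom(n_trials, 1, 0.5)
  stopifnot(length(conflict) == n_trials, all(conflict %in% c(0, 1)))

  st <- latent_state(gen$x0_base, gen$x0_conflict)
  xb <- numeric(n_trials); xc <- numeric(n_trials); rt <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    sv <- state_values(st)
    xb[k] <- sv[1]; xc[k] <- sv[2]
    mu <- mean_rt(sv[1], sv[2], conflict[k], gen$b0, gen$b1, gen$b2)
    rt[k] <- sample_rt(mu, gen$v, gen$alpha_offset)
    st <- step_states(st, gen, schedule[k])
  }
  data.frame(trial = seq_len(n_trials) - 1L, conflict = conflict,
             site = schedule, rt_s = rt,
             x_base_true = xb, x_conflict_true = xc)
}

# Shifted-gamma (location-offset) maximum-likelihood fit: profile the
# log-likelihood over the offset; for a fixed offset the shape solves
# log(shape) - digamma(shape) = log(mean(y)) - mean(log(y)) and
# rate = shape / mean(y).
.fit_shifted_gamma <- function(rt) {
  if (length(unique(rt)) < 3)
    stop("degenerate (near-constant) RT input")
  gamma_mle <- function(y) {
    s <- log(mean(y)) - mean(log(y))
    h <- function(k) log(k) - digamma(k) - s
    k <- stats::uniroot(h, c(1e-3, 1e7), tol = 1e-10)$root
    rate <- k / mean(y)
    list(shape = k, rate = rate,
         loglik = sum(stats::dgamma(y, shape = k, rate = rate, log = TRUE)))
  }
  prof <- function(off) gamma_mle(rt - off)$loglik
  hi <- min(rt) * (1 - 1e-6)
  opt <- stats::optimize(prof, c(0, hi), maximum = TRUE, tol = 1e-6)
  # offset 0 is a boundary candidate optimize() can miss
  off <- if (prof(0) >= opt$objective) 0 else opt$maximum
  fit <- gamma_mle(rt - off)
  list(offset = off, shape = fit$shape, rate = fit$rate)
}

#' KS test of a sample against its own maximum-likelihood shifted gamma
#'
#' Fits a shifted (location-offset) gamma to `rt` by profile maximum
#' likelihood and runs a one-sample Kolmogorov--Smirnov test of `rt` against
#' the fitted distribution.
#'
#' @param rt Numeric sample (reaction times, seconds).
#' @return List with `p_value`, `statistic`, and the fit (`offset`, `shape`,
#'   `rate`).
#' @export
ks_gamma_test <- function(rt) {
  fit <- .fit_shifted_gamma(rt)
  ks <- suppressWarnings(
    stats::ks.test(rt, function(q)
      stats::pgamma(q - fit$offset, shape = fit$shape, rate = fit$rate)))
  list(p_value = ks$p.value, statistic = unname(ks$statistic),
       offset = fit$offset, shape = fit$shape, rate = fit$rate)
}

#' Gamma-consistency of simulated RT output (KS validation)
#'
#' For each run: draw a participant from the pool, simulate an
#' unstimulated session, fit a shifted gamma distribution to the emitted
#' RTs by maximum likelihood, and run a one-sample Kolmogorov--Smirnov test
#' of the RTs against the fitted distribution. Because the reference
#' distribution is estimated from the same sample the test is conservative,
#' which is what makes a near-100% pass rate the expected signature of
#' gamma-like output.
#'
#' @param pool A [build_pool()] result (or list of [generator_params()]).
#' @param n_runs Number of simulation runs.
#' @param n_trials Trials per run (>= 100).
#' @param p_threshold Pass threshold for the KS p-value.
#' @return List with `fraction` (runs with p > threshold), `p_values`.
#' @export
ks_gamma_fraction <- function(pool, n_runs = 100, n_trials = 1000,
                              p_threshold = 0.05) {
  if (n_runs < 1) stop("ks_gamma_fraction: n_runs must be >= 1")
  stopifnot(n_trials >= 100)
  p <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    gen <- pool[[((r - 1) %% length(pool)) + 1]]
    ses <- simulate_session(gen, n_trials)
    p[r] <- ks_gamma_test(ses$rt_s)$p_value
  }
  list(fraction = mean(p > p_threshold), p_values = p)
}

#' Write / read a trial log as CSV
#'
#' Columns: `trial`, `conflict`, `site`, `rt_s`, `x_base_true`,
#' `x_conflict_true` (truth columns empty for real data; `site` empty for
#' none). UTF-8, header required.
#'
#' @param trials Trial-log `data.frame`.
#' @param path File path.
#' @return `read_trial_log` returns the trial-log `data.frame`.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("trial", "conflict", "rt_s")
  if (!all(need %in% names(df)))
    stop("read_trial_log: missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"site" %in% names(df)) df$site <- NA_integer_
  df$site <- suppressWarnings(as.integer(df$site))
  df
}

#' Serialize / load a generator pool as JSON lines
#'
#' One participant per line, with an optional seed provenance attribute.
#'
#' @param pool A `"generator_pool"`.
#' @param path File path.
#' @param seed Optional seed recorded in the first line's metadata.
#' @return `read_pool` returns the `"generator_pool"`.
#' @export
write_pool <- function(pool, path, seed = NULL) {
  lines <- vapply(pool, function(p)
    jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA),
    character(1))
  if (!is.null(seed))
    lines <- c(jsonlite::toJSON(list(meta = list(seed = seed)),
                                auto_unbox = TRUE), lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln)
    if (!is.null(obj$meta)) next
    out[[length(out) + 1]] <- generator_params(
      alpha_offset = obj$alpha_offset, v = obj$v, b0 = obj$b0,
      b1 = obj$b1, b2 = obj$b2, a1 = obj$a1, a2 = obj$a2,
      sigma1 = obj$sigma1, sigma2 = obj$sigma2,
      b_in_base = if (length(obj$b_in_base)) obj$b_in_base else numeric(0),
      b_in_conflict = if (length(obj$b_in_conflict)) obj$b_in_conflict
                      else numeric(0),
      x0_base = obj$x0_base, x0_conflict = obj$x0_conflict, rho = obj$rho)
  }
  structure(out, class = "generator_pool")
}
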