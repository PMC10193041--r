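# Site-selection algorithms and the block-wise closed loop. Everything is
# in minimization convention: lower block outcome (expected RT) is better.

BANDIT_ALGORITHMS <- c("brute_force", "greedy", "eps_greedy", "ucb1",
                       "bayes_ucb", "ts_bernoulli", "ts_poisson",
                       "ts_normal", "c_ts")

#' Create a fresh bandit state
#'
#' Holds per-site pull counts, running mean outcomes, and the conjugate
#' hyperparameters of the Bayesian algorithms. Hyperparameters start
#' improper -- gamma (0.5, 0.5), beta (1, 1), normal (first observation,
#' k = 1) -- and are made proper by forced exploration of every site before
#' algorithmic control.
#'
#' @param n_sites Number of stimulation sites (>= 1).
#' @param algorithm One of `"brute_force"`, `"greedy"`, `"eps_greedy"`,
#'   `"ucb1"`, `"bayes_ucb"`, `"ts_bernoulli"`, `"ts_poisson"`,
#'   `"ts_normal"`, `"c_ts"`.
#' @param eps Exploration probability for `eps_greedy`.
#' @param conf Confidence multiplier `c` for `bayes_ucb` (1.96 = 95%).
#' @return An object of class `"bandit_state"`.
#' @export
bandit_state <- function(n_sites, algorithm = "ucb1", eps = 0.1,
                         conf = 1.96) {
  if (n_sites < 1) stop("bandit_state: empty site set")
  algorithm <- match.arg(algorithm, BANDIT_ALGORITHMS)
  structure(list(
    algorithm = algorithm, n_sites = n_sites, eps = eps, conf = conf,
    N = integer(n_sites), mean = rep(NA_real_, n_sites), T = 0L,
    N_tr = integer(n_sites), T_tr = 0L,
    last_site = NA_integer_, last_outcome = NA_real_,
    forced_order = sample.int(n_sites),
    g_alpha = rep(0.5, n_sites), g_beta = rep(0.5, n_sites),
    b_alpha = rep(1, n_sites), b_beta = rep(1, n_sites),
    mu_z = rep(NA_real_, n_sites), k_z = rep(0, n_sites)),
    class = "bandit_state")
}

#' @export
print.bandit_state <- function(x, ...) {
  cat(sprintf("<bandit_state %s> %d sites, %d selections\n",
              x$algorithm, x$n_sites, x$T))
  cat("  N:   ", paste(x$N, collapse = " "), "\n")
  cat("  mean:", paste(format(round(x$mean, 4)), collapse = " "), "\n")
  invisible(x)
}

#' Forced-exploration selection sequence
#'
#' Every site must be pulled once (in seeded-random order) before control is
#' handed to the algorithm; this makes the Bayesian posteriors proper and
#' lets the sensor settle regardless of its initial state.
#'
#' @param state A fresh [bandit_state()].
#' @return Integer vector: a permutation of `1:n_sites`.
#' @export
forced_exploration <- function(state) {
  state$forced_order
}

#' Select the next stimulation site
#'
#' Applies the state's algorithm in minimization convention. All algorithms
#' except brute force require every site to have been pulled at least once
#' (see [forced_exploration()]).
#'
#' * `greedy`: argmin of mean outcomes (epsilon = 0 degenerate case).
#' * `eps_greedy`: random site with probability `eps`, else greedy.
#' * `ucb1`: argmin of `mean - sqrt(2 log(T) / N)` (exploration bonus);
#'   `T` and `N` count trials (the number of times a site's stimulation has
#'   been applied), so a block of `n` trials advances them by `n`.
#' * `bayes_ucb`: gamma-posterior `mu = alpha/beta`, `sigma = alpha/beta^2`,
#'   score `mu - conf * sigma / sqrt(N)`.
#' * `ts_*` / `c_ts`: one posterior draw per site; the best draw wins
#'   (argmin for the RT-scale posteriors, argmax for the Bernoulli success
#'   probability).
#' * `brute_force`: round-robin over the forced-exploration permutation.
#'
#' Ties break toward the lowest site index.
#'
#' @param state A [bandit_state()].
#' @return Site index (1-based).
#' @export
select_site <- function(state) {
  n <- state$n_sites
  if (state$algorithm == "brute_force")
    return(state$forced_order[(state$T %% n) + 1L])
  if (any(state$N == 0L))
    stop("select_site: forced exploration incomplete (un-initialized priors)")
  switch(state$algorithm,
    greedy = which.min(state$mean),
    eps_greedy = {
      if (stats::runif(1) < state$eps) sample.int(n, 1)
      else which.min(state$mean)
    },
    ucb1 = which.min(state$mean - sqrt(2 * log(state$T_tr) / state$N_tr)),
    bayes_ucb = {
      mu <- state$g_alpha / state$g_beta
      sg <- state$g_alpha / state$g_beta^2
      which.min(mu - state$conf * sg / sqrt(state$N_tr))
    },
    ts_bernoulli = which.max(stats::rbeta(n, state$b_alpha, state$b_beta)),
    ts_poisson = which.min(stats::rgamma(n, shape = state$g_alpha,
                                         rate = state$g_beta)),
    ts_normal = which.min(stats::rgamma(n, shape = state$g_alpha,
                                        rate = state$g_beta)),
    c_ts = which.min(stats::rnorm(n, state$mu_z,
                                  sqrt(1 / (1 + state$k_z)))))
}

#' Block outcome fed to the bandit
#'
#' @param value Block outcome: mean of the sensor's expected-RT estimate
#'   (or raw RT mean) over the block's trials. Must be positive.
#' @param values Per-trial estimates within the block (used by the
#'   normal-gamma posterior updates).
#' @return An object of class `"block_outcome"`.
#' @export
block_outcome <- function(value, values = value) {
  if (!is.finite(value) || value <= 0)
    stop("block_outcome: outcome must be positive")
  structure(list(value = value, values = as.numeric(values),
                 n = length(values)),
            class = "block_outcome")
}

# Reward threshold of the posterior update: the previous block's outcome if
# the site changed, else the best mean among the other sites. NA when no
# reference exists yet (very first block).
.rt_val <- function(state, site) {
  if (state$T == 0L) return(NA_real_)
  if (is.na(state$last_site) || site != state$last_site)
    return(state$last_outcome)
  others <- state$mean[-site]
  others <- others[is.finite(others)]
  if (!length(others)) NA_real_ else min(others)
}

#' Update the bandit after a block
#'
#' Increments the pull count, total selections and running mean outcome,
#' computes the reward threshold `RT_val` (previous block's outcome when the
#' site changed; the minimum mean of the other sites when it repeated), and
#' applies the algorithm's conjugate update. A block outcome at or above
#' `RT_val` counts against the site (failure); below it counts in its favor.
#' The very first block has no reference value, so only counts and means
#' update there.
#'
#' @param state A [bandit_state()].
#' @param site The site that was just stimulated.
#' @param outcome A [block_outcome()].
#' @return The updated `bandit_state`.
#' @export
update_state <- function(state, site, outcome) {
  stopifnot(site >= 1, site <= state$n_sites,
            inherits(outcome, "block_outcome"))
  rt_val <- .rt_val(state, site)
  val <- outcome$value

  if (is.finite(rt_val)) {
    fail <- as.numeric(val >= rt_val)
    switch(state$algorithm,
      bayes_ucb = ,
      ts_normal = {
        if (fail == 1) {
          state$g_alpha[site] <- state$g_alpha[site] + outcome$n / 2
        } else {
          mu_post <- state$g_alpha[site] / state$g_beta[site]
          state$g_beta[site] <- state$g_beta[site] +
            sum((outcome$values - mu_post)^2) / 2
        }
      },
      ts_bernoulli = {
        # beta posterior over the probability of a GOOD block (below the
        # reward threshold); best arm = largest posterior draw
        state$b_alpha[site] <- state$b_alpha[site] + (1 - fail)
        state$b_beta[site] <- state$b_beta[site] + fail
      },
      ts_poisson = {
        if (fail == 1) state$g_alpha[site] <- state$g_alpha[site] + val
        else state$g_beta[site] <- state$g_beta[site] + 1
      },
      NULL)
  }
  if (state$algorithm == "c_ts") {
    if (state$k_z[site] == 0) {
      state$mu_z[site] <- val
      state$k_z[site] <- 1
    } else {
      state$mu_z[site] <- (state$mu_z[site] * state$k_z[site] + val) /
        (state$k_z[site] + 1)
      state$k_z[site] <- state$k_z[site] + 1
    }
  }

  old_n <- state$N[site]
  state$N[site] <- old_n + 1L
  state$T <- state$T + 1L
  state$N_tr[site] <- state$N_tr[site] + outcome$n
  state$T_tr <- state$T_tr + outcome$n
  state$mean[site] <- if (old_n == 0L) val
    else (state$mean[site] * old_n + val) / (old_n + 1)
  state$last_site <- site
  state$last_outcome <- val
  state
}

#' Run one closed-loop optimization on a simulated participant
#'
#' Per block: a site is selected (held fixed for `blocksize` trials), the
#' generator emits RTs under that stimulation, each RT passes through the
#' sensor filter, the block outcome is the block's mean RT (by default the
#' observed mean; `outcome = "sensor"` uses the mean of the sensor's
#' conflict-free expected-RT estimate instead), and the bandit state is
#' updated. The sensor is fitted first to a
#' stimulation-free lead-in block; the optimization budget `n_trials` counts
#' only stimulated trials. After the budget the declared winner is the site
#' with the lowest mean block outcome.
#'
#' @param gen A [generator_params()] (its `b_in_*` are overridden by the
#'   problem's surface).
#' @param problem A [stim_problem()].
#' @param algorithm Bandit algorithm name (see [bandit_state()]).
#' @param n_trials Optimization trial budget; must cover at least one block
#'   per site.
#' @param blocksize Trials per block (1 = trial-wise operation).
#' @param sensor_fit_trials Length of the stimulation-free lead-in used to
#'   fit the sensor.
#' @param outcome `"raw"` (default; the block's mean observed RT) or
#'   `"sensor"` (mean of the sensor's conflict-free expected-RT estimate).
#' @param eps,conf Algorithm constants (see [bandit_state()]).
#' @return An object of class `"run_result"`: `chosen` site, `correct` flag,
#'   per-block trajectory `blocks`, per-site summary `per_site`, the final
#'   bandit `state` and the fitted `sensor`.
#' @export
run_closed_loop <- function(gen, problem, algorithm = "ucb1",
                            n_trials = 600, blocksize = 15,
                            sensor_fit_trials = 64,
                            outcome = c("raw", "sensor"),
                            eps = 0.1, conf = 1.96) {
  outcome <- match.arg(outcome)
  n_sites <- length(problem$effects)
  n_blocks <- n_trials %/% blocksize
  if (n_blocks < n_sites)
    stop("run_closed_loop: trial budget too small for forced exploration (",
         n_blocks, " blocks < ", n_sites, " sites)")
  gen <- generator_params(
    alpha_offset = gen$alpha_offset, v = gen$v, b0 = gen$b0,
    b1 = gen$b1, b2 = gen$b2, a1 = gen$a1, a2 = gen$a2,
    sigma1 = gen$sigma1, sigma2 = gen$sigma2,
    b_in_base = problem$effects,
    x0_base = gen$x0_base, x0_conflict = gen$x0_conflict, rho = gen$rho)

  # stimulation-free lead-in: generator runs, sensor is fitted to its output
  lead <- simulate_session(gen, sensor_fit_trials)
  sensor <- fit_sensor(lead)
  # continue the generator from the end of the lead-in (no stimulation was
  # applied there, so the recorded truth is the endogenous state)
  st <- latent_state(lead$x_base_true[sensor_fit_trials],
                     lead$x_conflict_true[sensor_fit_trials])
  st <- step_states(st, gen, NA)

  state <- bandit_state(n_sites, algorithm, eps = eps, conf = conf)
  forced <- forced_exploration(state)
  blocks <- data.frame(block = seq_len(n_blocks),
                       site = NA_integer_, outcome = NA_real_)
  for (b in seq_len(n_blocks)) {
    site <- if (b <= n_sites && algorithm != "brute_force") forced[b]
            else select_site(state)
    est <- numeric(blocksize); raw <- numeric(blocksize)
    for (k in seq_len(blocksize)) {
      sv <- state_values(st)
      I <- stats::rbinom(1, 1, 0.5)
      mu <- mean_rt(sv[1], sv[2], I, gen$b0, gen$b1, gen$b2)
      rt <- sample_rt(mu, gen$v, gen$alpha_offset)
      stp <- sensor_step(sensor, rt, I)
      sensor <- stp$sensor
      est[k] <- stp$estimate[["rt_base"]]
      raw[k] <- rt
      st <- step_states(st, gen, site)
    }
    vals <- if (outcome == "sensor") est else raw
    state <- update_state(state, site, block_outcome(mean(vals), vals))
    blocks$site[b] <- site
    blocks$outcome[b] <- mean(vals)
  }
  chosen <- which.min(state$mean)
  structure(list(chosen = chosen, correct = chosen == problem$optimal,
                 blocks = blocks,
                 per_site = data.frame(site = seq_len(n_sites),
                                       N = state$N, mean = state$mean),
                 state = state, sensor = sensor,
                 algorithm = algorithm, problem = problem),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result %s> chose site %d (%s); %d blocks\n",
              x$algorithm, x$chosen,
              if (x$correct) "correct" else
                sprintf("optimum was %d", x$problem$optimal),
              nrow(x$blocks)))
  invisible(x)
}

#' Majority vote over repeated optimization runs
#'
#' Declares the most frequently chosen site across runs. Ties break toward
#' the tied site with the lowest pooled mean outcome (pooled over all runs,
#' weighted by per-run pull counts).
#'
#' @param results Nonempty list of [run_closed_loop()] results.
#' @return Winning site index.
#' @export
majority_vote <- function(results) {
  if (!length(results)) stop("majority_vote: empty result list")
  votes <- vapply(results, function(r) r$chosen, integer(1))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  if (length(winners) == 1L) return(winners)
  pooled <- vapply(winners, function(s) {
    num <- 0; den <- 0
    for (r in results) {
      n <- r$per_site$N[s]
      if (n > 0 && is.finite(r$per_site$mean[s])) {
        num <- num + r$per_site$mean[s] * n
        den <- den + n
      }
    }
    if (den == 0) Inf else num / den
  }, numeric(1))
  winners[which.min(pooled)]
}
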