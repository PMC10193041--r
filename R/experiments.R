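# Declarative experiment harness: accuracy sweeps over blocksize, trial
# budget, problem size, SNR and effect discriminability, plus ensemble
# (majority-vote) runs. Replicate seeds are derived from the base seed by
# counter, so full reports are deterministic and order-invariant.

#' Signal-to-noise ratio of a stimulation problem, in decibels
#'
#' `20 * log10(b_diff / sigma)`, where `b_diff` is the gap between the best
#' and second-best site effects (log-seconds) and `sigma` the state-noise SD.
#'
#' @param b_diff Effect gap, > 0.
#' @param sigma State-noise SD, > 0.
#' @return SNR in dB.
#' @export
#' @examples
#' snr_db(0.03, 0.5)   # -24.44 dB
#' snr_db(0.03, 0.03)  # 0 dB
snr_db <- function(b_diff, sigma) {
  if (any(b_diff <= 0) || any(sigma <= 0))
    stop("snr_db: b_diff and sigma must be positive")
  20 * log10(b_diff / sigma)
}

#' Declarative experiment configuration
#'
#' @param sweep One of `"blocksize"`, `"budget"`, `"sites"`, `"snr"`,
#'   `"discriminability"`, or `"none"` (single cell).
#' @param values Sweep values: blocksizes, trial budgets, site counts
#'   (2/4/6/8), state-noise SDs, or discriminability labels `"b1"`..`"b7"`.
#' @param algorithms Character vector of bandit algorithms.
#' @param replicates Replicates per cell.
#' @param n_trials Trial budget per replicate (unless swept).
#' @param blocksize Trials per block (unless swept).
#' @param problem Problem label or [stim_problem()] (unless swept).
#' @param seed Base seed; all replicate seeds derive from it.
#' @param outcome `"raw"` or `"sensor"` block outcome.
#' @param sensor_fit_trials Sensor lead-in length.
#' @param archetype A [participant_archetype()].
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(sweep = "none", values = NULL,
                              algorithms = "ucb1", replicates = 1000,
                              n_trials = 600, blocksize = 15,
                              problem = "sites8", seed = 1,
                              outcome = "raw", sensor_fit_trials = 64,
                              archetype = participant_archetype()) {
  sweep <- match.arg(sweep, c("none", "blocksize", "budget", "sites",
                              "snr", "discriminability"))
  if (is.null(values)) values <- switch(sweep,
    none = NA, blocksize = c(1, seq(5, 50, by = 5)),
    budget = seq(100, 1000, by = 100), sites = c(2, 4, 6, 8),
    snr = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05, 0.04, 0.03, 0.02, 0.01, 0.005),
    discriminability = paste0("b", 1:7))
  stopifnot(replicates >= 1, n_trials >= 1, blocksize >= 1)
  algorithms <- vapply(algorithms, match.arg, character(1),
                       choices = BANDIT_ALGORITHMS, USE.NAMES = FALSE)
  structure(list(sweep = sweep, values = values, algorithms = algorithms,
                 replicates = replicates, n_trials = n_trials,
                 blocksize = blocksize, problem = problem, seed = seed,
                 outcome = outcome, sensor_fit_trials = sensor_fit_trials,
                 archetype = archetype),
            class = "experiment_config")
}

#' Load an experiment configuration from a YAML file
#'
#' Recognized keys mirror the [experiment_config()] arguments; unknown keys
#' are rejected. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config_from_yaml requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(experiment_config)), "archetype")
  bad <- setdiff(names(raw), c(known, "archetype"))
  if (length(bad))
    stop("config_from_yaml: unknown keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$archetype))
    raw$archetype <- do.call(participant_archetype, raw$archetype)
  do.call(experiment_config, raw)
}

# deterministic per-replicate seed table
.replicate_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# resolve one sweep cell into run_closed_loop arguments
.cell_setup <- function(config, value) {
  out <- list(n_trials = config$n_trials, blocksize = config$blocksize,
              problem = config$problem, sigma_override = NULL)
  switch(config$sweep,
    blocksize = { out$blocksize <- value },
    budget = { out$n_trials <- value },
    sites = { out$problem <- paste0("sites", value) },
    snr = { out$sigma_override <- value },
    discriminability = { out$problem <- value },
    none = NULL)
  out
}

.resolve_problem <- function(problem) {
  if (inherits(problem, "stim_problem")) problem else stim_problem(problem)
}

# one replicate: fresh participant, shuffled surface, one closed-loop run
.one_replicate <- function(config, cell, rep_seed) {
  set.seed(rep_seed)
  problem <- shuffle_problem(.resolve_problem(cell$problem))
  gen <- sample_participant(config$archetype)
  if (!is.null(cell$sigma_override)) {
    s <- abs(cell$sigma_override + stats::rnorm(2, 0, 1e-4))
    gen$sigma1 <- s[1]; gen$sigma2 <- s[2]
  }
  list(gen = gen, problem = problem)
}

#' Run an accuracy sweep
#'
#' For every cell (algorithm x sweep value), runs `replicates` independent
#' closed-loop optimizations, each with a fresh synthetic participant, a
#' fresh sensor, and the optimal site's position shuffled. Accuracy is the
#' fraction of replicates whose declared site equals the known optimum. The
#' SNR sweep overrides the generator's state-noise SDs with the swept value
#' (jittered by N(0, 1e-4) so each replicate uses a slightly different
#' generator). Failed replicates are excluded with their count reported.
#'
#' @param config An [experiment_config()].
#' @return An accuracy report `data.frame` (class `"accuracy_report"`):
#'   one row per cell with `algorithm`, `sweep`, `value`, `n`, `failed`,
#'   `accuracy` and binomial `se`.
#' @export
run_sweep <- function(config) {
  values <- config$values
  n_cells <- length(config$algorithms) * length(values)
  seeds <- matrix(.replicate_seeds(config$seed,
                                   n_cells * config$replicates),
                  nrow = config$replicates)
  rows <- list(); cell_i <- 0
  for (alg in config$algorithms) for (v in values) {
    cell_i <- cell_i + 1
    cell <- .cell_setup(config, v)
    correct <- logical(0); failed <- 0L
    for (r in seq_len(config$replicates)) {
      inp <- .one_replicate(config, cell, seeds[r, cell_i])
      res <- tryCatch(
        run_closed_loop(inp$gen, inp$problem, alg,
                        n_trials = cell$n_trials,
                        blocksize = cell$blocksize,
                        sensor_fit_trials = config$sensor_fit_trials,
                        outcome = config$outcome),
        error = function(e) NULL)
      if (is.null(res)) failed <- failed + 1L
      else correct <- c(correct, res$correct)
    }
    n <- length(correct)
    p <- if (n) mean(correct) else NA_real_
    rows[[cell_i]] <- data.frame(
      algorithm = alg, sweep = config$sweep, value = as.character(v),
      n = n, failed = failed, accuracy = p,
      se = if (n) sqrt(p * (1 - p) / n) else NA_real_)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Run ensemble (majority-vote) experiments
#'
#' Per ensemble replicate: one fixed synthetic participant, `max(n_votes)`
#' independent closed-loop runs (fresh sensor and fresh simulated behavior
#' each run), and for each requested ensemble size the hard majority vote of
#' the first that many runs. An ensemble of 1 reduces exactly to single-run
#' accuracy.
#'
#' @param config An [experiment_config()] (its `sweep` is ignored; `problem`,
#'   `n_trials`, `blocksize` define the task).
#' @param n_votes Integer vector of ensemble sizes (>= 1).
#' @return An accuracy report `data.frame` with `value` = ensemble size.
#' @export
run_ensemble <- function(config, n_votes = 1:7) {
  stopifnot(all(n_votes >= 1))
  n_max <- max(n_votes)
  seeds <- matrix(.replicate_seeds(config$seed,
                                   length(config$algorithms) *
                                     config$replicates),
                  nrow = config$replicates)
  rows <- list(); i <- 0
  for (a_i in seq_along(config$algorithms)) {
    alg <- config$algorithms[a_i]
    correct <- matrix(NA, config$replicates, length(n_votes))
    failed <- 0L
    for (r in seq_len(config$replicates)) {
      set.seed(seeds[r, a_i])
      problem <- shuffle_problem(.resolve_problem(config$problem))
      gen <- sample_participant(config$archetype)
      runs <- list()
      ok <- TRUE
      for (vte in seq_len(n_max)) {
        res <- tryCatch(
          run_closed_loop(gen, problem, alg,
                          n_trials = config$n_trials,
                          blocksize = config$blocksize,
                          sensor_fit_trials = config$sensor_fit_trials,
                          outcome = config$outcome),
          error = function(e) NULL)
        if (is.null(res)) { ok <- FALSE; break }
        runs[[vte]] <- res
      }
      if (!ok) { failed <- failed + 1L; next }
      for (j in seq_along(n_votes))
        correct[r, j] <- majority_vote(runs[seq_len(n_votes[j])]) ==
          problem$optimal
    }
    for (j in seq_along(n_votes)) {
      i <- i + 1
      cj <- correct[, j]
      cj <- cj[!is.na(cj)]
      p <- mean(cj)
      rows[[i]] <- data.frame(
        algorithm = alg, sweep = "ensemble",
        value = as.character(n_votes[j]),
        n = length(cj), failed = failed, accuracy = p,
        se = sqrt(p * (1 - p) / length(cj)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", class(out))
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
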