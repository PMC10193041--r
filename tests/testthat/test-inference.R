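test_that("logarithmic scale maps to the documented noise SDs", {
  expect_equal(scale_to_sigma(40), 9.5367e-07, tolerance = 1e-5)
  expect_equal(scale_to_sigma(1), 0.707, tolerance = 1e-3)
  expect_equal(scale_to_sigma(8), 0.0625, tolerance = 1e-12)
  expect_equal(scale_to_sigma(16), 0.00390625)
  expect_equal(scale_to_sigma(13), 0.0110, tolerance = 1e-2)
  expect_true(all(diff(scale_to_sigma(1:40)) < 0))
})

test_that("filter with no observations reproduces the AR rollout", {
  gp <- generator_params(alpha_offset = 0.2, v = 20, b0 = log(0.6),
                         a1 = 0.9, a2 = 0.8, sigma1 = 0, sigma2 = 0,
                         x0_base = 1, x0_conflict = -0.5)
  tr <- data.frame(trial = 0:9, conflict = 0, site = NA, rt_s = NA_real_)
  fs <- filter_states(gp, tr, P0 = 0.3)
  expect_equal(fs$filtered$x_base, 0.9^(1:10))
  expect_equal(fs$filtered$x_conflict, -0.5 * 0.8^(1:10))
  expect_equal(fs$smoothed$x_base, fs$filtered$x_base)
})

test_that("single-trial posterior agrees with a dense grid oracle", {
  gp <- quiet_gen()
  gp$a1 <- 1; gp$a2 <- 1; gp$sigma1 <- 0; gp$sigma2 <- 0
  for (rt in c(0.55, 0.9, 1.4)) {
    tr <- data.frame(trial = 0, conflict = 0, site = NA, rt_s = rt)
    fs <- filter_states(gp, tr, x0 = c(0, 0), P0 = 0.5, smooth = FALSE)
    oracle <- grid_posterior_1d(rt, gp, m0 = 0, P0 = 0.5)
    expect_lt(abs(fs$filtered$x_base[1] - oracle$mean), 1e-3)
    expect_lt(abs(fs$filtered$var_base[1] - oracle$var), 1e-3)
    # the update shrinks the prior uncertainty
    expect_lt(fs$filtered$var_base[1], 0.5)
  }
})

test_that("filter rejects RTs below the offset unless told to skip", {
  gp <- quiet_gen()
  tr <- data.frame(trial = 0:1, conflict = 0, site = NA, rt_s = c(0.8, 0.1))
  expect_error(filter_states(gp, tr), "inconsistent offset")
  fs <- filter_states(gp, tr, on_invalid = "skip")
  expect_identical(fs$n_skipped, 1L)
})

test_that("EM recovers generating parameters and obeys its stopping rule", {
  set.seed(300)
  gen <- quiet_gen()
  b0_err <- v_ratio <- numeric(8)
  for (i in 1:8) {
    tr <- simulate_session(gen, 800)
    fit <- suppressWarnings(
      em_fit(tr, fit_spec(scale1 = 14, scale2 = 20, x0 = c(0, 0.3),
                          P0 = 1e-4)))
    b0_err[i] <- fit$params$b0 - log(0.6)
    v_ratio[i] <- fit$params$v / 20
    # tracked likelihood is non-decreasing up to approximation tolerance
    if (fit$iterations > 1)
      expect_true(all(diff(fit$ml_trace) >
                        -1e-4 * abs(fit$ml_trace[-fit$iterations])))
    # stopping: relative ML change below the threshold exactly at the end
    if (fit$converged) {
      rel <- abs(diff(fit$ml_trace)) / abs(fit$ml_trace[-fit$iterations])
      expect_lt(rel[length(rel)], 0.001)
      if (length(rel) > 1)
        expect_true(all(rel[-length(rel)] >= 0.001))
    }
  }
  expect_lt(abs(mean(b0_err)), 0.1)
  expect_lt(abs(mean(v_ratio) - 1), 0.25)
})

test_that("EM reports non-convergence instead of hiding it", {
  set.seed(301)
  tr <- simulate_session(quiet_gen(), 300)
  expect_warning(em_fit(tr, fit_spec(scale1 = 14, scale2 = 20,
                                     x0 = c(0, 0.3), max_iter = 2)),
                 "did not reach")
})

test_that("deviance equals an independently coded gamma deviance", {
  set.seed(302)
  gen <- quiet_gen()
  tr <- simulate_session(gen, 10)
  traj <- filter_states(gen, tr, smooth = FALSE)
  d <- rt_deviance(gen, tr, traj)
  y <- tr$rt_s - gen$alpha_offset
  mu <- traj$filtered$mu_onestep
  oracle <- -2 * (sum(dgamma(y, shape = gen$v, rate = gen$v / mu, log = TRUE)) -
                  sum(dgamma(y, shape = gen$v, rate = gen$v / y, log = TRUE)))
  expect_equal(d, oracle, tolerance = 1e-10)

  # a model predicting each RT exactly has deviance zero
  perfect <- traj
  perfect$filtered$mu_onestep <- y
  expect_equal(rt_deviance(gen, tr, perfect), 0)

  # a worse-fitting b0 strictly increases deviance on the same data
  worse <- gen; worse$b0 <- gen$b0 + 1
  expect_gt(rt_deviance(worse, tr), d)
  expect_error(rt_deviance(generator_params(alpha_offset = 2, v = 20, b0 = 0),
                           tr), "undefined")
})

test_that("grid search returns a complete, reproducible surface", {
  set.seed(303)
  tr <- simulate_session(quiet_gen(10, 20), 150)
  run <- function() grid_search_w(tr, scale1 = c(8, 12), scale2 = c(18, 22),
                                  spec = fit_spec(max_iter = 10),
                                  n_restarts = 2)
  set.seed(42); g1 <- run()
  set.seed(42); g2 <- run()
  expect_identical(dim(g1$deviance), c(2L, 2L))
  expect_true(all(is.finite(g1$deviance)))
  expect_identical(g1$deviance, g2$deviance)
  df <- as.data.frame(g1)
  expect_identical(nrow(df), 4L)
  expect_true(all(c("scale1", "scale2", "deviance", "alpha", "v", "b0")
                  %in% names(df)))
  # full-range grid arithmetic
  expect_identical(length(1:40) * length(1:40), 1600L)
})
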