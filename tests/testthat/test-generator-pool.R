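test_that("archetype draws stay within the documented ranges", {
  set.seed(400)
  pool <- build_pool(200)
  s1 <- vapply(pool, `[[`, numeric(1), "sigma1")
  s2 <- vapply(pool, `[[`, numeric(1), "sigma2")
  expect_true(all(s1 >= scale_to_sigma(16) & s1 <= scale_to_sigma(7)))
  expect_true(all(s2 >= scale_to_sigma(27) & s2 <= scale_to_sigma(13)))
  a <- vapply(pool, `[[`, numeric(1), "alpha_offset")
  expect_true(all(a >= 0.1 & a <= 0.3))
  v <- vapply(pool, `[[`, numeric(1), "v")
  expect_true(all(v >= 10 & v <= 40))
  expect_true(all(vapply(pool, function(p) p$a1 == 0.9999, logical(1))))

  set.seed(9); p1 <- sample_participant()
  set.seed(9); p2 <- sample_participant()
  expect_identical(p1, p2)
})

test_that("response surfaces match their tables and shuffle cleanly", {
  p8 <- stim_problem("sites8")
  expect_identical(p8$effects,
                   c(0, -0.005, -0.01, -0.02, -0.03, -0.031, -0.04, -0.07))
  expect_identical(p8$optimal, 8L)
  expect_identical(stim_problem("sites4")$effects, c(0, -0.005, -0.01, -0.04))
  expect_identical(stim_problem("sites2")$effects, c(-0.01, -0.04))
  expect_identical(stim_problem("bss")$effects, c(0.25, -0.25))
  # degenerate two-site problem: identical effects, tie broken to site 1
  b7 <- stim_problem("b7")
  expect_identical(b7$effects, c(0, 0))
  expect_identical(b7$optimal, 1L)
  expect_error(stim_problem("b99"), "unknown surface")

  set.seed(401)
  sh <- shuffle_problem(p8)
  expect_setequal(sh$effects, p8$effects)
  expect_identical(sh$optimal, which.min(sh$effects))

  # conflict-state effects are ten-fold smaller than baseline effects
  gen <- sample_participant(problem = p8)
  expect_equal(gen$b_in_conflict, gen$b_in_base / 10)
})

test_that("simulated sessions have the expected structure and statistics", {
  set.seed(402)
  gen <- quiet_gen()
  tr <- simulate_session(gen, 1000)
  expect_identical(nrow(tr), 1000L)
  expect_true(all(tr$rt_s > gen$alpha_offset))
  # conflict fraction ~ 0.5 within a 3-sigma binomial band
  expect_lt(abs(mean(tr$conflict) - 0.5), 3 * sqrt(0.25 / 1000))
  # conflict cost visible in the raw RTs
  expect_gt(mean(tr$rt_s[tr$conflict == 1]), mean(tr$rt_s[tr$conflict == 0]))

  # noise-free unstimulated session: RT mean matches the closed form
  gnf <- noise_free_gen(v = 30)
  tnf <- simulate_session(gnf, 4000)
  nc <- tnf$conflict == 0
  mu0 <- exp(gnf$b0 + gnf$x0_base)
  se <- mu0 / sqrt(30 * sum(nc))
  expect_lt(abs(mean(tnf$rt_s[nc]) - (mu0 + gnf$alpha_offset)), 4 * se)
  expect_error(simulate_session(gen, 10, schedule = rep(3, 10)),
               "invalid site")
})

test_that("stimulation lowers late-session states by the site effect", {
  gnf <- noise_free_gen(effects = c(0, -0.005, -0.01, -0.04))
  n <- 60
  late_x <- vapply(1:4, function(s) {
    tr <- simulate_session(gnf, n, schedule = rep(s, n))
    tr$x_base_true[n]
  }, numeric(1))
  expect_equal(late_x, c(0, -0.005, -0.01, -0.04), tolerance = 1e-6)
  # effect-ordering: steady-state mean RTs ordered like the effects
  expect_identical(order(late_x), order(gnf$b_in_base))
})

test_that("KS gamma check passes true gamma data and rejects uniform data", {
  set.seed(403)
  # a pure shifted-gamma sample (no drift) must pass essentially always
  p_true <- replicate(20, ks_gamma_test(sample_rt(rep(0.6, 1000), 20,
                                                  0.2))$p_value)
  expect_gt(mean(p_true > 0.05), 0.9)
  # power check: uniform fake RTs are detected
  p_unif <- replicate(20, ks_gamma_test(runif(1000))$p_value)
  expect_lt(mean(p_unif > 0.05), 0.1)
  expect_error(ks_gamma_test(rep(1, 100)), "degenerate")
  expect_error(ks_gamma_fraction(build_pool(2), n_runs = 0), "n_runs")
})

test_that("trial logs and pools round-trip through their file formats", {
  set.seed(404)
  gen <- sample_participant(problem = stim_problem("sites2"))
  tr <- simulate_session(gen, 20, schedule = c(rep(NA, 10), rep(2, 10)))
  f <- tempfile(fileext = ".csv")
  write_trial_log(tr, f)
  back <- read_trial_log(f)
  expect_equal(back$rt_s, tr$rt_s)
  expect_identical(back$site, as.integer(tr$site))
  expect_identical(back$conflict, tr$conflict)

  pool <- build_pool(3, problem = stim_problem("sites4"))
  fp <- tempfile(fileext = ".jsonl")
  write_pool(pool, fp, seed = 404)
  back_pool <- read_pool(fp)
  expect_identical(length(back_pool), 3L)
  expect_equal(back_pool[[2]]$b0, pool[[2]]$b0)
  expect_equal(back_pool[[3]]$b_in_base, pool[[3]]$b_in_base)
  unlink(c(f, fp))
})
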