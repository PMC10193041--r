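# helper: a bandit state with hand-set statistics (counts in trials == blocks
# here, i.e. blocksize-1 operation)
make_state <- function(algorithm, means, counts, ...) {
  st <- bandit_state(length(means), algorithm, ...)
  st$mean <- means
  st$N <- as.integer(counts); st$N_tr <- as.integer(counts)
  st$T <- sum(as.integer(counts)); st$T_tr <- st$T
  st
}

test_that("UCB1 scores follow the printed cost function", {
  # equal counts: the bonus cancels and the lower mean wins
  st <- make_state("ucb1", c(0.5, 0.6), c(10, 10))
  expect_identical(select_site(st), 1L)
  # under-sampled site: exploration bonus dominates
  st <- make_state("ucb1", c(0.5, 0.6), c(50, 2))
  expect_identical(select_site(st), 2L)
  bonus2 <- sqrt(2 * log(52) / 2)
  expect_equal(bonus2, 1.987, tolerance = 1e-3)
  expect_lt(0.6 - bonus2, 0.5 - sqrt(2 * log(52) / 50))
})

test_that("greedy exploits, ties break to the lowest index", {
  st <- make_state("greedy", c(0.7, 0.5, 0.5), c(3, 3, 3))
  expect_identical(select_site(st), 2L)
  st$mean <- c(0.5, 0.5, 0.5)
  expect_identical(select_site(st), 1L)
  # eps-greedy explores with probability eps
  st <- make_state("eps_greedy", c(0.5, 0.9), c(5, 5), eps = 0.5)
  set.seed(600)
  picks <- replicate(2000, select_site(st))
  # greedy arm picked with p = 1 - eps + eps/2 = 0.75
  expect_lt(abs(mean(picks == 1L) - 0.75), 3 * sqrt(0.75 * 0.25 / 2000))
})

test_that("selection requires completed forced exploration", {
  st <- bandit_state(4, "greedy")
  expect_error(select_site(st), "forced exploration")
  expect_setequal(forced_exploration(st), 1:4)
  set.seed(601); o1 <- bandit_state(8, "ucb1")$forced_order
  set.seed(601); o2 <- bandit_state(8, "ucb1")$forced_order
  set.seed(602); o3 <- bandit_state(8, "ucb1")$forced_order
  expect_identical(o1, o2)
  expect_false(identical(o1, o3))
  expect_setequal(o1, 1:8)
})

test_that("Thompson variants are symmetric under identical hyperparameters", {
  set.seed(603)
  for (alg in c("ts_bernoulli", "ts_poisson", "ts_normal", "c_ts")) {
    st <- make_state(alg, rep(0.5, 4), rep(2, 4))
    st$mu_z <- rep(0.5, 4); st$k_z <- rep(1, 4)
    picks <- replicate(4000, select_site(st))
    freq <- tabulate(picks, 4) / 4000
    expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000) + 0.01),
                info = alg)
  }
})

test_that("conjugate updates follow the reward-threshold rule", {
  # thresholded Bernoulli branches: good block rewards, bad block penalizes
  st <- make_state("ts_bernoulli", c(0.8, NA), c(1, 0))
  st$last_site <- 1L; st$last_outcome <- 0.8
  st2 <- update_state(st, 2L, block_outcome(0.7))  # new site, 0.7 < 0.8
  expect_identical(st2$b_alpha[2], 2)   # success
  expect_identical(st2$b_beta[2], 1)
  st3 <- update_state(st2, 1L, block_outcome(0.9)) # new site, 0.9 >= 0.7
  expect_identical(st3$b_beta[1], 2)    # failure
  expect_identical(st3$b_alpha[1], 1)

  # repeated site: threshold is the best mean among the other sites
  st4 <- update_state(st3, 1L, block_outcome(0.6)) # 0.6 < mean(site2)=0.7
  expect_identical(st4$b_alpha[1], 2)

  # the very first block has no reference: only counts and means update
  st0 <- bandit_state(2, "ts_bernoulli")
  st0b <- update_state(st0, 1L, block_outcome(0.8))
  expect_identical(st0b$b_alpha, c(1, 1))
  expect_identical(st0b$b_beta, c(1, 1))
  expect_identical(st0b$N[1], 1L)
  expect_equal(st0b$mean[1], 0.8)

  # normal-gamma branch arithmetic (failure adds n/2 to the shape)
  sg <- make_state("bayes_ucb", c(0.5, 0.8), c(1, 1))
  sg$last_site <- 2L; sg$last_outcome <- 0.8
  sg2 <- update_state(sg, 1L, block_outcome(0.9, values = rep(0.9, 15)))
  expect_equal(sg2$g_alpha[1], 0.5 + 15 / 2)
  mu_post <- 0.5 / 0.5
  sg3 <- update_state(sg2, 2L, block_outcome(0.4, values = c(0.4, 0.5)))
  expect_equal(sg3$g_beta[2], 0.5 + sum((c(0.4, 0.5) - mu_post)^2) / 2)

  # C-TS conjugate normal update
  sc <- make_state("c_ts", c(1, 1), c(1, 1))
  sc$mu_z <- c(1, 1); sc$k_z <- c(1, 1)
  sc$last_site <- 2L; sc$last_outcome <- 1
  sc2 <- update_state(sc, 1L, block_outcome(0.5))
  expect_equal(sc2$mu_z[1], 0.75)
  expect_equal(sc2$k_z[1], 2)

  expect_error(block_outcome(-0.5), "positive")
})

test_that("closed loop conserves counts and honors its allocation rules", {
  set.seed(604)
  gen <- sample_participant()
  prob <- stim_problem("sites8")
  r <- run_closed_loop(gen, prob, "brute_force", 600, 15)
  # 600/15/8 = 5 blocks per site, counts conserved
  expect_identical(r$state$N, rep(5L, 8))
  expect_identical(r$state$T, 40L)
  expect_identical(sum(r$state$N_tr), 600L)
  expect_identical(nrow(r$blocks), 40L)

  r2 <- run_closed_loop(gen, stim_problem("sites2"), "ucb1", 30, 1)
  expect_identical(r2$state$T, 30L)  # blocksize 1 is trial-wise operation
  expect_identical(sum(r2$state$N), 30L)

  expect_error(run_closed_loop(gen, prob, "ucb1", 100, 15),
               "too small for forced exploration")
})

test_that("UCB1 concentrates on the better arm as samples accumulate", {
  set.seed(605)
  st <- bandit_state(2, "ucb1")
  outcomes <- c(0.5, 0.6)
  share <- numeric(2)
  for (b in 1:10000) {
    site <- if (b <= 2) forced_exploration(st)[b] else select_site(st)
    st <- update_state(st, site, block_outcome(outcomes[site]))
    if (b == 2000) share[1] <- st$N[1] / st$T
  }
  share[2] <- st$N[1] / st$T
  # suboptimal pulls grow only logarithmically: the optimum's share keeps
  # rising toward 1
  expect_gt(share[2], 0.85)
  expect_gt(share[2], share[1])
})

test_that("a separable noise-free two-site problem is always solved", {
  set.seed(606)
  prob <- stim_problem("b2")   # effects 0 vs -0.10
  for (alg in c("ucb1", "greedy", "brute_force")) {
    correct <- replicate(12, {
      gen <- noise_free_gen(effects = prob$effects, v = 30)
      run_closed_loop(gen, prob, alg, 600, 15)$correct
    })
    expect_identical(mean(correct), 1, info = alg)
  }
})

test_that("majority vote picks the modal site with the documented tie-break", {
  fake <- function(chosen, mean2 = 0.7)
    list(chosen = as.integer(chosen),
         per_site = data.frame(site = 1:3, N = c(5L, 5L, 5L),
                               mean = c(0.8, mean2, 0.9)))
  expect_identical(majority_vote(list(fake(2), fake(2), fake(3))), 2L)
  expect_identical(majority_vote(list(fake(1))), 1L)
  # tie between 1 and 2: site 2 has the lower pooled mean outcome
  expect_identical(majority_vote(list(fake(1), fake(1), fake(2), fake(2))), 2L)
  expect_error(majority_vote(list()), "empty")
})
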