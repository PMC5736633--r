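test_that("softmax policy matches direct evaluation and is stable at high beta", {
  expect_equal(softmax_policy(c(0.2, 0.7, 0.4), 0), rep(1 / 3, 3))
  expect_equal(softmax_policy(c(1, 0), 1),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  p <- softmax_policy(c(1, 0.5), 200)
  expect_gte(p[1], 1 - 1e-10)
  expect_false(anyNA(p))
  # order preservation on random values
  set.seed(1)
  for (i in 1:20) {
    v <- runif(4)
    p <- softmax_policy(v, runif(1, 0, 50))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(order(p), order(v))
  }
  expect_error(softmax_policy(numeric(0), 1), "empty")
})

test_that("model-based transitions follow the novel/repeat learning rules", {
  s <- mb_state()
  s <- mb_observe_transition(s, "F", c(eta = 0.5))
  expect_equal(unname(s$T[1, "F"]), 0.5)          # first traversal: T = eta
  expect_equal(s$current, 2L)
  s$current <- 1L
  s <- mb_observe_transition(s, "F", c(eta = 0.5))
  expect_equal(unname(s$T[1, "F"]), 0.75)         # repeat: T + eta (1 - T)
  # eta = 1 is a fixed point
  s1 <- mb_state()
  for (i in 1:5) {
    s1 <- mb_observe_transition(s1, "L", c(eta = 1))
    s1$current <- 1L
  }
  expect_equal(unname(s1$T[1, "L"]), 1)
  # U-turns never close cycles: a fresh node is created each time
  s2 <- mb_state()
  s2 <- mb_observe_transition(s2, "F", c(eta = 0.5))
  s2 <- mb_observe_transition(s2, "U", c(eta = 0.5))
  expect_equal(length(s2$V), 3L)
  expect_true(all(diff(s2$depth) > 0))
})

test_that("value iteration propagates reward down the transition tree", {
  # three-node chain with certain transitions and a rewarded leaf
  s <- mb_state()
  s <- mb_observe_transition(s, "F", c(eta = 1))
  s <- mb_observe_transition(s, "F", c(eta = 1), reward_found = TRUE)
  s <- mb_value_iteration(s, gamma = 0.9)
  expect_equal(unname(s$V), c(0.81, 0.9, 1.0), tolerance = 1e-6)

  # no reward anywhere: all values stay zero
  s0 <- mb_state()
  s0 <- mb_observe_transition(s0, "F", c(eta = 0.7))
  s0 <- mb_value_iteration(s0, gamma = 0.9)
  expect_true(all(s0$V == 0))

  # gamma = 0 kills propagation: V equals R
  sg <- mb_state()
  sg <- mb_observe_transition(sg, "F", c(eta = 1), reward_found = TRUE)
  sg <- mb_value_iteration(sg, gamma = 0)
  expect_equal(unname(sg$V), c(0, 1))
})

test_that("value iteration is monotone and bounded on random trees", {
  set.seed(3)
  for (rep in 1:5) {
    s <- mb_state()
    for (i in 1:40) {
      s$current <- sample(length(s$V), 1)
      s <- mb_observe_transition(s, sample(c("F", "L", "R", "U"), 1),
                                 c(eta = runif(1)),
                                 reward_found = runif(1) < 0.1)
    }
    v0 <- s$V
    s1 <- mb_value_iteration(s, gamma = 0.9)
    expect_true(all(s1$V >= v0 - 1e-12))
    expect_true(all(s1$V >= 0 & s1$V <= 1))
    expect_true(all(s1$T >= 0 & s1$T <= 1))
    # a second call is a no-op at the fixed point
    s2 <- mb_value_iteration(s1, gamma = 0.9)
    expect_equal(s2$V, s1$V, tolerance = 1e-5)
  }
})

test_that("action values are zero for untried actions else discounted products", {
  s <- mb_state()
  s <- mb_observe_transition(s, "F", c(eta = 1), reward_found = TRUE)
  s <- mb_value_iteration(s, gamma = 0.9)
  s$current <- 1L
  q <- mb_action_values(s, gamma = 0.9)
  expect_equal(unname(q["F"]), 0.9)   # T = 1, V(child) = 1, gamma 0.9
  expect_equal(unname(q[c("L", "R", "U")]), c(0, 0, 0))
})

test_that("model-free state keys concatenate observation and action memory", {
  expect_equal(mf_encode_state("Y"), "Y")
  expect_equal(mf_encode_state("I", rep("-", 3)), "I|-|-|-")
  k1 <- mf_encode_state("Y", c("F", "L", "F"))
  k2 <- mf_encode_state("Y", c("L", "F", "F"))
  expect_false(k1 == k2)
})

test_that("temporal-difference updates follow the prediction error", {
  s <- mf_state(3)
  p <- c(eta = 0.5, gamma = 0.9)
  # terminal reward from zero values: delta = 1
  s1 <- mf_td_update(s, "sA", "F", 1, NULL, p)
  expect_equal(attr(s1, "delta"), 1)
  expect_equal(unname(s1$V["sA"]), 0.5)
  expect_equal(unname(s1$p["sA@F"]), 0.5)
  # zero everywhere: no change
  s2 <- mf_td_update(s, "sA", "F", 0, "sB", p)
  expect_equal(attr(s2, "delta"), 0)
  # bootstrapped value: delta = gamma V(next)
  s3 <- mf_td_update(s1, "sC", "L", 0, "sD", p)
  expect_equal(attr(s3, "delta"), 0)
  s3$V["sD"] <- 1
  s3 <- mf_td_update(s3, "sC", "L", 0, "sD", p)
  expect_equal(attr(s3, "delta"), 0.9)
})

test_that("position belief stays normalized and its spread grows linearly", {
  grid <- list(gx = as.numeric(0:5) * 10, gy = rep(0, 6))
  s <- pi_state(grid, c(0, 0))
  expect_equal(sum(s$pos), 1)
  # zero noise: all mass on the nearest grid point to the dead-reckoned pos
  s0 <- pi_propagate(s, c(10, 0), c(sigma0 = 0))
  expect_equal(s0$pos, c(0, 1, 0, 0, 0, 0))
  # sigma = sigma0 * t, doubling with elapsed steps
  s1 <- pi_propagate(s, c(10, 0), c(sigma0 = 5))
  s2 <- pi_propagate(s1, c(10, 0), c(sigma0 = 5))
  g1 <- exp(-((grid$gx - 10)^2) / (2 * 5^2))
  g2 <- exp(-((grid$gx - 20)^2) / (2 * 10^2))
  expect_equal(s1$pos, g1 / sum(g1), tolerance = 1e-12)
  expect_equal(s2$pos, g2 / sum(g2), tolerance = 1e-12)
  expect_equal(sum(s2$pos), 1, tolerance = 1e-12)
})

test_that("goal belief updates as a convex mixture on goal attainment", {
  grid <- list(gx = c(0, 1, 2), gy = c(0, 0, 0))
  s <- pi_state(grid, c(0, 0))          # pos concentrated on first cell
  s1 <- pi_update_goal(s, c(eta = 1))
  expect_equal(s1$goal, s1$pos)          # full overwrite
  s2 <- pi_update_goal(s, c(eta = 0.5))
  expect_equal(s2$goal, c(0.5 / 3 + 0.5, 1 / 6, 1 / 6))
  expect_equal(sum(s2$goal), 1)
})

test_that("direction distribution reflects the goal bearing geometry", {
  grid <- list(gx = c(0, 10), gy = c(0, 0))
  s <- pi_state(grid, c(0, 0))
  s$goal <- c(0, 1)                      # goal known to lie due east
  p <- pi_direction_distribution(s, c(0, pi))
  expect_equal(p, c(1, 0))
  # uniform goal belief on a symmetric east/west grid: uniform directions
  g3 <- list(gx = c(-10, 0, 10), gy = c(0, 0, 0))
  su <- pi_state(g3, c(0, 0))
  pu <- pi_direction_distribution(su, c(0, pi))
  expect_equal(pu, c(0.5, 0.5))
})

test_that("unified action interface samples from the softmax over options", {
  s <- mf_state(3)
  set.seed(5)
  out <- agent_act("mf", s, "Y", c("L", "R", "U"), mf_fixture_params)
  expect_equal(unname(out$probs), rep(1 / 3, 3))  # equal preferences
  expect_equal(sum(out$probs), 1)
  set.seed(9)
  a1 <- agent_act("mf", s, "Y", c("L", "R", "U"), mf_fixture_params)$action
  set.seed(9)
  a2 <- agent_act("mf", s, "Y", c("L", "R", "U"), mf_fixture_params)$action
  expect_equal(a1, a2)                             # seeded reproducibility
})

test_that("compiled and reference engines agree step for step", {
  mz <- default_maze
  beh <- generate_behaviour(
    cohort_spec(1, "mf", protocol = short_protocol, seed = 7), mz)
  d <- beh$decisions[[1]]
  for (m in c("mf", "mf0", "mb", "pi")) {
    pp <- if (m == "pi") pi_fixture_params else mf_fixture_params
    llc <- sequence_log_likelihood(m, pp, d, mz, short_protocol, engine = "cpp")
    llr <- sequence_log_likelihood(m, pp, d, mz, short_protocol, engine = "r")
    expect_equal(as.numeric(llc), as.numeric(llr), tolerance = 1e-10)
    expect_equal(attr(llc, "n_decisions"), attr(llr, "n_decisions"))
  }
  for (m in c("mf", "mb", "pi")) {
    pp <- switch(m, mf = mf_fixture_params, mb = mb_fixture_params,
                 pi = pi_fixture_params)
    s1 <- simulate_agents(m, pp, mz, short_protocol, n_agents = 1,
                          seed = 11, return_actions = TRUE)
    s2 <- simulate_agents(m, pp, mz, short_protocol, n_agents = 1,
                          seed = 11, return_actions = TRUE, engine = "r")
    expect_identical(s1$actions[[1]], s2$actions[[1]])
    expect_equal(s1$success, s2$success)
  }
})
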