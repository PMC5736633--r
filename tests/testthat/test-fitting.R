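test_that("forced-choice likelihood reduces to counting under a uniform policy", {
  mz <- default_maze
  beh <- generate_behaviour(
    cohort_spec(1, "mf", protocol = short_protocol, seed = 3), mz)
  d <- beh$decisions[[1]]
  # beta = 0 makes every decision uniform over its available set
  ll <- sequence_log_likelihood("mf", list(eta = 0.3, beta = 0, gamma = 0.9),
                                d, mz, short_protocol)
  free <- d[!d$guided, ]
  expected <- -sum(log(lengths(strsplit(free$available, ","))))
  expect_equal(as.numeric(ll), expected, tolerance = 1e-10)
  expect_equal(attr(ll, "n_decisions"), nrow(free))

  # the likelihood is identical across models under beta = 0
  ll_mb <- sequence_log_likelihood("mb", list(eta = 0.3, beta = 0, gamma = 0.9),
                                   d, mz, short_protocol)
  expect_equal(as.numeric(ll_mb), expected, tolerance = 1e-10)
})

test_that("empty sequences and invalid decisions are handled explicitly", {
  mz <- default_maze
  empty <- data.frame(subject = character(0), day = integer(0),
                      session = integer(0), trial = integer(0),
                      step = integer(0), cell = integer(0),
                      observation = character(0), available = character(0),
                      action = character(0), reward = integer(0),
                      guided = logical(0))
  ll <- sequence_log_likelihood("mf", mf_fixture_params, empty, mz)
  expect_equal(as.numeric(ll), 0)

  beh <- generate_behaviour(
    cohort_spec(1, "mf", protocol = short_protocol, seed = 3), mz)
  d <- beh$decisions[[1]]
  i <- which(d$available == "F,U" & d$action == "F")[1]
  d$action[i] <- "L"
  expect_error(
    sequence_log_likelihood("mf", mf_fixture_params, d, mz, short_protocol),
    "not available at trial")
  expect_error(
    sequence_log_likelihood("mf", list(eta = 2, beta = 5, gamma = 0.9),
                            d, mz, short_protocol),
    "outside bounds")
})

test_that("the likelihood peaks near the generating parameters", {
  mz <- default_maze
  beh <- generate_behaviour(
    cohort_spec(1, "mf", param_ranges = point_ranges(mf_fixture_params),
                seed = 21), mz)
  d <- beh$decisions[[1]]
  ll_true <- sequence_log_likelihood("mf", mf_fixture_params, d, mz)
  for (eta in c(0.0, 0.6)) { # generating eta shifted by -/+ 0.3
    pp <- mf_fixture_params
    pp$eta <- eta
    expect_gt(as.numeric(ll_true),
              as.numeric(sequence_log_likelihood("mf", pp, d, mz)))
  }
})

test_that("fitting decisions from a uniform policy finds a flat beta axis", {
  mz <- default_maze
  beh <- generate_behaviour(
    cohort_spec(1, "mf",
                param_ranges = list(eta = c(0.3, 0.3), beta = c(0, 0),
                                    gamma = c(0.9, 0.9)),
                protocol = short_protocol, seed = 5), mz)
  d <- beh$decisions[[1]]
  fit <- fit_parameters("mf", d, mz, short_protocol,
                        control = list(pop_size = 12, generations = 20,
                                       n_restarts = 1), seed = 2)
  ll0 <- sequence_log_likelihood("mf", list(eta = fit$params["eta"], beta = 0,
                                            gamma = fit$params["gamma"]),
                                 d, mz, short_protocol)
  # nothing to exploit: the optimum is not meaningfully better than beta = 0
  expect_lt(fit$log_lik - as.numeric(ll0), 3)
  expect_equal(fit$n_decisions, sum(!d$guided))
  # the stored likelihood recomputes exactly from the stored parameters
  expect_equal(fit$log_lik,
               as.numeric(sequence_log_likelihood("mf", as.list(fit$params),
                                                  d, mz, short_protocol)),
               tolerance = 1e-10)
})

test_that("model selection restricts to sequence-capable models and flags ties", {
  mk <- function(model, ll, nd = 100)
    structure(list(model = model, params = c(eta = .3, beta = 5, gamma = .9),
                   log_lik = ll, n_decisions = nd), class = "fit_result")
  sel <- select_model_per_subject(list(mk("mf", -120), mk("mb", -100),
                                       mk("pi", -150), mk("mf0", -90)))
  expect_equal(sel$model, "mb")       # mf0 excluded despite best likelihood
  expect_equal(nrow(sel$table), 4)

  sel1 <- select_model_per_subject(list(mk("pi", -50)))
  expect_equal(sel1$model, "pi")

  tie <- select_model_per_subject(list(mk("mf", -100), mk("mb", -100)))
  expect_true(tie$tie)
  expect_equal(tie$model, "mf")       # deterministic tie-break order

  expect_error(select_model_per_subject(list(mk("mf", -10, 50),
                                             mk("mb", -9, 60))),
               "consistency error")
})
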