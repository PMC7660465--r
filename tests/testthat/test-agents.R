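test_that("delta-rule updates hit their stated values and fixed points", {
  expect_equal(update_pref_reinforced(1.0, 1.0, 0.05), 1.0)   # q = r fixed
  expect_equal(update_pref_reinforced(0.5, 1.0, 0.05), 0.525)
  expect_equal(update_pref_extinction(0.0, 0.01), 0.0)
  expect_equal(update_pref_extinction(0.5, 0.01), 0.495)
  expect_equal(update_cost(0.0, 1, 0.05), 0.0)                # ln 1 = 0
  expect_equal(update_cost(1.0, exp(1), 0.05), 1.0)           # q = ln x
  expect_equal(update_cost(0.0, 10, 0.05), 0.05 * log(10))
  expect_error(update_cost(0.0, 0, 0.05), ">= 1")
})

test_that("repeated reinforcement converges geometrically to r, extinction to 0", {
  q <- 0
  for (n in 1:50) {
    q <- update_pref_reinforced(q, 1.0, 0.05)
    expect_equal(q, 1 - 0.95^n, tolerance = 1e-12)
  }
  q <- 0.8
  prev <- q
  for (n in 1:200) {
    q <- update_pref_extinction(q, 0.01)
    expect_lt(q, prev)
    prev <- q
  }
  expect_equal(q, 0.8 * 0.99^200, tolerance = 1e-12)
  # cost fixed point at ln(x) under constant x
  q <- 0
  for (n in 1:2000) q <- update_cost(q, 7, 0.05)
  expect_equal(q, log(7), tolerance = 1e-8)
})

test_that("softmax choice probabilities normalize and match direct evaluation", {
  p <- choice_probabilities(c(operant = 0.7, others = 0.7), 12.5)
  expect_equal(unname(p), c(0.5, 0.5))
  p <- choice_probabilities(c(operant = 1.0, others = 0.5), 0)
  expect_equal(unname(p), c(0.5, 0.5))
  p <- choice_probabilities(c(operant = 1.0, others = 0.5), 12.5)
  expect_equal(unname(p["operant"]), 1 / (1 + exp(-6.25)), tolerance = 1e-12)
  # normalization under random values, including overflow-prone ones
  set.seed(1)
  for (i in 1:50) {
    q <- runif(3, 0, 400)
    p <- choice_probabilities(setNames(q, c("a", "b", "c")), runif(1, 0, 20))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("stay probability matches its closed form and is monotone", {
  expect_equal(stay_probability(0, 0, 1.0, 3.5), 0)
  expect_equal(stay_probability(0.5, 1.0, 1.0, 3.5), exp(-1 / 4.0))
  set.seed(2)
  for (i in 1:50) {
    qp <- runif(1, 0, 3); qc <- runif(1, 0, 3); eps <- runif(1, 0.01, 1)
    p0 <- stay_probability(qp, qc, 1.0, 3.5)
    expect_lt(p0, 1)
    expect_gt(stay_probability(qp + eps, qc, 1.0, 3.5), p0)
    expect_gt(stay_probability(qp, qc + eps, 1.0, 3.5), p0)
    # invariance under exchanging weighted contributions
    expect_equal(stay_probability(qp, qc, 1.0, 3.5),
                 stay_probability(qc, qp, 3.5, 1.0),
                 tolerance = 1e-12)
  }
})

test_that("two-state stay rule is a softmax over weighted scores", {
  expect_equal(two_state_stay_probability(
    c(operant = 1, others = 1), c(operant = 2, others = 2),
    4.0, 3.5, "operant"), 0.5)
  # scores (4, 0): sigmoid of the difference
  p <- two_state_stay_probability(c(operant = 1, others = 0),
                                  c(operant = 0, others = 0),
                                  4.0, 3.5, "operant")
  expect_equal(p, 1 / (1 + exp(-4)), tolerance = 1e-12)
  # stay and switch probabilities are complementary
  psw <- two_state_stay_probability(c(operant = 1, others = 0),
                                    c(operant = 0, others = 0),
                                    4.0, 3.5, "others")
  expect_equal(p + psw, 1, tolerance = 1e-12)
})

test_that("agent presets reproduce the published parameter sets exactly", {
  p <- agent_preset("dual")
  expect_identical(p$alpha_rft, 0.05)
  expect_identical(p$alpha_ext, 0.01)
  expect_identical(p$beta, 12.5)
  expect_identical(p$w_pref, 1.0)
  expect_identical(p$w_cost, 3.5)
  expect_identical(p$r_operant, 1.0)
  expect_identical(p$r_others, 0.5)
  expect_identical(p$response_prob, 1 / 3)
  expect_identical(p$dt, 0.1)
  expect_identical(agent_preset("no_choice"), p)
  expect_identical(agent_preset("no_cost"), p)
  ts <- agent_preset("two_state")
  expect_identical(ts$alpha_rft, 0.01)
  expect_identical(ts$alpha_ext, 0.01)
  expect_identical(ts$w_pref, 4.0)
  expect_identical(ts$w_cost, 3.5)
  expect_error(agent_params(alpha_rft = 0), "alpha_rft")
})
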