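test_that("identical seeds reproduce sessions exactly", {
  a <- run_session("dual", vi_schedule(30), max_reinforcers = 50, seed = 7)
  b <- run_session("dual", vi_schedule(30), max_reinforcers = 50, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$q_trace, b$q_trace)
  c <- run_session("dual", vi_schedule(30), max_reinforcers = 50, seed = 8)
  expect_false(identical(a$events, c$events))
})

test_that("session terminates at the reinforcer cap", {
  s <- run_session("dual", fr_schedule(1), max_reinforcers = 1, seed = 1)
  expect_equal(s$n_reinforcers_operant, 1)
  ev <- s$events
  expect_equal(max(ev$time), ev$time[ev$kind == "reinforcer_operant"])
  for (cap in c(5, 40)) {
    s <- run_session("dual", vi_schedule(10), max_reinforcers = cap,
                     seed = 3)
    expect_equal(s$n_reinforcers_operant, cap)
  }
})

test_that("event log is well-formed", {
  s <- run_session("dual", vi_schedule(30), max_reinforcers = 100,
                   seed = 21)
  ev <- s$events
  expect_false(is.unsorted(ev$time))
  steps <- round(ev$time / 0.1)
  expect_equal(ev$time, steps * 0.1, tolerance = 1e-9)
  # every operant reinforcer coincides with an operant response
  rft <- ev$time[ev$kind == "reinforcer_operant"]
  resp <- ev$time[ev$kind == "operant_response"]
  expect_true(all(rft %in% resp))
})

test_that("the no-cost agent returns to Choice after every response", {
  s <- baseline_no_cost()
  ev <- s$events
  k <- as.integer(ev$kind)
  resp <- which(k %in% c(1L, 2L))
  # between two successive responses there is always a Choice entry
  for (i in head(seq_along(resp), 2000)) {
    j <- resp[i]
    nxt <- k[(j + 1):min(j + 4, length(k))]
    expect_true(5L %in% nxt)
  }
})

test_that("transition probabilities follow the frequency definition", {
  tp <- estimate_transition_probabilities(toy_cycle_log(),
                                          after_reinforcers = 0)
  expect_equal(unname(tp$choice["operant"]), 0.5)
  expect_equal(unname(tp$operant["leave"]), 1.0)
  expect_equal(unname(tp$others["leave"]), 1.0)
  expect_equal(sum(tp$choice), 1)
  expect_equal(sum(tp$operant), 1)
  expect_equal(sum(tp$others), 1)
})

test_that("transition estimation demands enough reinforcers", {
  s <- run_session("dual", vi_schedule(30), max_reinforcers = 5, seed = 2)
  expect_error(estimate_transition_probabilities(s, 500), "reinforcers")
})

test_that("knockout agents alter the transition structure as designed", {
  tp <- estimate_transition_probabilities(baseline_no_choice(), 500)
  expect_equal(unname(tp$choice["operant"]), 1.0)   # operant only
  expect_equal(tp$counts[["others_responses"]], 0)
  tp <- estimate_transition_probabilities(baseline_no_cost(), 500)
  expect_equal(unname(tp$operant["leave"]), 1.0)    # stay forced to 0
  expect_equal(unname(tp$others["leave"]), 1.0)
})

test_that("generic timestamped records round-trip through session_log", {
  lg <- session_log(c(1.0, 1.3, 5.0), rep("operant_response", 3))
  ir <- extract_irts(lg, after_reinforcers = 0)
  expect_equal(ir$tau, c(0.3, 3.7))
  expect_error(session_log(c(2, 1), c("operant_response",
                                      "operant_response")),
               "non-decreasing")
  expect_error(session_log(1, "nonsense"), "kind")
})

test_that("session logs round-trip through the CSV/JSON writer", {
  s <- run_session("dual", with_extinction(vi_schedule(10), 60),
                   max_reinforcers = 20, seed = 5)
  dir <- tempfile()
  write_session_log(s, dir)
  s2 <- read_session_log(dir)
  expect_equal(s2$events, s$events)
  expect_equal(s2$agent, s$agent)
  expect_equal(s2$extinction_start, s$extinction_start)
  expect_equal(unclass(s2$params), unclass(s$params),
               tolerance = 1e-12)
  expect_equal(s2$q_trace, s$q_trace, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("q traces are recorded at each operant reinforcer", {
  s <- run_session("dual", vi_schedule(10), max_reinforcers = 30, seed = 9)
  expect_equal(nrow(s$q_trace), 30)
  rft <- s$events$time[s$events$kind == "reinforcer_operant"]
  expect_equal(s$q_trace$time, rft)
  expect_true(all(s$q_trace$q_pref_operant >= 0))
  expect_true(all(s$q_trace$q_cost_operant >= 0))
})
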