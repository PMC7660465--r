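test_that("Fleshler-Hoffman progression matches independent evaluation", {
  # frozen from a separate direct evaluation of the closed-form progression
  expected <- c(1.286246, 4.017287, 7.022307, 10.362534, 14.122361,
                18.422773, 23.446182, 29.486836, 37.066982, 47.260924,
                62.958369, 104.547199)
  expect_equal(fleshler_hoffman_intervals(30, 12), expected,
               tolerance = 1e-6)
})

test_that("Fleshler-Hoffman tables are mean-preserving, increasing, positive", {
  expect_equal(fleshler_hoffman_intervals(120, 1), 120)
  for (n in c(2, 5, 20, 77)) {
    iv <- fleshler_hoffman_intervals(120, n)
    expect_length(iv, n)
    expect_true(all(iv > 0))
    expect_true(all(diff(iv) > 0))
    expect_equal(mean(iv), 120, tolerance = 1e-9)
  }
  expect_equal(mean(fleshler_hoffman_intervals(30, 12)), 30,
               tolerance = 1e-9)
  expect_error(fleshler_hoffman_intervals(-1, 5), "positive")
  expect_error(fleshler_hoffman_intervals(120, 0), "whole number")
})

test_that("VI clock arms after the interval and delivers on the next response", {
  cfg <- vi_schedule(2, n_intervals = 1)
  st <- schedule_state(cfg)
  out <- schedule_step(st, cfg, dt = 1, operant_response = TRUE)
  expect_false(out$delivered)            # interval not yet elapsed
  out <- schedule_step(out$state, cfg, dt = 1.5, operant_response = FALSE)
  expect_false(out$delivered)
  expect_true(out$state$reinforcer_armed)
  out <- schedule_step(out$state, cfg, dt = 1, operant_response = TRUE)
  expect_true(out$delivered)             # armed reinforcer collected
  expect_equal(out$state$elapsed_in_interval, 0)
  expect_false(out$state$reinforcer_armed)
})

test_that("tandem VT VR 0 is trace-equivalent to VI on any response stream", {
  tbl <- fleshler_hoffman_intervals(5, 4)
  vi <- vi_schedule(5, 4)
  tan <- tandem_vt_vr_schedule(5, ratio = 0, n_intervals = 4)
  st1 <- schedule_state(vi, tbl)
  st2 <- schedule_state(tan, tbl)
  set.seed(42)
  responses <- runif(400) < 0.3
  for (resp in responses) {
    o1 <- schedule_step(st1, vi, 0.1, resp)
    o2 <- schedule_step(st2, tan, 0.1, resp)
    expect_identical(o1$delivered, o2$delivered)
    st1 <- o1$state; st2 <- o2$state
  }
})

test_that("tandem VR requirement delays delivery by the stated count", {
  cfg <- tandem_vt_vr_schedule(1, ratio = 3, n_intervals = 1)
  st <- schedule_state(cfg)
  out <- schedule_step(st, cfg, dt = 1.5, operant_response = FALSE)
  expect_true(out$state$reinforcer_armed)
  delivered <- logical(5)
  for (i in 1:5) {
    out <- schedule_step(out$state, cfg, dt = 0.1, operant_response = TRUE)
    delivered[i] <- out$delivered
  }
  expect_identical(delivered, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("FR delivers exactly one reinforcer per ratio responses", {
  cfg <- fr_schedule(1)
  st <- schedule_state(cfg)
  for (i in 1:5) {
    out <- schedule_step(st, cfg, 0.1, operant_response = TRUE)
    expect_true(out$delivered)
    st <- out$state
  }
  cfg3 <- fr_schedule(3)
  st <- schedule_state(cfg3)
  got <- logical(6)
  for (i in 1:6) {
    out <- schedule_step(st, cfg3, 0.1, TRUE)
    got[i] <- out$delivered
    st <- out$state
  }
  expect_identical(got, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("long-run VI reinforcer rate approaches 1/T under saturating responding", {
  # the no-choice agent responds nearly continuously, so delivery waits
  # little beyond each interval
  s <- run_session("no_choice", vi_schedule(10), max_reinforcers = 500,
                   seed = 11)
  span <- max(s$events$time)
  rate <- s$n_reinforcers_operant / span
  expect_equal(rate, 1 / 10, tolerance = 0.15)
})
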