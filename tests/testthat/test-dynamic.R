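test_that("dynamic likelihood reduces exactly to the static one at zero decay", {
  set.seed(20)
  ir <- irt_set(sort(runif(500, 0, 3600)), rexp(500, 0.5))
  omega <- 3.2
  for (q0 in c(0.1, 0.5)) for (b0 in c(0.05, 0.3)) {
    dyn <- dynamic_biexp_loglik(list(q0 = q0, b0 = b0, gamma = 0,
                                     delta = 0), ir, omega)
    stat <- boutsim:::.biexp_loglik(ir$tau, q0, omega, b0)
    expect_equal(dyn, stat, tolerance = 1e-10)
  }
})

test_that("dynamic likelihood matches hand evaluation and rejects bad points", {
  ir1 <- irt_set(0, 1)
  expect_equal(
    dynamic_biexp_loglik(list(q0 = 0.5, b0 = 0.5, gamma = 0, delta = 0),
                         ir1, omega = 2),
    log(0.5 * 2 * exp(-2) + 0.5 * 0.5 * exp(-0.5)))
  bad <- list(q0 = 1.5, b0 = 0.5, gamma = 0, delta = 0)
  expect_identical(dynamic_biexp_loglik(bad, ir1, 2), -Inf)
  expect_identical(dynamic_biexp_loglik(list(q0 = 0.5, b0 = -1,
                                             gamma = 0, delta = 0),
                                        ir1, 2), -Inf)
  # invariant under reordering observations
  set.seed(21)
  ir <- irt_set(sort(runif(50, 0, 100)), rexp(50, 1))
  perm <- sample(50)
  irp <- structure(data.frame(onset = ir$onset[perm], tau = ir$tau[perm]),
                   class = c("irt_set", "data.frame"))
  th <- list(q0 = 0.3, b0 = 0.1, gamma = 0.001, delta = 0.001)
  expect_equal(dynamic_biexp_loglik(th, ir, 3),
               dynamic_biexp_loglik(th, irp, 3), tolerance = 1e-10)
})

test_that("variants pin the excluded decay rate at zero", {
  ir <- irt_set(c(0, 100), c(1, 2))
  th <- list(q0 = 0.4, b0 = 0.2, gamma = 0.002, delta = 0.002)
  q_only <- dynamic_biexp_loglik(th, ir, 3, variant = "q_decay")
  expect_equal(q_only, dynamic_biexp_loglik(modifyList(th, list(delta = 0)),
                                            ir, 3))
  b_only <- dynamic_biexp_loglik(th, ir, 3, variant = "b_decay")
  expect_equal(b_only, dynamic_biexp_loglik(modifyList(th, list(gamma = 0)),
                                            ir, 3))
})

test_that("MCMC recovers dynamic decay parameters from simulated data", {
  # simulation-based check at one qb-decay truth point
  set.seed(22)
  n <- 2000
  omega <- 3.3
  q0 <- 0.3; b0 <- 0.1; gam <- 0.002; del <- 0.001
  t <- sort(runif(n, 0, 3600))
  qt <- 1 - (1 - q0) * exp(-gam * t)
  bt <- b0 * exp(-del * t)
  slow <- runif(n) < qt
  tau <- ifelse(slow, rexp(n, bt), rexp(n, omega))
  ir <- irt_set(t, tau)
  fit <- fit_dynamic_biexponential(ir, "qb_decay", omega = omega,
                                   chains = 2, warmup = 800, iter = 800,
                                   seed = 23)
  expect_true(fit$converged)
  sm <- fit$samples
  for (p in c("q0", "b0", "gamma", "delta")) {
    ci <- quantile(sm[[p]], c(0.025, 0.975))
    truth <- c(q0 = q0, b0 = b0, gamma = gam, delta = del)[p]
    expect_true(ci[1] <= truth && truth <= ci[2],
                label = sprintf("%s 95%% interval covers truth", p))
  }
  # the q_decay variant never samples delta
  fq <- fit_dynamic_biexponential(ir, "q_decay", omega = omega,
                                  chains = 2, warmup = 400, iter = 500,
                                  seed = 24)
  expect_false("delta" %in% names(fq$samples))
})

test_that("WAIC equals mean negative log-likelihood for a point-mass posterior", {
  set.seed(25)
  ir <- irt_set(sort(runif(200, 0, 1000)), rexp(200, 0.8))
  th <- data.frame(q0 = rep(0.4, 600), b0 = 0.2, gamma = 0.001,
                   delta = 0.002)
  expect_warning(w <- compute_waic(th, ir, omega = 3, variant = "qb_decay"),
                 "degenerate")
  ll <- dynamic_biexp_loglik(as.list(th[1, ]), ir, 3)
  expect_equal(as.numeric(w), -ll / nrow(ir), tolerance = 1e-10)
  expect_true(attr(w, "degenerate"))
})

test_that("per-observation WAIC is stable under duplicating the sample", {
  set.seed(26)
  ir <- irt_set(sort(runif(300, 0, 1000)), rexp(300, 0.8))
  draws <- data.frame(q0 = runif(600, 0.2, 0.4),
                      b0 = runif(600, 0.1, 0.3),
                      gamma = 0, delta = 0)
  w1 <- compute_waic(draws, ir, omega = 3)
  ir2 <- structure(data.frame(onset = rep(ir$onset, 2)[order(rep(ir$onset, 2))],
                              tau = rep(ir$tau, 2)[order(rep(ir$onset, 2))]),
                   class = c("irt_set", "data.frame"))
  w2 <- compute_waic(draws, ir2, omega = 3)
  expect_equal(as.numeric(w1), as.numeric(w2), tolerance = 1e-8)
})
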