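# Session fixtures are expensive (full 1000-reinforcer sessions), so they
# are simulated once per test run and cached across test files. Fixture
# seeds are fixed: 101.. for the model-comparison sessions, 106 for the
# extinction session, 301.. for the schedule sweep.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

baseline_dual <- function()
  fixture("dual", run_session("dual", vi_schedule(120), 1000, seed = 101))

baseline_no_choice <- function()
  fixture("no_choice",
          run_session("no_choice", vi_schedule(120), 1000, seed = 102))

baseline_no_cost <- function()
  fixture("no_cost",
          run_session("no_cost", vi_schedule(120), 1000, seed = 103))

extinction_session <- function()
  fixture("extinction",
          run_session("dual", with_extinction(vi_schedule(120), 3600), 1000,
                      seed = 106))

# a hand-built log: Choice -> Operant -> (respond, leave) -> Choice ->
# Others -> (respond, leave) cycle, for frequency-definition checks
toy_cycle_log <- function() {
  session_log(
    time = c(0.1, 0.2, 0.2, 0.3, 0.4, 0.4, 0.4),
    kind = c("enter_operant", "operant_response", "enter_choice",
             "enter_others", "others_response", "reinforcer_others",
             "enter_choice"),
    agent = "dual")
}

# IRTs simulated from the bi-exponential mixture itself
rbiexp <- function(n, q, omega, b) {
  slow <- runif(n) < q
  ifelse(slow, rexp(n, b), rexp(n, omega))
}
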