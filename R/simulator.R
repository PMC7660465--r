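.EVENT_KINDS <- c("operant_response", "others_response",
                  "reinforcer_operant", "reinforcer_others",
                  "enter_choice", "enter_operant", "enter_others")

#' Event kinds recorded in a session log
#'
#' @return Character vector of the seven event kinds, in the order of their
#'   integer codes.
#' @export
event_kinds <- function() .EVENT_KINDS

.agent_code <- function(agent) {
  switch(agent, dual = 1L, no_choice = 2L, no_cost = 3L, two_state = 4L,
         stop("unknown agent kind: ", agent))
}

#' Construct a session log from timestamped records
#'
#' Builds the event-log container used by every analysis function, either
#' from a simulation (see [run_session()]) or from generic timestamped
#' response records (e.g. real event data). Only the event kinds present
#' need to be meaningful for the analyses applied: IRT extraction uses
#' \code{operant_response} and \code{reinforcer_operant} events; transition
#' estimation additionally uses the \code{enter_*} events.
#'
#' @param time Non-decreasing numeric vector of event times, seconds.
#' @param kind Character vector (one of [event_kinds()]) or integer codes.
#' @param params Optional \code{agent_params} metadata.
#' @param schedule Optional \code{schedule_config} metadata.
#' @param agent Optional agent kind string.
#' @param seed Optional seed metadata.
#' @param extinction_start Time at which the extinction phase began, or
#'   \code{NA} if none.
#' @param q_trace Optional data frame of value snapshots.
#' @return An object of class \code{session_log}: a list with an
#'   \code{events} data frame (columns \code{time}, \code{kind} [factor])
#'   and metadata fields.
#' @export
session_log <- function(time, kind, params = NULL, schedule = NULL,
                        agent = NA_character_, seed = NA_integer_,
                        extinction_start = NA_real_, q_trace = NULL) {
  if (is.character(kind) || is.factor(kind))
    kind <- match(as.character(kind), .EVENT_KINDS)
  kind <- as.integer(kind)
  if (anyNA(kind) || any(kind < 1L | kind > 7L))
    stop("`kind` must be one of event_kinds() or integer codes 1..7")
  if (is.unsorted(time)) stop("event times must be non-decreasing")
  events <- data.frame(time = as.numeric(time),
                       kind = factor(.EVENT_KINDS[kind],
                                     levels = .EVENT_KINDS))
  structure(list(events = events, agent = agent, params = params,
                 schedule = schedule, seed = seed,
                 n_reinforcers_operant =
                   sum(kind == 3L),
                 extinction_start = extinction_start,
                 q_trace = q_trace),
            class = "session_log")
}

#' Simulate one operant session
#'
#' Runs the time-stepped session loop for the requested agent variant on the
#' given schedule until \code{max_reinforcers} operant reinforcers have been
#' delivered (followed, if the schedule carries an extinction phase, by the
#' extinction epilogue during which operant responses are never reinforced).
#'
#' Each 0.1 s step proceeds in order: a Choice state resolves by the softmax
#' choice rule (resetting the bout response counter); an engaged agent emits
#' a response with probability \code{response_prob}; after an operant
#' response the stay/leave decision is drawn, then the schedule is
#' consulted — a delivered reinforcer updates the operant preference toward
#' \code{r_operant} and the operant cost toward \eqn{\ln x}, while an
#' unreinforced departure decays the preference; other behaviors are
#' reinforced FR 1 on every response, updating the Others values likewise.
#' The competing-behavior schedule is always FR 1. Identical inputs and seed
#' reproduce the event log exactly.
#'
#' Agent variants: \code{"dual"} has both the choice and the changeover-cost
#' mechanisms; \code{"no_choice"} deterministically selects the operant
#' behavior in the Choice state; \code{"no_cost"} returns to the Choice
#' state after every response (stay probability identically 0);
#' \code{"two_state"} drops the Choice state and switches directly between
#' Operant and Others via a softmax over weighted preference-plus-cost
#' scores.
#'
#' @param agent Agent variant; see Details.
#' @param schedule A \code{schedule_config} for the operant behavior.
#' @param max_reinforcers Operant reinforcer cap ending the acquisition
#'   phase.
#' @param seed Integer seed; sessions with the same arguments and seed are
#'   identical. \code{NULL} leaves the RNG state alone.
#' @param params \code{agent_params}; defaults to [agent_preset()] for the
#'   chosen variant.
#' @param record_qtrace Record the four values at every operant reinforcer
#'   delivery (used for value boxplots and manipulation summaries).
#' @return A \code{session_log}; see [session_log()].
#' @examples
#' s <- run_session("dual", vi_schedule(120), max_reinforcers = 20, seed = 1)
#' s
#' @export
run_session <- function(agent = c("dual", "no_choice", "no_cost",
                                  "two_state"),
                        schedule = vi_schedule(120),
                        max_reinforcers = 1000, seed = NULL,
                        params = NULL, record_qtrace = TRUE) {
  agent <- match.arg(agent)
  stopifnot(inherits(schedule, "schedule_config"), max_reinforcers >= 1)
  if (is.null(params)) params <- agent_preset(agent)
  stopifnot(inherits(params, "agent_params"))
  if (!is.null(seed)) set.seed(seed)

  table <- numeric(0)
  if (schedule$kind != "FR") {
    table <- sample(fleshler_hoffman_intervals(schedule$mean_interval,
                                               schedule$n_intervals))
  }
  ext <- schedule$extinction_duration
  raw <- run_session_cpp(.agent_code(agent), unclass(params),
                         .schedule_code(schedule), table,
                         schedule$ratio_requirement,
                         as.integer(max_reinforcers),
                         if (is.na(ext)) -1 else ext,
                         record_qtrace)

  q_trace <- NULL
  if (record_qtrace)
    q_trace <- data.frame(time = raw$qtrace_time,
                          q_pref_operant = raw$qtrace_qp_op,
                          q_pref_others = raw$qtrace_qp_oth,
                          q_cost_operant = raw$qtrace_qc_op,
                          q_cost_others = raw$qtrace_qc_oth)

  out <- session_log(raw$time, raw$kind, params = params,
                     schedule = schedule, agent = agent,
                     seed = if (is.null(seed)) NA_integer_ else seed,
                     extinction_start = raw$extinction_start,
                     q_trace = q_trace)
  out$q_final <- raw$q_final
  out$max_reinforcers <- max_reinforcers
  out
}

#' @export
print.session_log <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<session_log> agent=%s, %d events, %d operant reinforcers\n",
              x$agent, nrow(ev), x$n_reinforcers_operant))
  if (nrow(ev))
    cat(sprintf("  span: %.1f s; responses: %d operant, %d others\n",
                max(ev$time), sum(ev$kind == "operant_response"),
                sum(ev$kind == "others_response")))
  if (!is.na(x$extinction_start))
    cat(sprintf("  extinction phase from t = %.1f s\n", x$extinction_start))
  invisible(x)
}

# time of the n-th operant reinforcer, or stop()
.reinforcer_cutoff_time <- function(session, after_reinforcers) {
  ev <- session$events
  rft <- ev$time[ev$kind == "reinforcer_operant"]
  if (after_reinforcers == 0) return(-Inf)
  if (length(rft) < after_reinforcers)
    stop("log contains only ", length(rft), " operant reinforcers; ",
         after_reinforcers, " requested")
  rft[after_reinforcers]
}

#' Empirical state-transition probabilities
#'
#' Estimates, from the event log, the empirical frequency of each transition
#' decision after stabilization: the Choice-state resolution
#' (Choice to Operant vs Choice to Others) and the per-response stay/leave
#' decisions in the Operant and Others states. Only events strictly after
#' the \code{after_reinforcers}-th operant reinforcer contribute. Each
#' outgoing distribution sums to 1.
#'
#' @param session A \code{session_log}.
#' @param after_reinforcers Number of operant reinforcers defining the
#'   stabilization cutoff (0 uses the whole log).
#' @return A list of class \code{transition_probs} with components
#'   \code{choice} (named probabilities \code{operant}, \code{others}),
#'   \code{operant} and \code{others} (named probabilities \code{stay},
#'   \code{leave}), and \code{counts} (decision counts behind each row).
#'   For a two-state session the \code{choice} component is \code{NULL} and
#'   "leave" means switching directly to the other engaged state.
#' @examples
#' s <- run_session("dual", vi_schedule(30), max_reinforcers = 60, seed = 1)
#' estimate_transition_probabilities(s, after_reinforcers = 30)
#' @export
estimate_transition_probabilities <- function(session,
                                              after_reinforcers = 500) {
  stopifnot(inherits(session, "session_log"))
  cutoff <- .reinforcer_cutoff_time(session, after_reinforcers)
  ev <- session$events[session$events$time > cutoff, , drop = FALSE]
  if (nrow(ev) < 2) stop("no events after the stabilization cutoff")
  kk <- as.integer(ev$kind)  # codes 1..7 in .EVENT_KINDS order
  tt <- ev$time
  n <- length(kk)
  k1 <- c(kk[-1], NA_integer_); t1 <- c(tt[-1], NA_real_)
  k2 <- c(kk[-(1:2)], NA_integer_, NA_integer_)
  t2 <- c(tt[-(1:2)], NA_real_, NA_real_)

  # a leave decision shows up as an enter_* event at the response's own
  # timestamp, possibly with the reinforcer event in between
  entry <- c(5L, 6L, 7L)
  leave_after <- function(idx) {
    (!is.na(k1[idx]) & t1[idx] == tt[idx] & k1[idx] %in% entry) |
      (!is.na(k2[idx]) & k1[idx] %in% c(3L, 4L) & t1[idx] == tt[idx] &
         t2[idx] == tt[idx] & k2[idx] %in% entry)
  }

  op <- which(kk == 1L)
  oth <- which(kk == 2L)
  op_leave <- sum(leave_after(op))
  oth_leave <- sum(leave_after(oth))

  two_state <- identical(session$agent, "two_state")
  choice <- NULL
  n_co <- sum(kk == 6L); n_ct <- sum(kk == 7L)
  if (!two_state && (n_co + n_ct) > 0)
    choice <- c(operant = n_co / (n_co + n_ct),
                others = n_ct / (n_co + n_ct))

  mk <- function(n_tot, n_leave) {
    if (n_tot == 0) return(c(stay = NA_real_, leave = NA_real_))
    c(stay = (n_tot - n_leave) / n_tot, leave = n_leave / n_tot)
  }
  structure(list(
    choice = choice,
    operant = mk(length(op), op_leave),
    others = mk(length(oth), oth_leave),
    counts = c(choice = n_co + n_ct, operant_responses = length(op),
               others_responses = length(oth)),
    after_reinforcers = after_reinforcers),
    class = "transition_probs")
}

#' @export
print.transition_probs <- function(x, ...) {
  cat("<transition_probs> (after", x$after_reinforcers,
      "operant reinforcers)\n")
  if (!is.null(x$choice))
    cat(sprintf("  Choice  -> Operant %.3f | Others %.3f  (n=%d)\n",
                x$choice["operant"], x$choice["others"],
                x$counts["choice"]))
  cat(sprintf("  Operant -> stay %.3f | leave %.3f  (n=%d)\n",
              x$operant["stay"], x$operant["leave"],
              x$counts["operant_responses"]))
  cat(sprintf("  Others  -> stay %.3f | leave %.3f  (n=%d)\n",
              x$others["stay"], x$others["leave"],
              x$counts["others_responses"]))
  invisible(x)
}
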