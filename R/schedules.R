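#' Fleshler-Hoffman variable-interval progression
#'
#' Generates the classic constant-probability interval series used to build
#' variable-interval (VI) and variable-time (VT) schedule tables. The k-th
#' of N intervals with mean T seconds is
#' \deqn{t_k = T\,[1 + \ln N + (N-k)\ln(N-k) - (N-k+1)\ln(N-k+1)],}
#' with the convention \eqn{0 \ln 0 = 0}. The progression is strictly
#' increasing in k and its arithmetic mean is exactly \code{mean_interval}.
#'
#' @param mean_interval Mean interval in seconds (> 0).
#' @param n_intervals Number of intervals N (>= 1).
#' @return Numeric vector of \code{n_intervals} interval lengths in seconds,
#'   in increasing order (shuffle before use in a session).
#' @examples
#' fleshler_hoffman_intervals(120, 20)
#' mean(fleshler_hoffman_intervals(30, 12))  # exactly 30
#' @export
fleshler_hoffman_intervals <- function(mean_interval, n_intervals) {
  if (!is.numeric(mean_interval) || length(mean_interval) != 1L ||
      !is.finite(mean_interval) || mean_interval <= 0)
    stop("`mean_interval` must be a single positive number")
  if (!is.numeric(n_intervals) || length(n_intervals) != 1L ||
      n_intervals < 1 || n_intervals != round(n_intervals))
    stop("`n_intervals` must be a positive whole number")
  n <- as.integer(n_intervals)
  k <- seq_len(n)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  mean_interval * (1 + log(n) + xlogx(n - k) - xlogx(n - k + 1))
}

#' Schedule configurations
#'
#' Constructors for the reinforcement schedules driving the operant
#' behavior: VI (interval clock, first response after the interval is
#' reinforced), FR (every \code{ratio}-th response is reinforced; FR 1 is
#' used for the competing other behaviors), and tandem VT VR (a variable-time
#' clock arms the reinforcer, after which \code{ratio} further responses must
#' occur before the next response is reinforced; VR 0 is identical to VI).
#' \code{with_extinction()} appends an extinction phase: once the session's
#' reinforcer cap is reached, the simulation continues for \code{duration}
#' seconds during which operant responses are never reinforced (the FR 1
#' schedule for other behaviors continues unchanged).
#'
#' @param mean_interval Mean of the interval (VI) or time (VT) component,
#'   seconds.
#' @param ratio Ratio requirement: responses per reinforcer (FR) or the
#'   tandem VR requirement.
#' @param n_intervals Size of the Fleshler-Hoffman table backing the
#'   interval component.
#' @param schedule A schedule configuration to extend.
#' @param duration Extinction-phase duration in seconds.
#' @return An object of class \code{schedule_config}.
#' @examples
#' vi_schedule(120)
#' with_extinction(vi_schedule(120), 3600)
#' tandem_vt_vr_schedule(120, ratio = 4)
#' @export
vi_schedule <- function(mean_interval, n_intervals = 20) {
  stopifnot(mean_interval > 0)
  structure(list(kind = "VI", mean_interval = mean_interval,
                 ratio_requirement = 0L,
                 n_intervals = as.integer(n_intervals),
                 extinction_duration = NA_real_),
            class = "schedule_config")
}

#' @rdname vi_schedule
#' @export
fr_schedule <- function(ratio = 1) {
  stopifnot(ratio >= 1, ratio == round(ratio))
  structure(list(kind = "FR", mean_interval = NA_real_,
                 ratio_requirement = as.integer(ratio),
                 n_intervals = 0L,
                 extinction_duration = NA_real_),
            class = "schedule_config")
}

#' @rdname vi_schedule
#' @export
tandem_vt_vr_schedule <- function(mean_interval, ratio, n_intervals = 20) {
  stopifnot(mean_interval > 0, ratio >= 0, ratio == round(ratio))
  structure(list(kind = "TANDEM_VT_VR", mean_interval = mean_interval,
                 ratio_requirement = as.integer(ratio),
                 n_intervals = as.integer(n_intervals),
                 extinction_duration = NA_real_),
            class = "schedule_config")
}

#' @rdname vi_schedule
#' @export
with_extinction <- function(schedule, duration = 3600) {
  stopifnot(inherits(schedule, "schedule_config"), duration > 0)
  schedule$extinction_duration <- duration
  schedule
}

#' @export
print.schedule_config <- function(x, ...) {
  desc <- switch(x$kind,
    VI = sprintf("VI %g s (Fleshler-Hoffman table of %d)", x$mean_interval,
                 x$n_intervals),
    FR = sprintf("FR %d", x$ratio_requirement),
    TANDEM_VT_VR = sprintf("tandem VT %g s VR %d", x$mean_interval,
                           x$ratio_requirement))
  cat("<schedule>", desc, "\n")
  if (!is.na(x$extinction_duration))
    cat("  extinction phase after reinforcer cap:", x$extinction_duration,
        "s\n")
  invisible(x)
}

.schedule_code <- function(config) {
  switch(config$kind, VI = 1L, FR = 2L, TANDEM_VT_VR = 3L,
         stop("unknown schedule kind: ", config$kind))
}

#' Initialize and advance schedule bookkeeping
#'
#' Reference implementation of the per-step schedule mechanics used by the
#' simulation engine, exposed for inspection and testing. \code{schedule_state()}
#' builds the runtime bookkeeping for a configuration (the interval table
#' should already be shuffled for a session); \code{schedule_step()} advances
#' it by one time step and reports whether a reinforcer is delivered for an
#' operant response emitted in that step.
#'
#' VI/VT time accrues every step in session time; when the current interval
#' has elapsed the reinforcer is armed and held until collected. Under VI the
#' first operant response after arming collects it; under tandem VT VR,
#' \code{ratio_requirement} responses must occur after arming before the next
#' response collects it (so VR 0 behaves exactly like VI). After a delivery
#' the table cursor advances cyclically and the clock restarts. FR delivers
#' on every \code{ratio_requirement}-th response.
#'
#' @param config A \code{schedule_config}.
#' @param interval_table Optional explicit interval table (seconds); defaults
#'   to the unshuffled Fleshler-Hoffman table of the configuration.
#' @param state A state list produced by \code{schedule_state()} or a prior
#'   \code{schedule_step()} call.
#' @param dt Step length in seconds (> 0).
#' @param operant_response Whether an operant response is emitted this step.
#' @return \code{schedule_state()}: a list with fields \code{interval_table},
#'   \code{table_cursor}, \code{elapsed_in_interval}, \code{reinforcer_armed},
#'   \code{vr_remaining}, \code{fr_count}. \code{schedule_step()}: a list with
#'   \code{state} (the advanced bookkeeping) and \code{delivered} (logical).
#' @examples
#' st <- schedule_state(vi_schedule(2, n_intervals = 1))
#' out <- schedule_step(st, vi_schedule(2, 1), dt = 2.5, operant_response = TRUE)
#' out$delivered
#' @export
schedule_state <- function(config, interval_table = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  if (is.null(interval_table) && config$kind != "FR")
    interval_table <- fleshler_hoffman_intervals(config$mean_interval,
                                                 config$n_intervals)
  list(interval_table = interval_table, table_cursor = 1L,
       elapsed_in_interval = 0, reinforcer_armed = FALSE,
       vr_remaining = 0L, fr_count = 0L)
}

#' @rdname schedule_state
#' @export
schedule_step <- function(state, config, dt, operant_response) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  delivered <- FALSE
  if (config$kind == "FR") {
    if (operant_response) {
      state$fr_count <- state$fr_count + 1L
      if (state$fr_count >= config$ratio_requirement) {
        delivered <- TRUE
        state$fr_count <- 0L
      }
    }
    return(list(state = state, delivered = delivered))
  }
  if (!state$reinforcer_armed) {
    state$elapsed_in_interval <- state$elapsed_in_interval + dt
    if (state$elapsed_in_interval >=
        state$interval_table[state$table_cursor] - 1e-9) {
      state$reinforcer_armed <- TRUE
      state$vr_remaining <- if (config$kind == "TANDEM_VT_VR")
        config$ratio_requirement else 0L
    }
  }
  if (operant_response && state$reinforcer_armed) {
    if (state$vr_remaining == 0L) {
      delivered <- TRUE
      state$reinforcer_armed <- FALSE
      state$elapsed_in_interval <- 0
      state$table_cursor <- state$table_cursor %% length(state$interval_table) + 1L
    } else {
      state$vr_remaining <- state$vr_remaining - 1L
    }
  }
  list(state = state, delivered = delivered)
}
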