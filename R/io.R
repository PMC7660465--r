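#' Read and write session logs
#'
#' A session log round-trips as a tidy two-column CSV of events
#' (\code{time_s}, \code{event_kind}) with a JSON sidecar holding the
#' metadata (agent, parameters, schedule, seed, counts, extinction onset).
#'
#' @param session A \code{session_log}.
#' @param dir Directory to hold \code{events.csv} and \code{meta.json}.
#' @return \code{write_session_log()} returns the directory invisibly;
#'   \code{read_session_log()} returns the reconstructed
#'   \code{session_log}.
#' @export
write_session_log <- function(session, dir) {
  stopifnot(inherits(session, "session_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- data.frame(time_s = session$events$time,
                   event_kind = as.character(session$events$kind))
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  meta <- list(agent = session$agent,
               params = unclass(session$params),
               schedule = unclass(session$schedule),
               seed = session$seed,
               n_reinforcers_operant = session$n_reinforcers_operant,
               extinction_start = session$extinction_start)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  if (!is.null(session$q_trace))
    write.csv(session$q_trace, file.path(dir, "q_trace.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(dir) {
  ev <- read.csv(file.path(dir, "events.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  params <- NULL
  if (!is.null(meta$params))
    params <- do.call(agent_params, meta$params)
  schedule <- NULL
  if (!is.null(meta$schedule) && !is.null(meta$schedule$kind)) {
    m <- meta$schedule
    schedule <- switch(m$kind,
      VI = vi_schedule(m$mean_interval, m$n_intervals),
      FR = fr_schedule(m$ratio_requirement),
      TANDEM_VT_VR = tandem_vt_vr_schedule(m$mean_interval,
                                           m$ratio_requirement,
                                           m$n_intervals))
    if (!is.null(m$extinction_duration) && !is.na(m$extinction_duration))
      schedule <- with_extinction(schedule, m$extinction_duration)
  }
  qt <- NULL
  qt_path <- file.path(dir, "q_trace.csv")
  if (file.exists(qt_path)) qt <- read.csv(qt_path)
  session_log(ev$time_s, ev$event_kind, params = params,
              schedule = schedule,
              agent = if (is.null(meta$agent)) NA_character_ else meta$agent,
              seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
              extinction_start = if (is.null(meta$extinction_start))
                NA_real_ else meta$extinction_start,
              q_trace = qt)
}

#' Read and write IRT sets
#'
#' IRT sets round-trip as a two-column CSV (\code{onset_s}, \code{tau_s}).
#'
#' @param irts An \code{irt_set}.
#' @param path CSV file path.
#' @return \code{write_irts()} returns \code{path} invisibly;
#'   \code{read_irts()} returns an \code{irt_set}.
#' @export
write_irts <- function(irts, path) {
  write.csv(data.frame(onset_s = irts$onset, tau_s = irts$tau), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_irts
#' @export
read_irts <- function(path) {
  d <- read.csv(path)
  irt_set(d$onset_s, d$tau_s)
}

#' Serialize a fit to JSON
#'
#' Writes the scalar components of a \code{biexp_fit},
#' \code{dynamic_biexp_fit} or \code{herrnstein_fit} (parameter estimates
#' and goodness-of-fit metadata; posterior samples and residual vectors are
#' omitted) to a JSON file.
#'
#' @param fit A fit object.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- Filter(function(v) is.atomic(v) && length(v) <= 8, unclass(fit))
  keep$samples <- NULL; keep$fitted <- NULL; keep$residuals <- NULL
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
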