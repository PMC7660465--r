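#' Condition tables for the packaged simulation experiments
#'
#' Returns the declarative condition list behind each experiment preset:
#' the model-comparison study (\code{"sim1"}: dual vs choice/cost
#' knockouts on VI 120 s), the four manipulation studies
#' (\code{"sim2-rate"}: VI 30/120/480 s; \code{"sim2-deprivation"}:
#' operant reinforcer value 0.5/1.0/1.5; \code{"sim2-extinction"}: VI
#' 120 s followed by a 3600 s extinction phase; \code{"sim2-tandem"}:
#' tandem VT 120 s VR 0/4/8), the two-state variant study (\code{"sim3"}:
#' VI 30/120/480 s), and the matching-law sweep (\code{"fig6"}: VI
#' 15-960 s).
#'
#' @param preset Preset name.
#' @return Data frame with one row per condition: \code{label},
#'   \code{agent}, \code{schedule_kind}, \code{mean_interval},
#'   \code{ratio}, \code{r_operant}, \code{extinction_duration}.
#' @export
experiment_conditions <- function(preset = c("sim1", "sim2-rate",
                                             "sim2-deprivation",
                                             "sim2-extinction",
                                             "sim2-tandem", "sim3",
                                             "fig6")) {
  preset <- match.arg(preset)
  row <- function(label, agent = "dual", kind = "VI", mi = 120, ratio = 0L,
                  r_op = 1.0, ext = NA_real_)
    data.frame(label = label, agent = agent, schedule_kind = kind,
               mean_interval = mi, ratio = ratio, r_operant = r_op,
               extinction_duration = ext)
  switch(preset,
    "sim1" = rbind(row("dual", "dual"), row("no_choice", "no_choice"),
                   row("no_cost", "no_cost")),
    "sim2-rate" = rbind(row("VI 30", mi = 30), row("VI 120", mi = 120),
                        row("VI 480", mi = 480)),
    "sim2-deprivation" = rbind(row("low", r_op = 0.5),
                               row("baseline", r_op = 1.0),
                               row("high", r_op = 1.5)),
    "sim2-extinction" = row("extinction", ext = 3600),
    "sim2-tandem" = rbind(
      row("VR 0", kind = "TANDEM_VT_VR", ratio = 0L),
      row("VR 4", kind = "TANDEM_VT_VR", ratio = 4L),
      row("VR 8", kind = "TANDEM_VT_VR", ratio = 8L)),
    "sim3" = rbind(row("VI 30", "two_state", mi = 30),
                   row("VI 120", "two_state", mi = 120),
                   row("VI 480", "two_state", mi = 480)),
    "fig6" = do.call(rbind, lapply(c(5, 10, 15, 30, 60, 120, 240, 480, 960),
                                   function(mi)
                                     row(sprintf("VI %g", mi), mi = mi))))
}

.condition_schedule <- function(cond) {
  sch <- switch(cond$schedule_kind,
                VI = vi_schedule(cond$mean_interval),
                FR = fr_schedule(cond$ratio),
                TANDEM_VT_VR = tandem_vt_vr_schedule(cond$mean_interval,
                                                     cond$ratio))
  if (!is.na(cond$extinction_duration))
    sch <- with_extinction(sch, cond$extinction_duration)
  sch
}

#' Run a table of simulation conditions
#'
#' Workhorse driver: runs every condition row under every seed, fits the
#' static bi-exponential model to the post-stabilization IRTs (when
#' requested and enough IRTs are available), and summarizes rates and mean
#' values. An empty condition table yields an empty summary.
#'
#' @param conditions Data frame as returned by [experiment_conditions()].
#' @param seeds Integer vector of session seeds.
#' @param max_reinforcers Operant reinforcer cap per session.
#' @param after_reinforcers Stabilization cutoff for all analyses; defaults
#'   to 500 or half the reinforcer cap, whichever is smaller.
#' @param fit_biexp Fit the bi-exponential mixture per session.
#' @param keep_sessions Also return the raw session logs (memory-heavy for
#'   long schedules).
#' @return A list of class \code{experiment_result} with \code{summary}
#'   (one row per session: condition fields, seed, IRT count, fitted
#'   \code{q}, \code{omega}, \code{b}, post-cutoff mean preference and cost
#'   values for the operant option, response and reinforcement rates) and
#'   optionally \code{sessions}.
#' @export
run_conditions <- function(conditions, seeds = 1L, max_reinforcers = 1000,
                           after_reinforcers = NULL, fit_biexp = TRUE,
                           keep_sessions = FALSE) {
  if (is.null(after_reinforcers))
    after_reinforcers <- min(500, floor(max_reinforcers / 2))
  rows <- list(); sessions <- list()
  if (!is.null(conditions) && nrow(conditions) > 0) {
    for (i in seq_len(nrow(conditions))) {
      cond <- conditions[i, , drop = FALSE]
      sch <- .condition_schedule(cond)
      params <- agent_preset(cond$agent)
      params$r_operant <- cond$r_operant
      for (sd in seeds) {
        s <- run_session(cond$agent, sch, max_reinforcers, seed = sd,
                         params = params)
        ir <- extract_irts(s, after_reinforcers)
        fit <- NULL
        if (fit_biexp && nrow(ir) >= 50) fit <- fit_biexponential(ir)
        cut_t <- .reinforcer_cutoff_time(s, after_reinforcers)
        qt <- s$q_trace[s$q_trace$time > cut_t, , drop = FALSE]
        rates <- rates_from_log(s, after_reinforcers)
        rows[[length(rows) + 1L]] <- data.frame(
          cond, seed = sd, n_irts = nrow(ir),
          q = if (is.null(fit)) NA_real_ else fit$q,
          omega = if (is.null(fit)) NA_real_ else fit$omega,
          b = if (is.null(fit)) NA_real_ else fit$b,
          degenerate = if (is.null(fit)) NA else fit$degenerate,
          mean_q_pref_operant = mean(qt$q_pref_operant),
          mean_q_cost_operant = mean(qt$q_cost_operant),
          reinforcement_rate = rates$reinforcement_rate,
          response_rate = rates$response_rate)
        if (keep_sessions)
          sessions[[sprintf("%s.seed%d", cond$label, sd)]] <- s
      }
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  structure(list(summary = summary,
                 sessions = if (keep_sessions) sessions else NULL,
                 after_reinforcers = after_reinforcers,
                 seeds = seeds),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", nrow(x$summary), "sessions\n")
  if (nrow(x$summary))
    print(x$summary[, intersect(c("label", "seed", "q", "omega", "b",
                                  "reinforcement_rate", "response_rate"),
                                names(x$summary))])
  invisible(x)
}

#' Run a packaged experiment preset end to end
#'
#' Runs all conditions of a preset and attaches the preset's analyses:
#' transition probabilities and log-survivor curves for \code{"sim1"},
#' per-condition bi-exponential parameters and mean value summaries for the
#' manipulation presets, the three dynamic bi-exponential fits and their
#' WAIC table for \code{"sim2-extinction"}, log-survivor curves for
#' \code{"sim3"}, and the Herrnstein matching fit for \code{"fig6"}.
#'
#' @param preset See [experiment_conditions()].
#' @param seed Base seed; condition seeds are \code{seed + 0:(n_seeds-1)}.
#' @param n_seeds Seeds per condition (defaults: 1 for \code{"sim1"} and
#'   \code{"sim2-extinction"}, 3 otherwise, matching the single-session
#'   design of the comparison studies and seed-averaged trend analyses).
#' @param max_reinforcers Operant reinforcer cap per session.
#' @param after_reinforcers Stabilization cutoff; see [run_conditions()].
#' @param mcmc Named list overriding the MCMC configuration of the
#'   extinction preset (\code{chains}, \code{warmup}, \code{iter}).
#' @param output_dir If non-\code{NULL}, summaries and fits are written
#'   there as CSV/JSON.
#' @return An \code{experiment_result} (see [run_conditions()]) with
#'   preset-specific extra components (\code{transitions},
#'   \code{survivor_curves}, \code{dynamic_fits}, \code{waic_table},
#'   \code{matching_fit}, \code{rate_points}).
#' @export
run_experiment <- function(preset, seed = 1, n_seeds = NULL,
                           max_reinforcers = 1000,
                           after_reinforcers = NULL, mcmc = list(),
                           output_dir = NULL) {
  preset <- match.arg(preset, c("sim1", "sim2-rate", "sim2-deprivation",
                                "sim2-extinction", "sim2-tandem", "sim3",
                                "fig6"))
  if (is.null(n_seeds))
    n_seeds <- if (preset %in% c("sim1", "sim2-extinction")) 1L else 3L
  seeds <- seed + seq_len(n_seeds) - 1L
  keep <- preset %in% c("sim1", "sim2-extinction", "sim3")
  res <- run_conditions(experiment_conditions(preset), seeds,
                        max_reinforcers, after_reinforcers,
                        keep_sessions = keep)
  after <- res$after_reinforcers
  res$preset <- preset

  if (preset == "sim1") {
    res$transitions <- lapply(res$sessions,
                              estimate_transition_probabilities, after)
    res$survivor_curves <- lapply(res$sessions, function(s)
      log_survivor(extract_irts(s, after)))
  }
  if (preset == "sim3") {
    res$survivor_curves <- lapply(res$sessions, function(s)
      log_survivor(extract_irts(s, after)))
  }
  if (preset == "sim2-extinction") {
    s <- res$sessions[[1]]
    ir_all <- extract_irts(s, after)
    pre <- ir_all$onset + ir_all$tau <= s$extinction_start
    static <- fit_biexponential(irt_set(ir_all$onset[pre],
                                        ir_all$tau[pre]))
    ext_ir <- extinction_irts(s)
    cfg <- modifyList(list(chains = 4, warmup = 2000, iter = 2000), mcmc)
    res$static_fit <- static
    res$extinction_irts <- ext_ir
    res$dynamic_fits <- lapply(
      setNames(.DYN_VARIANTS, .DYN_VARIANTS),
      function(v) fit_dynamic_biexponential(
        ext_ir, variant = v, omega = static$omega, chains = cfg$chains,
        warmup = cfg$warmup, iter = cfg$iter, seed = seed + 1000L))
    res$waic_table <- data.frame(
      variant = .DYN_VARIANTS,
      waic = vapply(res$dynamic_fits, function(f) f$waic, numeric(1)),
      converged = vapply(res$dynamic_fits, function(f) f$converged,
                         logical(1)))
  }
  if (preset == "fig6") {
    res$rate_points <- res$summary[, c("reinforcement_rate",
                                       "response_rate")]
    res$matching_fit <- fit_herrnstein(res$rate_points)
  }

  if (!is.null(output_dir)) .write_experiment(res, output_dir)
  res
}

#' Aggregate an experiment summary by condition
#'
#' Means of the fitted bout parameters, values, and rates over seeds, one
#' row per condition label (in the condition table's order).
#'
#' @param result An \code{experiment_result}.
#' @return Data frame of per-condition means.
#' @export
summarize_experiment <- function(result) {
  s <- result$summary
  if (!nrow(s)) return(s)
  num <- c("q", "omega", "b", "mean_q_pref_operant", "mean_q_cost_operant",
           "reinforcement_rate", "response_rate")
  num <- intersect(num, names(s))
  labs <- unique(s$label)
  out <- do.call(rbind, lapply(labs, function(lb) {
    sub <- s[s$label == lb, num, drop = FALSE]
    cbind(data.frame(label = lb, n_sessions = nrow(sub)),
          as.data.frame(as.list(colMeans(sub, na.rm = TRUE))))
  }))
  rownames(out) <- NULL
  out
}

.write_experiment <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(res$waic_table))
    write.csv(res$waic_table, file.path(dir, "waic.csv"),
              row.names = FALSE)
  if (!is.null(res$matching_fit))
    write_fit_json(res$matching_fit, file.path(dir, "matching_fit.json"))
  invisible(res)
}
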