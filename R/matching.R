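#' Steady-state response and reinforcement rates from a session
#'
#' Computes the molar rates entering the matching-law analysis: operant
#' responses per minute and operant reinforcers per minute over the span of
#' the log after the stabilization cutoff.
#'
#' @param session A \code{session_log}.
#' @param after_reinforcers Stabilization cutoff (number of operant
#'   reinforcers; 0 uses the whole log).
#' @return One-row data frame with columns \code{reinforcement_rate} and
#'   \code{response_rate} (per minute).
#' @export
rates_from_log <- function(session, after_reinforcers = 500) {
  stopifnot(inherits(session, "session_log"))
  cutoff <- .reinforcer_cutoff_time(session, after_reinforcers)
  ev <- session$events
  if (nrow(ev) == 0) stop("log spans no time after the cutoff")
  t_end <- max(ev$time)
  if (!is.finite(cutoff)) cutoff <- 0
  span <- t_end - cutoff
  if (span <= 0) stop("log spans no time after the cutoff")
  post <- ev[ev$time > cutoff, , drop = FALSE]
  data.frame(
    reinforcement_rate = sum(post$kind == "reinforcer_operant") / span * 60,
    response_rate = sum(post$kind == "operant_response") / span * 60)
}

#' Fit the modern Herrnstein hyperbola
#'
#' Fits the generalized matching hyperbola
#' \deqn{R = \frac{k\,r^a}{r^a + r_e^a/c}}
#' to response-rate (\eqn{R}) vs reinforcement-rate (\eqn{r}) points by
#' nonlinear least squares on the raw rate scale, estimating the asymptote
#' \eqn{k}, the sensitivity exponent \eqn{a} (\eqn{a > 1} is overmatching)
#' and the combined external-reinforcement term \eqn{r_e^a/c} (the two
#' factors are not separately identifiable). A deterministic multi-start
#' over sensitivity values guards against local optima; all parameters are
#' constrained positive.
#'
#' @param points Data frame with columns \code{reinforcement_rate} and
#'   \code{response_rate} (per minute), at least 3 distinct reinforcement
#'   rates.
#' @return An object of class \code{herrnstein_fit}: list with \code{k},
#'   \code{a}, \code{re_term}, \code{vaf} (percent variance accounted for,
#'   \eqn{100(1 - SS_{res}/SS_{tot})}), \code{n}, \code{fitted} and
#'   \code{residuals}.
#' @examples
#' r <- c(0.25, 0.5, 1, 2, 4)
#' pts <- data.frame(reinforcement_rate = r,
#'                   response_rate = 200 * r / (r + 2))
#' fit_herrnstein(pts)
#' @export
fit_herrnstein <- function(points) {
  stopifnot(all(c("reinforcement_rate", "response_rate") %in% names(points)))
  r <- points$reinforcement_rate
  R <- points$response_rate
  if (length(unique(r)) < 3)
    stop("need at least 3 points with distinct reinforcement rates")
  if (any(r < 0) || any(R < 0)) stop("rates must be non-negative")

  dat <- data.frame(r = r, R = R)
  ss_fun <- function(th) {
    k <- exp(th[1]); a <- exp(th[2]); re <- exp(th[3])
    v <- sum((R - k * r^a / (r^a + re))^2)
    if (!is.finite(v)) 1e300 else v
  }
  # multi-start least squares on the log scale (positivity for free and
  # robust on the k/re ridge that arises when the data do not bracket the
  # asymptote), then a Levenberg-Marquardt polish
  best <- NULL
  for (a0 in c(0.5, 1, 1.5, 2, 3)) for (k0 in c(1.1, 1.5, 3) * max(R)) {
    th0 <- c(log(k0), log(a0), log(max(median(r)^a0, 1e-6)))
    o <- optim(th0, ss_fun, control = list(maxit = 5000, reltol = 1e-12))
    o <- tryCatch(optim(o$par, ss_fun, method = "BFGS",
                        control = list(maxit = 1000)),
                  error = function(e) o)
    if (is.null(best) || o$value < best$value) best <- o
  }
  cf <- exp(best$par)
  names(cf) <- c("k", "a", "re")
  polish <- tryCatch(
    minpack.lm::nlsLM(R ~ k * r^a / (r^a + re), data = dat,
                      start = as.list(cf),
                      lower = c(k = 1e-9, a = 1e-9, re = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(polish) && sum(residuals(polish)^2) <= best$value)
    cf <- coef(polish)
  fitted_R <- cf["k"] * r^cf["a"] / (r^cf["a"] + cf["re"])
  ss_res <- sum((R - fitted_R)^2)
  ss_tot <- sum((R - mean(R))^2)
  structure(list(k = unname(cf["k"]), a = unname(cf["a"]),
                 re_term = unname(cf["re"]),
                 vaf = 100 * (1 - ss_res / ss_tot),
                 n = length(r), fitted = fitted_R,
                 residuals = R - fitted_R),
            class = "herrnstein_fit")
}

#' @export
print.herrnstein_fit <- function(x, ...) {
  cat(sprintf(
    "<herrnstein_fit> k = %.2f resp/min, a = %.3f, re_term = %.3f (n = %d)\n",
    x$k, x$a, x$re_term, x$n))
  cat(sprintf("  %%VAF = %.2f%s\n", x$vaf,
              if (x$a > 1.001) "  (a > 1: overmatching)" else ""))
  invisible(x)
}

#' @export
plot.herrnstein_fit <- function(x, points = NULL, ...) {
  if (is.null(points))
    stop("supply the fitted `points` data frame to plot")
  r <- points$reinforcement_rate
  plot(r, points$response_rate, xlab = "reinforcers/min",
       ylab = "responses/min", ...)
  rr <- seq(min(r), max(r), length.out = 200)
  lines(rr, x$k * rr^x$a / (rr^x$a + x$re_term))
  invisible(x)
}
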