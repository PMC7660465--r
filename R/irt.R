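#' Interresponse-time sets
#'
#' \code{irt_set()} builds the container used by the IRT analyses: one row
#' per interresponse time (IRT), with the onset time of the interval (the
#' time of the response that opens it) and the interval length \code{tau}.
#'
#' \code{extract_irts()} computes IRTs from a session log as successive
#' differences of operant-response times only — events of other kinds
#' (other-behavior responses, reinforcers, state entries) neither break nor
#' contribute to an IRT — restricted to responses strictly after the
#' \code{after_reinforcers}-th operant reinforcer.
#'
#' \code{extinction_irts()} restricts instead to operant responses in the
#' extinction phase and rebases onset times to the extinction onset, as
#' required by the dynamic bi-exponential model.
#'
#' @param onset Numeric vector of IRT onset times, seconds, non-decreasing.
#' @param tau Positive IRT lengths, seconds.
#' @param session A \code{session_log}.
#' @param after_reinforcers Stabilization cutoff (0 uses all responses).
#' @return An \code{irt_set}: a data frame with columns \code{onset} and
#'   \code{tau}. Fewer than two qualifying responses yield an empty set.
#' @examples
#' irt_set(c(1, 1.3), c(0.3, 3.7))
#' @export
irt_set <- function(onset, tau) {
  stopifnot(length(onset) == length(tau))
  if (length(tau) && any(tau <= 0)) stop("IRTs must be positive")
  if (is.unsorted(onset)) stop("onset times must be non-decreasing")
  structure(data.frame(onset = as.numeric(onset), tau = as.numeric(tau)),
            class = c("irt_set", "data.frame"))
}

#' @rdname irt_set
#' @export
extract_irts <- function(session, after_reinforcers = 500) {
  stopifnot(inherits(session, "session_log"))
  cutoff <- .reinforcer_cutoff_time(session, after_reinforcers)
  ev <- session$events
  rt <- ev$time[ev$kind == "operant_response" & ev$time > cutoff]
  if (length(rt) < 2) return(irt_set(numeric(0), numeric(0)))
  irt_set(rt[-length(rt)], diff(rt))
}

#' @rdname irt_set
#' @export
extinction_irts <- function(session) {
  stopifnot(inherits(session, "session_log"))
  t0 <- session$extinction_start
  if (is.na(t0)) stop("session has no extinction phase")
  ev <- session$events
  rt <- ev$time[ev$kind == "operant_response" & ev$time > t0]
  if (length(rt) < 2) return(irt_set(numeric(0), numeric(0)))
  rt <- rt - t0
  irt_set(rt[-length(rt)], diff(rt))
}

#' Empirical log-survivor curve
#'
#' The log-survivor curve plots \eqn{\ln P(IRT > \tau)} against \eqn{\tau}.
#' A single-exponential IRT distribution gives a straight line; a
#' bi-exponential mixture gives the "broken-stick" shape diagnostic of
#' bout-and-pause patterning. The empirical survivor proportion is computed
#' at each distinct IRT value (right-continuous step convention; the
#' largest value, where the survivor proportion is 0, is dropped from the
#' log-scale curve).
#'
#' @param irts An \code{irt_set} (non-empty).
#' @return A data frame of class \code{survivor_curve} with columns
#'   \code{tau}, \code{survivor} and \code{log_survivor}, non-increasing in
#'   \code{tau}.
#' @examples
#' log_survivor(irt_set(1:4, c(1, 2, 3, 4)))
#' @export
log_survivor <- function(irts) {
  tau <- sort(irts$tau)
  n <- length(tau)
  if (n == 0) stop("empty IRT set")
  u <- unique(tau)
  cnt <- tabulate(match(tau, u), nbins = length(u))
  s <- (n - cumsum(cnt)) / n
  keep <- s > 0
  structure(data.frame(tau = u[keep], survivor = s[keep],
                       log_survivor = log(s[keep])),
            class = c("survivor_curve", "data.frame"))
}

#' @export
plot.survivor_curve <- function(x, ..., xlab = "IRT (s)",
                                ylab = "log survivor") {
  plot(x$tau, x$log_survivor, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# slope-based rate of the slow (right) limb, used for starting values
.tail_rate <- function(irts, frac = 0.3) {
  sc <- log_survivor(irts)
  k <- max(5L, ceiling(nrow(sc) * frac))
  tl <- tail(sc, k)
  if (nrow(tl) < 2 || diff(range(tl$tau)) == 0) return(1 / mean(irts$tau))
  max(1e-4, -coef(lm(log_survivor ~ tau, data = tl))[2])
}

# bi-exponential mixture log-likelihood terms, overflow-safe
.biexp_loglik <- function(tau, q, omega, b) {
  l1 <- log1p(-q) + log(omega) - omega * tau
  l2 <- log(q) + log(b) - b * tau
  m <- pmax(l1, l2)
  sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

.single_exp_loglik <- function(tau) {
  rate <- 1 / mean(tau)
  length(tau) * log(rate) - rate * sum(tau)
}

#' Fit the bi-exponential IRT mixture by maximum likelihood
#'
#' Fits the mixture density
#' \deqn{p(\tau) = (1-q)\,\omega e^{-\omega\tau} + q\,b e^{-b\tau}}
#' to an IRT sample under the constraints \eqn{q \in [0,1]} and
#' \eqn{\omega \ge b} (the fast component is the within-bout rate, the slow
#' component the bout-initiation rate; the constraint excludes label
#' switching). Optimization is quasi-Newton on the unconstrained scale
#' \code{(logit q, log b, log(omega - b))} from a deterministic set of
#' multi-starts; the slow-rate start is taken from the tail slope of the
#' log-survivor curve.
#'
#' @param irts An \code{irt_set} with at least 50 IRTs.
#' @param n_starts Number of multi-starts (>= 1).
#' @return An object of class \code{biexp_fit}: a list with elements
#'   \code{q}, \code{omega}, \code{b}, \code{loglik}, \code{loglik_single}
#'   (single-exponential fit of the same data), \code{lr} (likelihood-ratio
#'   statistic of bi- vs single-exponential), \code{n}, \code{degenerate}
#'   (\code{TRUE} when the fit is effectively mono-exponential: mixture
#'   weight within 0.02 of a boundary or \eqn{\omega/b < 1.5}), and
#'   \code{convergence}.
#' @examples
#' set.seed(1)
#' tau <- ifelse(runif(500) < 0.3, rexp(500, 0.1), rexp(500, 3))
#' fit_biexponential(irt_set(seq_along(tau), tau))
#' @export
fit_biexponential <- function(irts, n_starts = 10) {
  tau <- irts$tau
  n <- length(tau)
  if (n < 50) stop("need at least 50 IRTs to fit the bi-exponential model")

  nll <- function(th) {
    q <- plogis(th[1]); b <- exp(th[2]); omega <- b + exp(th[3])
    v <- -.biexp_loglik(tau, q, omega, b)
    if (!is.finite(v)) 1e10 else v
  }

  b0 <- min(.tail_rate(irts), 1 / mean(tau))
  fast <- tau[tau <= median(tau)]
  w0 <- max(1 / mean(fast), b0 * 2)
  qs <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  bm <- c(1, 0.5, 2)
  starts <- list()
  for (qq in qs) for (mm in bm) {
    starts[[length(starts) + 1L]] <-
      c(qlogis(qq), log(b0 * mm), log(max(w0 - b0 * mm, 1e-3)))
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(optim(st, nll, method = "BFGS",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(optim(st, nll, control = list(maxit = 2000)),
                      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("bi-exponential optimization failed for all starts")

  th <- best$par
  q <- plogis(th[1]); b <- exp(th[2]); omega <- b + exp(th[3])
  ll <- -best$value
  ll1 <- .single_exp_loglik(tau)
  structure(list(q = unname(q), omega = unname(omega), b = unname(b),
                 loglik = ll, loglik_single = ll1,
                 lr = 2 * (ll - ll1), n = n,
                 degenerate = q < 0.02 || q > 0.98 || omega / b < 1.5,
                 convergence = best$convergence),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> q = %.3f, omega = %.3f /s, b = %.4f /s  (n = %d)\n",
              x$q, x$omega, x$b, x$n))
  cat(sprintf("  loglik %.2f (single-exponential %.2f, LR = %.1f)%s\n",
              x$loglik, x$loglik_single, x$lr,
              if (x$degenerate) " [effectively mono-exponential]" else ""))
  invisible(x)
}
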