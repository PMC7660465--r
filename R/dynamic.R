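.DYN_VARIANTS <- c("qb_decay", "q_decay", "b_decay")

# fill a parameter point with the variant's fixed zeros
.dyn_complete <- function(params, variant) {
  th <- c(q0 = NA_real_, b0 = NA_real_, gamma = 0, delta = 0)
  th[names(params)] <- unlist(params)
  if (variant == "q_decay") th["delta"] <- 0
  if (variant == "b_decay") th["gamma"] <- 0
  th
}

#' Dynamic bi-exponential log-likelihood
#'
#' Log-likelihood of the time-varying bi-exponential IRT model used for
#' extinction data,
#' \deqn{p(\tau \mid t) = (1-q_t)\,\omega e^{-\omega\tau} +
#'       q_t\,b_t e^{-b_t\tau},}
#' where extinction decays the parameters as \eqn{1-q_t = (1-q_0)e^{-\gamma t}}
#' and \eqn{b_t = b_0 e^{-\delta t}}, with \eqn{t} each IRT's onset time
#' measured from extinction onset. The within-bout rate \eqn{\omega} is held
#' fixed (it is set by the response-emission mechanism, not by extinction).
#' Variants fix one decay rate at zero: \code{"q_decay"} forces
#' \eqn{\delta = 0}, \code{"b_decay"} forces \eqn{\gamma = 0}; with
#' \eqn{\gamma = \delta = 0} the model reduces exactly to the static
#' mixture.
#'
#' @param params Named list/vector with \code{q0}, \code{b0} and the
#'   variant's free decay rates \code{gamma}, \code{delta}.
#' @param irts An \code{irt_set} with onsets measured from extinction onset.
#' @param omega Fixed within-bout rate, per second (> 0).
#' @param variant One of \code{"qb_decay"}, \code{"q_decay"},
#'   \code{"b_decay"}.
#' @return The summed log-likelihood; \code{-Inf} for invalid parameter
#'   points (rates <= 0, \code{q0} outside [0, 1], negative decay rates).
#' @examples
#' ir <- irt_set(c(0, 0), c(1, 2))
#' dynamic_biexp_loglik(list(q0 = 0.5, b0 = 0.5, gamma = 0, delta = 0),
#'                      ir, omega = 2)
#' @export
dynamic_biexp_loglik <- function(params, irts, omega,
                                 variant = "qb_decay") {
  variant <- match.arg(variant, .DYN_VARIANTS)
  th <- .dyn_complete(params, variant)
  q0 <- th["q0"]; b0 <- th["b0"]; gam <- th["gamma"]; del <- th["delta"]
  if (anyNA(th) || omega <= 0 || b0 <= 0 || q0 < 0 || q0 > 1 ||
      gam < 0 || del < 0)
    return(-Inf)
  t <- irts$onset; tau <- irts$tau
  one_minus_qt <- (1 - q0) * exp(-gam * t)
  qt <- 1 - one_minus_qt
  bt <- b0 * exp(-del * t)
  l1 <- log(one_minus_qt) + log(omega) - omega * tau
  l2 <- log(qt) + log(bt) - bt * tau
  m <- pmax(l1, l2)
  v <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
  if (!is.finite(v)) -Inf else v
}

# vector of per-observation log densities at one parameter point
.dyn_loglik_i <- function(th, irts, omega) {
  t <- irts$onset; tau <- irts$tau
  one_minus_qt <- (1 - th["q0"]) * exp(-th["gamma"] * t)
  qt <- 1 - one_minus_qt
  bt <- th["b0"] * exp(-th["delta"] * t)
  l1 <- log(one_minus_qt) + log(omega) - omega * tau
  l2 <- log(qt) + log(bt) - bt * tau
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

# split-half potential scale reduction factor over a draws x chains matrix
.split_rhat <- function(draws) {
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  w <- mean(apply(halves, 2, var))
  bvar <- n * var(mu)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + bvar / n) / w)
}

#' Fit a dynamic bi-exponential model by MCMC
#'
#' Samples the posterior of the variant's free parameters under weakly
#' informative priors (\code{q0} uniform on [0, 1]; \code{b0},
#' \code{gamma}, \code{delta} half-normal with scales
#' \code{prior_scales}) with an adaptive random-walk Metropolis sampler,
#' and scores the model by per-observation WAIC.
#'
#' @param irts Extinction-phase \code{irt_set} (onsets from extinction
#'   onset; see [extinction_irts()]).
#' @param variant Which parameters decay; see [dynamic_biexp_loglik()].
#' @param omega Fixed within-bout rate. The conventional choice is the
#'   \code{omega} of a static fit to the pre-extinction IRTs of the same
#'   session; if \code{NULL}, it is estimated by a static fit to the
#'   supplied IRTs.
#' @param chains,warmup,iter MCMC configuration: number of chains, warmup
#'   iterations discarded per chain, and kept iterations per chain.
#' @param prior_scales Half-normal prior scales for \code{b0} (per second)
#'   and the decay rates (per second of extinction time).
#' @param seed Optional seed.
#' @param max_waic_draws Posterior draws used for the WAIC computation
#'   (thinned evenly from the kept draws).
#' @return An object of class \code{dynamic_biexp_fit}: list with
#'   \code{variant}, \code{omega}, \code{samples} (data frame of kept draws
#'   with a \code{chain} column), \code{rhat} (split-\eqn{\hat R} per
#'   parameter), \code{converged} (all \eqn{\hat R < 1.05}), \code{waic}
#'   (per observation; lower is better), \code{p_waic}, \code{accept_rate}
#'   and \code{n}.
#' @export
fit_dynamic_biexponential <- function(irts, variant = "qb_decay",
                                      omega = NULL, chains = 4,
                                      warmup = 2000, iter = 2000,
                                      prior_scales = c(b0 = 1, gamma = 0.01,
                                                       delta = 0.01),
                                      seed = NULL, max_waic_draws = 2000) {
  variant <- match.arg(variant, .DYN_VARIANTS)
  stopifnot(nrow(irts) >= 10, chains >= 1, warmup >= 100, iter >= 100)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(omega)) omega <- fit_biexponential(irts)$omega

  free <- switch(variant,
                 qb_decay = c("q0", "b0", "gamma", "delta"),
                 q_decay = c("q0", "b0", "gamma"),
                 b_decay = c("q0", "b0", "delta"))

  log_prior <- function(th) {
    if (th["q0"] < 0 || th["q0"] > 1 || th["b0"] <= 0) return(-Inf)
    lp <- -0.5 * (th["b0"] / prior_scales["b0"])^2
    if ("gamma" %in% free) {
      if (th["gamma"] < 0) return(-Inf)
      lp <- lp - 0.5 * (th["gamma"] / prior_scales["gamma"])^2
    }
    if ("delta" %in% free) {
      if (th["delta"] < 0) return(-Inf)
      lp <- lp - 0.5 * (th["delta"] / prior_scales["delta"])^2
    }
    unname(lp)
  }
  log_post <- function(th)
    log_prior(th) + dynamic_biexp_loglik(as.list(th), irts, omega, variant)

  # componentwise random-walk Metropolis with per-parameter step
  # adaptation during warmup; chains start overdispersed on the log scale
  step0 <- c(q0 = 0.05, b0 = 0.02, gamma = 0.002, delta = 0.002)[free]
  kept <- vector("list", chains)
  acc_rates <- numeric(chains)
  npar <- length(free)
  for (ch in seq_len(chains)) {
    th <- c(q0 = runif(1, 0.05, 0.6),
            b0 = exp(runif(1, log(0.01), log(0.5))),
            gamma = exp(runif(1, log(1e-5), log(5e-3))),
            delta = exp(runif(1, log(1e-5), log(5e-3))))[free]
    lp <- log_post(th)
    step <- step0
    draws <- matrix(NA_real_, iter, npar, dimnames = list(NULL, free))
    n_acc <- 0L; n_try <- 0L
    win_acc <- setNames(numeric(npar), free)
    win_n <- 0L
    total <- warmup + iter
    for (it in seq_len(total)) {
      for (p in free) {
        prop <- th
        prop[p] <- prop[p] + rnorm(1) * step[p]
        lpp <- log_post(prop)
        n_try <- n_try + 1L
        if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
          th <- prop; lp <- lpp
          n_acc <- n_acc + 1L; win_acc[p] <- win_acc[p] + 1L
        }
      }
      win_n <- win_n + 1L
      if (it <= warmup && it %% 50L == 0L) {
        rate <- win_acc / win_n
        step <- ifelse(rate > 0.5, step * 1.4,
                       ifelse(rate < 0.25, step / 1.4, step))
        win_acc[] <- 0; win_n <- 0L
      }
      if (it > warmup) draws[it - warmup, ] <- th
    }
    kept[[ch]] <- draws
    acc_rates[ch] <- n_acc / n_try
  }

  rhat <- vapply(free, function(p)
    .split_rhat(sapply(kept, function(d) d[, p])), numeric(1))

  samples <- do.call(rbind, lapply(seq_len(chains), function(ch)
    data.frame(chain = ch, kept[[ch]])))

  waic <- compute_waic(samples, irts, omega = omega, variant = variant,
                       max_draws = max_waic_draws)

  structure(list(variant = variant, omega = omega, samples = samples,
                 rhat = rhat, converged = all(rhat < 1.05, na.rm = TRUE),
                 waic = as.numeric(waic),
                 p_waic = attr(waic, "p_waic"),
                 accept_rate = mean(acc_rates), n = nrow(irts),
                 prior_scales = prior_scales),
            class = "dynamic_biexp_fit")
}

#' @export
print.dynamic_biexp_fit <- function(x, ...) {
  pm <- colMeans(x$samples[setdiff(names(x$samples), "chain")])
  cat(sprintf("<dynamic_biexp_fit> variant = %s (omega fixed at %.3f /s)\n",
              x$variant, x$omega))
  cat("  posterior means:",
      paste(sprintf("%s = %.4g", names(pm), pm), collapse = ", "), "\n")
  cat(sprintf("  WAIC/obs = %.4f (p_waic = %.2f), max split-Rhat = %.3f%s\n",
              x$waic, x$p_waic, max(x$rhat),
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  invisible(x)
}

#' Per-observation WAIC from posterior samples
#'
#' Computes the widely applicable information criterion on the
#' per-observation scale,
#' \deqn{\mathrm{WAIC} = -\frac1n \sum_i \ln\left(\mathrm{mean}_s\,
#'   p(\tau_i \mid \theta_s)\right) + \frac1n \sum_i \mathrm{var}_s\left(
#'   \ln p(\tau_i \mid \theta_s)\right),}
#' where \eqn{s} indexes posterior draws. Lower is better.
#'
#' @param samples Data frame of posterior draws (columns among \code{q0},
#'   \code{b0}, \code{gamma}, \code{delta}; extra columns such as
#'   \code{chain} are ignored), or a \code{dynamic_biexp_fit}.
#' @param irts The \code{irt_set} the model was fitted to.
#' @param omega Fixed within-bout rate (taken from the fit if a fit is
#'   supplied).
#' @param variant Model variant (taken from the fit if supplied).
#' @param max_draws Number of draws used (evenly thinned). At least 500
#'   post-warmup draws are required.
#' @return The per-observation WAIC (numeric scalar) with attributes
#'   \code{p_waic} (effective number of parameters per observation times n)
#'   and \code{degenerate} (\code{TRUE}, with a warning, if the posterior
#'   has zero variance).
#' @export
compute_waic <- function(samples, irts, omega = NULL, variant = "qb_decay",
                         max_draws = 2000) {
  if (inherits(samples, "dynamic_biexp_fit")) {
    omega <- samples$omega
    variant <- samples$variant
    samples <- samples$samples
  }
  stopifnot(!is.null(omega))
  variant <- match.arg(variant, .DYN_VARIANTS)
  cols <- intersect(c("q0", "b0", "gamma", "delta"), names(samples))
  s <- nrow(samples)
  if (s < 500) stop("need at least 500 posterior draws")
  idx <- unique(round(seq(1, s, length.out = min(max_draws, s))))
  n <- nrow(irts)
  ll <- matrix(NA_real_, length(idx), n)
  for (j in seq_along(idx)) {
    th <- .dyn_complete(samples[idx[j], cols, drop = FALSE], variant)
    ll[j, ] <- .dyn_loglik_i(th, irts, omega)
  }
  # log mean_s p_i, computed stably
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, var)
  degenerate <- all(p_i == 0)
  if (degenerate) warning("degenerate posterior: zero variance in draws")
  out <- mean(-lppd_i) + mean(p_i)
  attr(out, "p_waic") <- sum(p_i)
  attr(out, "degenerate") <- degenerate
  out
}
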