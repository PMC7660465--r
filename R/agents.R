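#' Agent parameters
#'
#' Bundles the learning and decision parameters of the bout-and-pause
#' agents. Defaults are the baseline three-state (dual) configuration:
#' reinforcement learning rate \code{alpha_rft} = 0.05, extinction learning
#' rate \code{alpha_ext} = 0.01, softmax inverse temperature \code{beta} =
#' 12.5, stay-decision weights \code{w_pref} = 1.0 and \code{w_cost} = 3.5,
#' reinforcer values 1.0 (operant) and 0.5 (other behaviors), a response
#' emission probability of 1/3 per time step, and a 0.1 s time step.
#'
#' @param alpha_rft Learning rate applied when a reinforcer is delivered,
#'   in (0, 1].
#' @param alpha_ext Learning rate applied when an engagement ends without a
#'   reinforcer, in (0, 1].
#' @param beta Softmax inverse temperature (>= 0) of the choice rule.
#' @param w_pref,w_cost Positive weights of preference and changeover cost
#'   in the stay probability.
#' @param r_operant,r_others Reinforcer values (>= 0) for the operant and
#'   other behaviors.
#' @param response_prob Per-step probability of emitting a response while
#'   engaged, in (0, 1].
#' @param dt Simulation time step, seconds.
#' @return A named list of class \code{agent_params}.
#' @seealso [agent_preset()] for the published parameter sets.
#' @export
agent_params <- function(alpha_rft = 0.05, alpha_ext = 0.01, beta = 12.5,
                         w_pref = 1.0, w_cost = 3.5,
                         r_operant = 1.0, r_others = 0.5,
                         response_prob = 1 / 3, dt = 0.1) {
  p <- list(alpha_rft = alpha_rft, alpha_ext = alpha_ext, beta = beta,
            w_pref = w_pref, w_cost = w_cost,
            r_operant = r_operant, r_others = r_others,
            response_prob = response_prob, dt = dt)
  stopifnot(alpha_rft > 0, alpha_rft <= 1, alpha_ext > 0, alpha_ext <= 1,
            beta >= 0, w_pref > 0, w_cost > 0,
            r_operant >= 0, r_others >= 0,
            response_prob > 0, response_prob <= 1, dt > 0)
  structure(p, class = "agent_params")
}

#' Published agent parameter presets
#'
#' Returns the parameter set belonging to each agent variant. The
#' \code{"dual"}, \code{"no_choice"} and \code{"no_cost"} three-state agents
#' share the baseline parameters (the knockouts differ structurally, not
#' parametrically). The \code{"two_state"} agent uses its own selected set:
#' alpha_rft = 0.01, alpha_ext = 0.01, w_pref = 4.0, w_cost = 3.5 (its stay
#' rule is a softmax over weighted values, so no separate inverse
#' temperature is involved).
#'
#' @param agent One of \code{"dual"}, \code{"no_choice"}, \code{"no_cost"},
#'   \code{"two_state"}.
#' @return An \code{agent_params} object.
#' @export
agent_preset <- function(agent = c("dual", "no_choice", "no_cost",
                                   "two_state")) {
  agent <- match.arg(agent)
  if (agent == "two_state")
    agent_params(alpha_rft = 0.01, alpha_ext = 0.01, w_pref = 4.0,
                 w_cost = 3.5)
  else
    agent_params()
}

#' Q-learning value updates
#'
#' The delta-rule updates of the agent's preference and changeover-cost
#' values. \code{update_pref_reinforced()} moves the preference toward the
#' reinforcer value r after a reinforced engagement; \code{update_pref_extinction()}
#' decays it toward 0 after an engagement that ended without a reinforcer;
#' \code{update_cost()} moves the cost toward \eqn{\ln x}, where x is the
#' number of responses emitted to obtain the reinforcer since bout
#' initiation (the logarithm implements Fechnerian attenuation of the
#' response count).
#'
#' @param q Current value (preference or cost).
#' @param r Reinforcer value (>= 0).
#' @param alpha_rft,alpha_ext Learning rates in (0, 1].
#' @param x Response count since bout initiation (>= 1).
#' @return The updated value (vectorized over \code{q}).
#' @examples
#' update_pref_reinforced(0.5, 1.0, 0.05)   # 0.525
#' update_pref_extinction(0.5, 0.01)        # 0.495
#' update_cost(0, 10, 0.05)                 # 0.05 * log(10)
#' @export
update_pref_reinforced <- function(q, r, alpha_rft) {
  stopifnot(alpha_rft > 0, alpha_rft <= 1)
  q + alpha_rft * (r - q)
}

#' @rdname update_pref_reinforced
#' @export
update_pref_extinction <- function(q, alpha_ext) {
  stopifnot(alpha_ext > 0, alpha_ext <= 1)
  q + alpha_ext * (0 - q)
}

#' @rdname update_pref_reinforced
#' @export
update_cost <- function(q, x, alpha_rft) {
  stopifnot(alpha_rft > 0, alpha_rft <= 1)
  if (any(x < 1)) stop("`x` (response count) must be >= 1")
  q + alpha_rft * (log(x) - q)
}

#' Choice and stay probabilities
#'
#' \code{choice_probabilities()} is the softmax choice rule over the
#' preference values of the available options,
#' \eqn{p_i = e^{\beta q_i} / \sum_j e^{\beta q_j}}, computed with
#' max-subtraction for overflow safety.
#'
#' \code{stay_probability()} is the three-state agent's probability of
#' staying in the currently engaged state after a response,
#' \eqn{p_{stay} = \exp\{-1 / (w_{pref} Q_{pref} + w_{cost} Q_{cost})\}},
#' defined as 0 when the weighted sum is 0. It is strictly increasing in
#' both values and bounded in [0, 1).
#'
#' \code{two_state_stay_probability()} is the two-state agent's stay rule: a
#' softmax over the weighted scores \eqn{s_i = w_{pref} Q_{pref}^{(i)} +
#' w_{cost} Q_{cost}^{(i)}} of the two options, returning the probability
#' mass of the currently engaged option.
#'
#' @param q_pref Named numeric vector of preference values (for
#'   \code{stay_probability()}, the scalar value of the engaged option).
#' @param q_cost Cost value(s), matching \code{q_pref}.
#' @param beta Softmax inverse temperature (>= 0).
#' @param w_pref,w_cost Positive weights.
#' @param current Name of the currently engaged option.
#' @return Probabilities; \code{choice_probabilities()} returns a named
#'   vector summing to 1.
#' @examples
#' choice_probabilities(c(operant = 1.0, others = 0.5), beta = 12.5)
#' stay_probability(0.5, 1.0, 1.0, 3.5)   # exp(-1/4)
#' two_state_stay_probability(c(operant = 1, others = 0),
#'                            c(operant = 0, others = 0),
#'                            w_pref = 4, w_cost = 3.5, current = "operant")
#' @export
choice_probabilities <- function(q_pref, beta) {
  stopifnot(beta >= 0, length(q_pref) >= 2)
  z <- beta * q_pref
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @rdname choice_probabilities
#' @export
stay_probability <- function(q_pref, q_cost, w_pref, w_cost) {
  stopifnot(w_pref > 0, w_cost > 0)
  s <- w_pref * q_pref + w_cost * q_cost
  ifelse(s <= 0, 0, exp(-1 / s))
}

#' @rdname choice_probabilities
#' @export
two_state_stay_probability <- function(q_pref, q_cost, w_pref, w_cost,
                                       current) {
  stopifnot(w_pref > 0, w_cost > 0, length(q_pref) == length(q_cost),
            length(q_pref) >= 2)
  if (!current %in% names(q_pref))
    stop("`current` must name one of the options in `q_pref`")
  s <- w_pref * q_pref + w_cost * q_cost
  s <- s - max(s)
  e <- exp(s)
  unname(e[current] / sum(e))
}
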