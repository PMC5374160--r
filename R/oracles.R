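#' Exact expected outcome by exhaustive enumeration
#'
#' Independent verification oracle for the Monte-Carlo mean: enumerates every
#' equally likely interaction sequence (`n_alters ^ n_steps` of them), applies
#' the exact update rule including clamping to each, and averages the final
#' states. Intended for toy problem sizes; refuses when the sequence count
#' exceeds `max_sequences`.
#'
#' @param network an [ego_network()].
#' @param mech a [mechanism()].
#' @param config a [sim_config()].
#' @param max_sequences enumeration cap (default `1e6`).
#' @return a list with `expected_id_a`, `expected_id_b` and `n_sequences`.
#' @examples
#' net <- ego_network(c("A", "B"))
#' exact_expectation(net, mechanism("positive"), sim_config(n_steps = 2))
#' @export
exact_expectation <- function(network, mech, config = sim_config(),
                              max_sequences = 1e6) {
  stopifnot(inherits(network, "ego_network"), inherits(mech, "mechanism"),
            inherits(config, "sim_config"))
  n <- network$n_alters
  steps <- config$n_steps
  n_seq <- n^steps
  if (n_seq > max_sequences) {
    stop(sprintf(
      "enumeration of %d^%d = %s sequences exceeds cap %s",
      n, steps, format(n_seq, big.mark = ","),
      format(max_sequences, big.mark = ",")
    ), call. = FALSE)
  }
  if (steps == 0L) {
    return(list(expected_id_a = config$initial_identification,
                expected_id_b = config$initial_identification,
                n_sequences = 1L))
  }
  is_a <- network$cultures == "A"
  delta <- config$base_increment * (1 + same_culture_degrees(network))
  w <- mechanism_weight(mech)
  lo <- config$lower_bound
  up <- config$upper_bound
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), steps),
                                KEEP.OUT.ATTRS = FALSE))
  a <- rep(config$initial_identification, nrow(seqs))
  b <- a
  for (t in seq_len(steps)) {
    i <- seqs[, t]
    d <- delta[i]
    sa <- is_a[i]
    a <- a + ifelse(sa, w * d, -(1 - w) * d)
    b <- b + ifelse(sa, -(1 - w) * d, w * d)
    a <- pmin(up, pmax(lo, a))
    b <- pmin(up, pmax(lo, b))
  }
  list(expected_id_a = mean(a), expected_id_b = mean(b),
       n_sequences = nrow(seqs))
}

#' Closed-form expected outcome where clamping is unreachable
#'
#' When no interaction sequence can push either identification to a bound,
#' expectations are linear in time: each step contributes
#' `(1/n) * (w * sum over same-culture alters of delta_i
#'          - (1 - w) * sum over other-culture alters of delta_i)`
#' to each identification, with `delta_i = base_increment * (1 + degree_i)`
#' and `w` the mechanism's positive weight (1, 0, or alpha). So, e.g., under
#' the positive mechanism
#' `E[id_a] = initial + n_steps * (1/n) * sum_{A alters} base_increment * (1 + degree_i)`.
#'
#' The precondition is checked against the worst-case path: drawing the
#' strongest-influence alter at every step must keep both identifications
#' inside the bounds. Designs where a bound is reachable only with
#' vanishingly small probability (e.g. one culture-A alter drawn 26+ times
#' out of 50) fail this strict check; pass `on_clamp_risk = "warn"` (or
#' `"ignore"`) to obtain the no-clamp linear value anyway as an approximate
#' oracle.
#'
#' @param n_alters roster size.
#' @param n_culture_a number of culture-A alters (roster slots `0..n_culture_a-1`).
#' @param degrees integer vector of per-alter same-culture degrees, length
#'   `n_alters`, aligned with the roster (first `n_culture_a` entries are the
#'   A alters).
#' @param mech a [mechanism()].
#' @param config a [sim_config()].
#' @param on_clamp_risk `"error"` (default), `"warn"` or `"ignore"`: what to
#'   do when some path could reach a bound.
#' @return a list with `expected_id_a` and `expected_id_b`.
#' @examples
#' # one culture-A alter with no same-culture ties, 50 steps, positive effect
#' no_clamp_mean(8, 1, rep(0L, 8), mechanism("positive"),
#'               on_clamp_risk = "ignore")
#' @export
no_clamp_mean <- function(n_alters, n_culture_a, degrees, mech,
                          config = sim_config(),
                          on_clamp_risk = c("error", "warn", "ignore")) {
  stopifnot(inherits(mech, "mechanism"), inherits(config, "sim_config"))
  on_clamp_risk <- match.arg(on_clamp_risk)
  n_alters <- as.integer(n_alters)
  if (length(degrees) != n_alters) {
    stop("degrees must have one entry per alter", call. = FALSE)
  }
  if (n_culture_a < 0 || n_culture_a > n_alters) {
    stop(sprintf("n_culture_a out of bounds [0, %d]", n_alters), call. = FALSE)
  }
  is_a <- seq_len(n_alters) <= n_culture_a
  w <- mechanism_weight(mech)
  delta <- config$base_increment * (1 + degrees)
  steps <- config$n_steps
  init <- config$initial_identification
  # worst-case cumulative move of each coordinate
  max_up_a <- if (any(is_a)) max(w * delta[is_a]) else 0
  max_dn_a <- if (any(!is_a)) max((1 - w) * delta[!is_a]) else 0
  max_up_b <- if (any(!is_a)) max(w * delta[!is_a]) else 0
  max_dn_b <- if (any(is_a)) max((1 - w) * delta[is_a]) else 0
  reachable <-
    init + steps * max(max_up_a, max_up_b) > config$upper_bound ||
    init - steps * max(max_dn_a, max_dn_b) < config$lower_bound
  if (reachable) {
    msg <- "a bound is reachable by some interaction sequence; the no-clamp closed form is invalid there"
    if (on_clamp_risk == "error") stop(msg, call. = FALSE)
    if (on_clamp_risk == "warn") warning(msg, call. = FALSE)
  }
  per_step_a <- (w * sum(delta[is_a]) - (1 - w) * sum(delta[!is_a])) / n_alters
  per_step_b <- (w * sum(delta[!is_a]) - (1 - w) * sum(delta[is_a])) / n_alters
  list(expected_id_a = init + steps * per_step_a,
       expected_id_b = init + steps * per_step_b)
}
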