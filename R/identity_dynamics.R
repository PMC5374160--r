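#' Ego's identification state
#'
#' Ego carries two cultural identification scores on a Likert-type 1--6
#' scale: `id_a` (identification with culture A) and `id_b` (culture B).
#' Every update clamps both back into the configured bounds, so states stay
#' within `[1, 6]` throughout a simulation.
#'
#' @param id_a,id_b numeric identification scores.
#' @return an object of class `identity_state`.
#' @export
identity_state <- function(id_a, id_b) {
  stopifnot(is.numeric(id_a), is.numeric(id_b),
            length(id_a) == 1L, length(id_b) == 1L)
  structure(list(id_a = as.numeric(id_a), id_b = as.numeric(id_b)),
            class = "identity_state")
}

#' @export
print.identity_state <- function(x, ...) {
  cat(sprintf("<identity_state: id_a = %g, id_b = %g>\n", x$id_a, x$id_b))
  invisible(x)
}

#' Influence mechanism
#'
#' Which update rule an interaction applies:
#' * `"positive"` -- interaction raises identification with the alter's
#'   culture; the other identification is untouched.
#' * `"negative"` -- interaction lowers identification with the *other*
#'   culture; the alter's own culture is untouched.
#' * `"mixed"` -- both at once, weighted by `alpha` on `[0, 1]`: the alter's
#'   culture gains `alpha` of the increment and the other culture loses
#'   `1 - alpha` of it. `alpha = 1` reproduces the positive mechanism exactly
#'   and `alpha = 0` the negative one (bit-identical given the same random
#'   stream); only `alpha = 0.5` weighs the two effects equally.
#'
#' @param kind `"positive"`, `"negative"` or `"mixed"`.
#' @param alpha mixing weight in `[0, 1]`; required for (and only allowed
#'   with) `"mixed"`.
#' @return an object of class `mechanism` with fields `kind` and `alpha`
#'   (`NA` unless mixed).
#' @export
mechanism <- function(kind = c("positive", "negative", "mixed"), alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "mixed") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L ||
        is.na(alpha) || alpha < 0 || alpha > 1) {
      stop("mixed mechanism requires alpha in [0, 1]", call. = FALSE)
    }
  } else if (!is.null(alpha)) {
    stop(sprintf("alpha is only meaningful for the mixed mechanism (got kind = '%s')",
                 kind), call. = FALSE)
  }
  structure(
    list(kind = kind,
         alpha = if (kind == "mixed") as.numeric(alpha) else NA_real_),
    class = "mechanism"
  )
}

#' @export
print.mechanism <- function(x, ...) {
  if (x$kind == "mixed") {
    cat(sprintf("<mechanism: mixed, alpha = %g>\n", x$alpha))
  } else {
    cat(sprintf("<mechanism: %s>\n", x$kind))
  }
  invisible(x)
}

# Positive weight w: the alter's culture gains w * delta, the other loses
# (1 - w) * delta. positive == w = 1, negative == w = 0, mixed == w = alpha.
# Routing all three kinds through one weight makes the alpha-endpoint
# equivalence bit-exact by construction.
mechanism_weight <- function(mech) {
  switch(mech$kind, positive = 1, negative = 0, mixed = mech$alpha)
}

#' Simulation configuration
#'
#' Defaults encode the model's stated world: 50 interaction steps, both
#' identifications initialized at the 3.5 scale midpoint, a base increment of
#' 0.1 per interaction (the basic unit of change, multiplied by
#' `1 + degree centrality`), and clamping bounds 1 and 6.
#'
#' @param n_steps positive integer number of interactions.
#' @param initial_identification starting value of both identifications.
#' @param base_increment positive base change per interaction.
#' @param lower_bound,upper_bound clamping bounds of the identification scale.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 50L, initial_identification = 3.5,
                       base_increment = 0.1, lower_bound = 1,
                       upper_bound = 6) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 0L) {
    stop("n_steps must be a non-negative integer", call. = FALSE)
  }
  if (!(base_increment > 0)) stop("base_increment must be > 0", call. = FALSE)
  if (!(lower_bound <= initial_identification &&
        initial_identification <= upper_bound)) {
    stop("initial_identification must lie within [lower_bound, upper_bound]",
         call. = FALSE)
  }
  structure(
    list(n_steps = n_steps,
         initial_identification = as.numeric(initial_identification),
         base_increment = as.numeric(base_increment),
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound)),
    class = "sim_config"
  )
}

clamp1 <- function(x, lo, up) {
  if (x > up) up else if (x < lo) lo else x
}

#' Apply one interaction to ego's state
#'
#' One social interaction with an alter of culture `alter_culture` and
#' same-culture degree `degree` changes ego's state by
#' `delta = base_increment * (1 + degree)`:
#' the alter's culture gains `w * delta` and the other culture loses
#' `(1 - w) * delta`, where `w` is 1 (positive), 0 (negative) or `alpha`
#' (mixed). Both coordinates are computed from the pre-update state, then
#' clamped into `[lower_bound, upper_bound]`. Pure function: the input state
#' is not modified.
#'
#' @param state an [identity_state()].
#' @param alter_culture `"A"` or `"B"` (or alias).
#' @param degree non-negative integer same-culture degree of the alter.
#' @param mech a [mechanism()].
#' @param config a [sim_config()].
#' @return the new [identity_state()].
#' @examples
#' s <- identity_state(3.5, 3.5)
#' apply_interaction(s, "A", 2, mechanism("positive"), sim_config())
#' @export
apply_interaction <- function(state, alter_culture, degree, mech,
                              config = sim_config()) {
  stopifnot(inherits(state, "identity_state"), inherits(mech, "mechanism"),
            inherits(config, "sim_config"))
  alter_culture <- normalize_culture(alter_culture)
  if (!is.numeric(degree) || length(degree) != 1L || is.na(degree) ||
      degree < 0 || degree != round(degree)) {
    stop("degree must be a non-negative integer", call. = FALSE)
  }
  w <- mechanism_weight(mech)
  delta <- config$base_increment * (1 + degree)
  a <- state$id_a
  b <- state$id_b
  if (alter_culture == "A") {
    a <- a + w * delta
    b <- b - (1 - w) * delta
  } else {
    b <- b + w * delta
    a <- a - (1 - w) * delta
  }
  identity_state(clamp1(a, config$lower_bound, config$upper_bound),
                 clamp1(b, config$lower_bound, config$upper_bound))
}

#' Simulate an identification trajectory
#'
#' Runs the dynamics on a static network: at each of `n_steps` time steps one
#' alter is drawn uniformly at random (independently, with replacement) and
#' [apply_interaction()] is applied with that alter's same-culture degree.
#' Degrees are computed once up front -- composition and structure of the
#' network are held constant through time.
#'
#' @param network an [ego_network()] with at least one alter.
#' @param mech a [mechanism()].
#' @param config a [sim_config()].
#' @param seed optional integer seed; when `NULL`, draws come from the global
#'   random stream. Identical seeds give bit-identical trajectories.
#' @return an `identity_trajectory`: a data frame with one row per state
#'   (row 1 = initial state at step 0) and columns `step`,
#'   `interacted_alter_id` (0-based, `NA` on the initial row),
#'   `alter_culture` (`NA` on the initial row), `id_a`, `id_b`.
#' @examples
#' net <- generate_network(8, 8, 0, seed = 1)
#' traj <- simulate_identity(net, mechanism("positive"), seed = 42)
#' final_state(traj)
#' @export
simulate_identity <- function(network, mech, config = sim_config(),
                              seed = NULL) {
  stopifnot(inherits(network, "ego_network"), inherits(mech, "mechanism"),
            inherits(config, "sim_config"))
  n <- network$n_alters
  if (n < 1L) stop("network must contain at least one alter", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  is_a <- network$cultures == "A"
  delta <- config$base_increment * (1 + same_culture_degrees(network))
  w <- mechanism_weight(mech)
  lo <- config$lower_bound
  up <- config$upper_bound
  steps <- config$n_steps
  draws <- if (steps > 0L) sample.int(n, steps, replace = TRUE) else integer(0)
  a <- numeric(steps + 1L)
  b <- numeric(steps + 1L)
  a[1] <- b[1] <- config$initial_identification
  ca <- a[1]
  cb <- b[1]
  for (t in seq_len(steps)) {
    i <- draws[t]
    d <- delta[i]
    if (is_a[i]) {
      ca <- ca + w * d
      cb <- cb - (1 - w) * d
    } else {
      cb <- cb + w * d
      ca <- ca - (1 - w) * d
    }
    if (ca > up) ca <- up else if (ca < lo) ca <- lo
    if (cb > up) cb <- up else if (cb < lo) cb <- lo
    a[t + 1L] <- ca
    b[t + 1L] <- cb
  }
  traj <- data.frame(
    step = 0:steps,
    interacted_alter_id = c(NA_integer_, draws - 1L),
    alter_culture = c(NA_character_,
                      ifelse(is_a[draws], "A", "B"))[seq_len(steps + 1L)],
    id_a = a,
    id_b = b,
    stringsAsFactors = FALSE
  )
  class(traj) <- c("identity_trajectory", "data.frame")
  traj
}

#' Final state of a trajectory
#'
#' The pair of outcome identifications after the last simulated interaction
#' (for a zero-step trajectory, the initial state).
#'
#' @param trajectory an `identity_trajectory` from [simulate_identity()].
#' @return an [identity_state()].
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "identity_trajectory"),
            nrow(trajectory) >= 1L)
  identity_state(trajectory$id_a[nrow(trajectory)],
                 trajectory$id_b[nrow(trajectory)])
}

#' Write a trajectory as tidy CSV
#'
#' Columns `step, interacted_alter_id, alter_culture, id_a, id_b`; the step-0
#' row carries the initial state with empty interaction fields.
#' Identification values are formatted with 6 decimal places so output is
#' byte-reproducible.
#'
#' @param trajectory an `identity_trajectory`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "identity_trajectory"))
  out <- data.frame(
    step = trajectory$step,
    interacted_alter_id = ifelse(is.na(trajectory$interacted_alter_id), "",
                                 trajectory$interacted_alter_id),
    alter_culture = ifelse(is.na(trajectory$alter_culture), "",
                           trajectory$alter_culture),
    id_a = sprintf("%.6f", trajectory$id_a),
    id_b = sprintf("%.6f", trajectory$id_b)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
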