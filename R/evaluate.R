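#' Noisy-OR probability of a binary effect
#'
#' Probability that a binary effect occurs given binary generative causes
#' with independent causal influences:
#' \deqn{P(E) = 1 - \prod_i (1 - w_i \delta_i).}
#'
#' @param strengths Numeric vector of causal strengths in `[0, 1]`.
#' @param indicators Binary vector (`0`/`1`) of the same length: which causes
#'   are present.
#' @return Probability in `[0, 1]`.
#' @examples
#' noisy_or(c(0.5, 0.5), c(1, 1)) # 0.75
#' @export
noisy_or <- function(strengths, indicators) {
  check_noisy_inputs(strengths, indicators, probability = TRUE)
  1 - prod(1 - strengths * indicators)
}

#' Noisy-OR/AND probability of a binary effect
#'
#' Extends [noisy_or()] with non-cause-specific preventers: the effect occurs
#' iff at least one generative capacity is active AND no preventive capacity
#' is active:
#' \deqn{P(E) = \prod_j (1 - w_j \delta(P_j)) \,
#'   [1 - \prod_i (1 - w_i \delta(C_i))].}
#'
#' With every generative cause absent the bracket is 0, so the effect stays
#' at its baseline with probability 1 regardless of the preventers.
#'
#' @param gen_strengths,gen_indicators Generative strengths in `[0, 1]` and
#'   their binary presence indicators.
#' @param prev_strengths,prev_indicators Preventive strengths in `[0, 1]` and
#'   indicators. Default: no preventers.
#' @return Probability in `[0, 1]`.
#' @examples
#' noisy_or_and(c(0.8), c(1), c(0.5), c(1)) # 0.4
#' @export
noisy_or_and <- function(gen_strengths, gen_indicators,
                         prev_strengths = numeric(0),
                         prev_indicators = numeric(0)) {
  check_noisy_inputs(gen_strengths, gen_indicators, probability = TRUE)
  check_noisy_inputs(prev_strengths, prev_indicators, probability = TRUE)
  prod(1 - prev_strengths * prev_indicators) *
    (1 - prod(1 - gen_strengths * gen_indicators))
}

#' Noisy-MAX expected effect
#'
#' One traditional generalization of noisy-OR to a real-valued effect: the
#' expectation is the largest single active contribution,
#' \eqn{\max_i(w_i \delta_i)} (0 when no cause is present).
#'
#' @inheritParams noisy_or
#' @param strengths Nonnegative strengths (not restricted to `[0, 1]`).
#' @return Nonnegative real.
#' @export
noisy_max <- function(strengths, indicators) {
  check_noisy_inputs(strengths, indicators, probability = FALSE)
  if (length(strengths) == 0L) return(0)
  max(c(0, strengths * indicators))
}

#' Noisy-addition expected effect
#'
#' The other traditional generalization: contributions add,
#' \eqn{\sum_i w_i \delta_i}.
#'
#' @inheritParams noisy_max
#' @return Nonnegative real.
#' @export
noisy_addition <- function(strengths, indicators) {
  check_noisy_inputs(strengths, indicators, probability = FALSE)
  sum(strengths * indicators)
}

check_noisy_inputs <- function(strengths, indicators, probability) {
  if (length(strengths) != length(indicators)) {
    stop("strengths and indicators must have equal length", call. = FALSE)
  }
  if (length(strengths) == 0L) return(invisible(NULL))
  if (any(strengths < 0) || (probability && any(strengths > 1))) {
    stop(if (probability) "strengths must lie in [0, 1]"
         else "strengths must be nonnegative", call. = FALSE)
  }
  if (!all(indicators %in% c(0, 1))) {
    stop("indicators must be 0 or 1", call. = FALSE)
  }
  invisible(NULL)
}

#' The privileged two-argument combination function
#'
#' Combines two nonnegative causal contributions `x`, `y` in `[0, U]` into a
#' single contribution,
#' \deqn{f(x, y) = x + y - xy/U,}
#' the unique finite-polynomial accumulation function that is symmetric,
#' associative, leaves a single contribution unchanged (`f(x, 0) = x`),
#' produces no uncaused effect (`f(0, 0) = 0`), and saturates at the upper
#' bound (`f(U, U) = U`). At `U = 1` it is the noisy-OR combination.
#'
#' @param x,y Contributions in `[0, U]`.
#' @param U Positive upper bound of the effect range.
#' @return Combined contribution in `[0, U]`.
#' @examples
#' pairwise_combine(0.5, 0.5, 1)  # 0.75
#' pairwise_combine(3, 4, 10)     # 5.8
#' @export
pairwise_combine <- function(x, y, U) {
  stopifnot(is.numeric(U), length(U) == 1L, U > 0)
  if (any(x < 0 | x > U) || any(y < 0 | y > U)) {
    stop(sprintf("inputs must lie in [0, %g]", U), call. = FALSE)
  }
  x + y - x * y / U
}

#' Probability that no blocker fires
#'
#' The pass-through factor \eqn{\prod_k (1 - w_k b_k)}: the probability that
#' none of the blocking capacities is active, i.e. that the other causes'
#' influence on the effect is expressed at all. The empty product is 1.
#'
#' @param strengths Blocker strengths.
#' @param values Blocker values, with every product `w_k * b_k` in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @export
blocking_passthrough <- function(strengths, values) {
  if (length(strengths) != length(values)) {
    stop("strengths and values must have equal length", call. = FALSE)
  }
  p <- strengths * values
  if (any(p < 0 | p > 1 + 1e-12)) {
    stop("each blocker's strength * value must lie in [0, 1]", call. = FALSE)
  }
  prod(1 - pmin(p, 1))
}

#' Expected effect under the bounded capacity model
#'
#' Evaluates the privileged expected-effect equation for a finite-bound
#' model: generators combine through the normalized noisy-OR product toward
#' the upper bound `U`, reducers combine symmetrically toward the lower bound
#' `-L`, their difference is the unblocked expectation, and the blocker
#' pass-through scales the whole bracket:
#' \deqn{E(E) = \prod_k (1 - w_k b_k)\Big[
#'   U\Big(1 - \prod_i \frac{U - w_i g_i}{U}\Big) -
#'   L\Big(1 - \prod_j \frac{L - w_j r_j}{L}\Big)\Big].}
#'
#' When `L = 0` (and hence no reducers) the reducer bracket is 0; likewise
#' for `U = 0` and generators. Both bounds must be finite; the unbounded
#' linear regime is served by [linear_expected_effect()].
#'
#' @param model A [capacity_model()] with finite bounds.
#' @param values Named numeric assignment of cause values (see
#'   [check_assignment()]).
#' @return The expectation of the effect, a number in `[-L, U]`.
#' @examples
#' m <- capacity_model(
#'   effect_range(2, 10),
#'   list(cause("g", "generator", 2, max_value = 3),
#'        cause("r", "reducer", 1, max_value = 2),
#'        cause("b", "blocker", 0.5, max_value = 1))
#' )
#' expected_effect(m, c(g = 3, r = 1, b = 1))
#' @export
expected_effect <- function(model, values) {
  stopifnot(inherits(model, "capacity_model"))
  L <- model$range$lower
  U <- model$range$upper
  if (!is.finite(L) || !is.finite(U)) {
    stop("expected_effect requires finite bounds; use linear_expected_effect ",
         "for the unbounded linear regime", call. = FALSE)
  }
  validate_model(model, allow_na_strength = FALSE)
  values <- check_assignment(model, values)
  roles <- cause_roles(model)
  w <- cause_strengths(model)
  contrib <- w * values

  gen <- contrib[roles == "generator"]
  red <- contrib[roles == "reducer"]
  blk <- contrib[roles == "blocker"]

  if (length(gen) && any(gen > U + 1e-12)) {
    stop("a generator contribution w * g exceeds the upper bound", call. = FALSE)
  }
  if (length(red) && any(red > L + 1e-12)) {
    stop("a reducer contribution w * r exceeds the lower-bound magnitude",
         call. = FALSE)
  }

  up <- if (length(gen)) U * (1 - prod((U - gen) / U)) else 0
  down <- if (length(red)) L * (1 - prod((L - red) / L)) else 0
  blocking_passthrough(rep(1, length(blk)), blk) * (up - down)
}

#' Expected effect in the unbounded linear regime
#'
#' In the limit of an unbounded effect range the normalized products
#' linearize and the expectation becomes
#' \deqn{E(E) = \prod_k (1 - w_k b_k)\Big[\sum_i w_i g_i -
#'   \sum_j w_j r_j\Big].}
#' With no blockers this is the pure linear (delta-P-style) form. The model
#' must be declared with infinite bounds; blockers retain their `[0, 1]`
#' constraint.
#'
#' @param model A [capacity_model()] with `effect_range(Inf, Inf)` (or one
#'   infinite side with no causes of the other sign).
#' @param values Named numeric assignment. Generator and reducer values may
#'   be any reals here (signed contributions are meaningful in the linear
#'   regime); blocker values stay in `[0, max_value]`.
#' @return The linear expectation, any real number.
#' @export
linear_expected_effect <- function(model, values) {
  stopifnot(inherits(model, "capacity_model"))
  L <- model$range$lower
  U <- model$range$upper
  roles <- cause_roles(model)
  if (any(roles == "generator") && is.finite(U)) {
    stop("linear_expected_effect requires an infinite upper bound", call. = FALSE)
  }
  if (any(roles == "reducer") && is.finite(L)) {
    stop("linear_expected_effect requires an infinite lower bound", call. = FALSE)
  }
  labels <- cause_labels(model)
  if (is.null(names(values)) && length(values) == length(labels)) {
    names(values) <- labels
  }
  if (!setequal(names(values), labels)) {
    stop("assignment labels do not match model causes", call. = FALSE)
  }
  values <- values[labels]
  w <- cause_strengths(model)
  contrib <- w * values
  gen <- contrib[roles == "generator"]
  red <- contrib[roles == "reducer"]
  blk <- contrib[roles == "blocker"]
  blocking_passthrough(rep(1, length(blk)), blk) * (sum(gen) - sum(red))
}

#' Evaluate a model over a table of assignments
#'
#' Vectorized [expected_effect()] (or [linear_expected_effect()] for
#' infinite-bound models) over the rows of a data frame whose columns are
#' the model's cause labels.
#'
#' @param model A `capacity_model`.
#' @param assignments Data frame with one column per cause label, one row per
#'   assignment.
#' @return Numeric vector of expectations, one per row.
#' @export
evaluate_model <- function(model, assignments) {
  stopifnot(inherits(model, "capacity_model"), is.data.frame(assignments))
  labels <- cause_labels(model)
  missing <- setdiff(labels, names(assignments))
  if (length(missing)) {
    stop("assignment table is missing cause column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(assignments[labels])
  mx <- cause_max_values(model)
  L <- model$range$lower
  U <- model$range$upper
  linear <- !is.finite(L) || !is.finite(U)
  if (!linear) {
    for (j in seq_along(labels)) {
      bad <- which(vals[, j] < 0 | vals[, j] > mx[j] + 1e-12)
      if (length(bad)) {
        stop(sprintf("row %d: value %g for cause '%s' outside [0, %g]",
                     bad[1], vals[bad[1], j], labels[j], mx[j]), call. = FALSE)
      }
    }
  }
  roles <- cause_roles(model)
  w <- cause_strengths(model)
  contrib <- sweep(vals, 2, w, `*`)

  pass <- rep(1, nrow(vals))
  for (j in which(roles == "blocker")) {
    p <- contrib[, j]
    if (any(p < 0 | p > 1 + 1e-12)) {
      stop(sprintf("blocker '%s': w * value outside [0, 1]", labels[j]),
           call. = FALSE)
    }
    pass <- pass * (1 - pmin(p, 1))
  }
  if (linear) {
    up <- rowSums(contrib[, roles == "generator", drop = FALSE])
    down <- rowSums(contrib[, roles == "reducer", drop = FALSE])
    return(pass * (up - down))
  }
  gprod <- rep(1, nrow(vals))
  for (j in which(roles == "generator")) gprod <- gprod * (U - contrib[, j]) / U
  rprod <- rep(1, nrow(vals))
  for (j in which(roles == "reducer")) rprod <- rprod * (L - contrib[, j]) / L
  up <- if (any(roles == "generator")) U * (1 - gprod) else 0
  down <- if (any(roles == "reducer")) L * (1 - rprod) else 0
  pass * (up - down)
}

#' Rescale a non-linear cause to act linearly
#'
#' A cause whose effect on the expectation is a non-linear (but strictly
#' monotone, zero-preserving) function of its raw value can always be
#' replaced by the rescaled cause `transform(value)`, which then acts
#' linearly with a single strength number. The transform must fix the
#' inactive state: `transform(0) = 0`.
#'
#' @param values Numeric vector of raw cause values.
#' @param transform A strictly monotone function with `transform(0) = 0`.
#' @return The rescaled values `transform(values)`.
#' @examples
#' linearize_cause(c(0, 1, 4, 9), sqrt)
#' @export
linearize_cause <- function(values, transform) {
  stopifnot(is.function(transform))
  if (abs(transform(0)) > 1e-12) {
    stop("transform must map the inactive value 0 to 0", call. = FALSE)
  }
  out <- vapply(values, transform, numeric(1))
  o <- order(values)
  d <- diff(out[o][!duplicated(values[o])])
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("transform is not strictly monotone on the supplied values",
         call. = FALSE)
  }
  out
}
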