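#' Effect value range
#'
#' Declares the value interval of an effect variable as \eqn{[-L, U]} with the
#' baseline value fixed at 0. The two magnitudes are given as nonnegative
#' numbers (or `Inf`); the lower bound of the interval is `-lower`. The
#' baseline (the value the effect takes when no represented cause is active)
#' is always 0 and is conceptually distinct from the lower bound: `lower = 0`
#' means baseline and lower bound coincide, `lower > 0` means the effect can
#' be pushed below its resting value.
#'
#' @param lower Nonnegative magnitude \eqn{L} of the lower bound (the bound
#'   itself is \eqn{-L}), or `Inf`.
#' @param upper Nonnegative magnitude \eqn{U} of the upper bound, or `Inf`.
#' @return An object of class `effect_range` with elements `lower` and
#'   `upper`.
#' @examples
#' effect_range(0, 1)    # probability-like effect on [0, 1]
#' effect_range(2, 10)   # effect on [-2, 10], baseline 0
#' effect_range(Inf, Inf) # unbounded effect (linear regime)
#' @export
effect_range <- function(lower, upper) {
  stopifnot(is.numeric(lower), length(lower) == 1L,
            is.numeric(upper), length(upper) == 1L)
  if (is.na(lower) || is.na(upper)) {
    stop("effect_range bounds must not be NA", call. = FALSE)
  }
  if (lower < 0 || upper < 0) {
    stop("effect_range magnitudes must be nonnegative (the lower bound is -lower)",
         call. = FALSE)
  }
  if (lower == 0 && upper == 0) {
    stop("at least one of lower, upper must be strictly positive", call. = FALSE)
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 baseline = 0), class = "effect_range")
}

#' @export
print.effect_range <- function(x, ...) {
  cat(sprintf("<effect_range> [%s, %s], baseline 0\n",
              format(-x$lower), format(x$upper)))
  invisible(x)
}

#' A single causal capacity
#'
#' A cause is a capacity of one of three kinds: a `"generator"` pushes the
#' effect up from its baseline toward the upper bound, a `"reducer"` pushes
#' it down toward the lower bound, and a `"blocker"` probabilistically
#' prevents every other capacity from influencing the effect. The inactive
#' value of every cause is 0 and its active values lie in `[0, max_value]`.
#'
#' The strength `w` is on the expected-change scale: the expected change in
#' the effect per one-unit increase of this cause from its inactive state,
#' with every other cause inactive. For a blocker, `w` is the per-unit
#' increase in the probability of complete blocking. In an all-binary model
#' (`max_value = 1`, values in `{0, 1}`) the expected-change reading of a
#' generator's strength coincides with the classic probability-of-activation
#' reading of the noisy-OR weight.
#'
#' @param label Character scalar naming the cause.
#' @param role One of `"generator"`, `"reducer"`, `"blocker"`.
#' @param strength Nonnegative causal strength `w`. May be `NA` in a skeleton
#'   model handed to [fit_weights()].
#' @param max_value Positive maximum value `M` of the cause, or `Inf`.
#' @return An object of class `cause`.
#' @examples
#' cause("caffeine", "generator", strength = 0.4)
#' cause("anesthetic", "reducer", strength = 0.3, max_value = 2)
#' cause("beta_blocker", "blocker", strength = 0.8)
#' @export
cause <- function(label, role = c("generator", "reducer", "blocker"),
                  strength, max_value = 1) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(is.numeric(strength), length(strength) == 1L)
  stopifnot(is.numeric(max_value), length(max_value) == 1L)
  if (!is.na(strength) && strength < 0) {
    stop(sprintf("cause '%s': strength must be nonnegative, got %g",
                 label, strength), call. = FALSE)
  }
  if (is.na(max_value) || max_value <= 0) {
    stop(sprintf("cause '%s': max_value must be strictly positive", label),
         call. = FALSE)
  }
  structure(list(label = label, role = role,
                 strength = as.numeric(strength),
                 max_value = as.numeric(max_value)),
            class = "cause")
}

#' @export
print.cause <- function(x, ...) {
  cat(sprintf("<cause> %s: %s, w = %s, values in [0, %s]\n",
              x$label, x$role, format(x$strength), format(x$max_value)))
  invisible(x)
}

#' Causal capacity model
#'
#' Bundles an effect range and an ordered list of causes into the object
#' evaluated by [expected_effect()]. Construction validates the joint
#' constraints between each cause and the effect range: a generator's maximal
#' contribution `w * M` may not exceed `U`, a reducer's may not exceed `L`,
#' and a blocker's blocking probability `w * M` may not exceed 1. Reducers
#' require `L > 0` and generators require `U > 0` (otherwise the normalizing
#' division in the expected-effect equation is undefined).
#'
#' @param range An [effect_range()].
#' @param causes A list of [cause()] objects with distinct labels (a single
#'   `cause` is accepted and wrapped).
#' @return An object of class `capacity_model` with elements `range` and
#'   `causes` (named by cause label).
#' @examples
#' m <- capacity_model(
#'   effect_range(0, 1),
#'   list(cause("c1", "generator", 0.5),
#'        cause("c2", "generator", 0.5))
#' )
#' expected_effect(m, c(c1 = 1, c2 = 1))
#' @export
capacity_model <- function(range, causes = list()) {
  if (!inherits(range, "effect_range")) {
    stop("range must be an effect_range object", call. = FALSE)
  }
  if (inherits(causes, "cause")) causes <- list(causes)
  if (!is.list(causes) || !all(vapply(causes, inherits, logical(1), "cause"))) {
    stop("causes must be a list of cause objects", call. = FALSE)
  }
  labels <- vapply(causes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("cause labels must be distinct: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  names(causes) <- labels
  model <- structure(list(range = range, causes = causes),
                     class = "capacity_model")
  validate_model(model)
  model
}

#' Validate a capacity model
#'
#' Checks every cause's constraints against the model's effect range. Called
#' by [capacity_model()]; exported so that models assembled by hand or read
#' from file can be re-checked.
#'
#' @param model A `capacity_model`.
#' @param allow_na_strength If `TRUE`, `NA` strengths (skeleton models for
#'   estimation) pass validation.
#' @return `model`, invisibly; errors name the offending cause and field.
#' @export
validate_model <- function(model, allow_na_strength = TRUE) {
  stopifnot(inherits(model, "capacity_model"))
  L <- model$range$lower
  U <- model$range$upper
  for (cs in model$causes) {
    w <- cs$strength
    if (is.na(w)) {
      if (!allow_na_strength) {
        stop(sprintf("cause '%s': strength is NA", cs$label), call. = FALSE)
      }
      next
    }
    wmax <- w * cs$max_value
    switch(cs$role,
      generator = {
        if (U == 0) {
          stop(sprintf("cause '%s': generators require upper > 0", cs$label),
               call. = FALSE)
        }
        if (is.finite(U) && wmax > U + 1e-12) {
          stop(sprintf(
            "cause '%s': generator strength * max_value = %g exceeds upper bound %g",
            cs$label, wmax, U), call. = FALSE)
        }
      },
      reducer = {
        if (L == 0) {
          stop(sprintf("cause '%s': reducers require lower > 0", cs$label),
               call. = FALSE)
        }
        if (is.finite(L) && wmax > L + 1e-12) {
          stop(sprintf(
            "cause '%s': reducer strength * max_value = %g exceeds lower magnitude %g",
            cs$label, wmax, L), call. = FALSE)
        }
      },
      blocker = {
        if (wmax > 1 + 1e-12) {
          stop(sprintf(
            "cause '%s': blocker strength * max_value = %g exceeds 1",
            cs$label, wmax), call. = FALSE)
        }
      }
    )
  }
  invisible(model)
}

#' @export
print.capacity_model <- function(x, ...) {
  cat(sprintf("<capacity_model> effect in [%s, %s], %d cause(s)\n",
              format(-x$range$lower), format(x$range$upper), length(x$causes)))
  for (cs in x$causes) {
    cat(sprintf("  %-12s %-9s w = %-8s M = %s\n",
                cs$label, cs$role, format(cs$strength), format(cs$max_value)))
  }
  invisible(x)
}

# Internal helpers --------------------------------------------------------

cause_roles <- function(model) {
  vapply(model$causes, `[[`, character(1), "role")
}

cause_strengths <- function(model) {
  vapply(model$causes, `[[`, numeric(1), "strength")
}

cause_labels <- function(model) {
  names(model$causes)
}

cause_max_values <- function(model) {
  vapply(model$causes, `[[`, numeric(1), "max_value")
}

#' Check a cause-value assignment against a model
#'
#' An assignment maps every cause label of the model to a value in
#' `[0, max_value]` for that cause. Labels must match the model exactly:
#' no extras, none missing.
#'
#' @param model A `capacity_model`.
#' @param values Named numeric vector of cause values.
#' @return The values, reordered to the model's cause order, invisibly
#'   returned visibly for chaining.
#' @export
check_assignment <- function(model, values) {
  labels <- cause_labels(model)
  if (is.null(names(values)) && length(values) == length(labels)) {
    names(values) <- labels
  }
  extra <- setdiff(names(values), labels)
  missing <- setdiff(labels, names(values))
  if (length(extra) || length(missing)) {
    stop("assignment labels do not match model causes",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  values <- values[labels]
  mx <- cause_max_values(model)
  bad <- which(values < 0 | values > mx + 1e-12)
  if (length(bad)) {
    stop(sprintf("assignment value out of range for cause '%s': %g not in [0, %g]",
                 labels[bad[1]], values[bad[1]], mx[bad[1]]), call. = FALSE)
  }
  values
}

#' Number of free parameters of a binary causal model
#'
#' For a model whose causes and effect are all binary, compares the cost of
#' the capacity representation (one strength per cause, `n` parameters) with
#' the unrestricted conditional distribution over the `2^n` parent
#' configurations.
#'
#' @param model A `capacity_model`.
#' @param representation `"capacity"` (one weight per cause) or
#'   `"unrestricted"` (full conditional table).
#' @return Integer parameter count. An empty model has 0 capacity parameters
#'   and 1 unrestricted parameter (the single marginal).
#' @export
parameter_count <- function(model,
                            representation = c("capacity", "unrestricted")) {
  representation <- match.arg(representation)
  n <- length(model$causes)
  if (representation == "capacity") return(n)
  if (n > 0 && any(cause_max_values(model) != 1)) {
    stop("unrestricted parameter count is defined only for all-binary models",
         call. = FALSE)
  }
  as.integer(2^n)
}
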