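#' Reduction report
#'
#' Result container for the special-case verifiers: the named reduction, a
#' one-line model summary, the maximum absolute discrepancy between the full
#' bounded expected-effect equation and the special-case form over the
#' tested assignments, and a pass flag at the stated tolerance.
#'
#' @keywords internal
reduction_report <- function(case, model_summary, discrepancies, tolerance,
                             detail = NULL) {
  max_d <- if (length(discrepancies)) max(abs(discrepancies)) else 0
  structure(list(case = case, model_summary = model_summary,
                 max_discrepancy = max_d,
                 n_assignments = length(discrepancies),
                 tolerance = tolerance,
                 pass = max_d <= tolerance,
                 detail = detail),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("Reduction check [%s]: %s\n", x$case, x$model_summary))
  cat(sprintf("  max |discrepancy| = %.3g over %d assignment(s); tol %.3g -> %s\n",
              x$max_discrepancy, x$n_assignments, x$tolerance,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

model_summary_line <- function(model) {
  roles <- cause_roles(model)
  sprintf("[%s, %s]; %dG/%dR/%dB",
          format(-model$range$lower), format(model$range$upper),
          sum(roles == "generator"), sum(roles == "reducer"),
          sum(roles == "blocker"))
}

binary_assignments <- function(labels) {
  g <- do.call(expand.grid, stats::setNames(rep(list(c(0, 1)), length(labels)),
                                            labels))
  as.data.frame(g)
}

#' Verify the binary noisy-OR/AND reduction
#'
#' For an all-binary model on `[0, 1]` (no reducers), the bounded
#' expected-effect equation and the noisy-OR/AND probability are the same
#' function: generators fill the noisy-OR bracket and blockers the noisy-AND
#' pass-through. This verifier evaluates both sides over binary assignments
#' — exhaustively for up to `max_exhaustive` causes, by seeded sampling
#' beyond — and reports the maximum discrepancy, which should sit at
#' machine-rounding level.
#'
#' @param model A `capacity_model` with `lower = 0`, `upper = 1`, all
#'   `max_value = 1`, and no reducers.
#' @param n_assignments Number of sampled assignments when the exhaustive
#'   enumeration is too large (ignored otherwise).
#' @param seed Seed for the sampled case.
#' @param tolerance Pass tolerance on the maximum absolute discrepancy.
#' @param max_exhaustive Enumerate exhaustively up to `2^max_exhaustive`
#'   assignments.
#' @return A `reduction_report`.
#' @export
verify_binary_reduction <- function(model, n_assignments = 1000, seed = 1,
                                    tolerance = 1e-12, max_exhaustive = 10) {
  stopifnot(inherits(model, "capacity_model"))
  roles <- cause_roles(model)
  if (model$range$lower != 0 || model$range$upper != 1 ||
      any(cause_max_values(model) != 1) || any(roles == "reducer")) {
    stop("binary reduction requires lower = 0, upper = 1, binary causes, ",
         "and no reducers", call. = FALSE)
  }
  labels <- cause_labels(model)
  n <- length(labels)
  if (n <= max_exhaustive) {
    asg <- binary_assignments(labels)
  } else {
    set.seed(seed)
    asg <- as.data.frame(matrix(stats::rbinom(n_assignments * n, 1, 0.5),
                                ncol = n, dimnames = list(NULL, labels)))
  }
  w <- cause_strengths(model)
  gen <- roles == "generator"
  blk <- roles == "blocker"
  lhs <- evaluate_model(model, asg)
  rhs <- vapply(seq_len(nrow(asg)), function(r) {
    noisy_or_and(w[gen], as.numeric(asg[r, gen, drop = TRUE]),
                 w[blk], as.numeric(asg[r, blk, drop = TRUE]))
  }, numeric(1))
  reduction_report("noisy-or-and", model_summary_line(model),
                   lhs - rhs, tolerance)
}

# Rebuild a finite-bound model with new bound magnitudes, keeping causes.
rebound_model <- function(model, lower, upper) {
  capacity_model(effect_range(lower, upper), unname(model$causes))
}

#' Verify convergence to the linear form as bounds grow
#'
#' With no blockers and fixed contributions `w_i g_i`, `w_j r_j`, the
#' bounded expectation approaches the linear form
#' `sum(w_i g_i) - sum(w_j r_j)` as both bound magnitudes grow: the
#' normalized products linearize, leaving only cross-terms of order
#' `1/min(U, L)`. The verifier evaluates the discrepancy along a sequence of
#' bound magnitudes, checks that it decreases monotonically in `min(U, L)`,
#' and fits the constant `C` in the `C/min(U, L)` envelope.
#'
#' @param model A `capacity_model` with generators and/or reducers only; its
#'   bounds are replaced by each tested pair. Cause strengths and the
#'   assignment fix the contributions.
#' @param values Named assignment of cause values.
#' @param U_values,L_values Increasing sequences of finite bound magnitudes
#'   (recycled to a common length). `L_values` is ignored (kept at its first
#'   value or 0) when the model has no reducers.
#' @param tolerance Pass tolerance for the discrepancy at the largest
#'   bounds.
#' @return A `reduction_report`; `detail` holds the per-bound discrepancy
#'   table and fitted envelope constant.
#' @export
verify_linear_limit <- function(model, values,
                                U_values = c(10, 100, 1000, 10000),
                                L_values = c(10, 100, 1000, 10000),
                                tolerance = 1e-3) {
  stopifnot(inherits(model, "capacity_model"))
  roles <- cause_roles(model)
  if (any(roles == "blocker")) {
    stop("linear-limit verification requires a model without blockers; ",
         "use verify_blocked_linear_limit", call. = FALSE)
  }
  has_red <- any(roles == "reducer")
  k <- max(length(U_values), length(L_values))
  U_values <- rep_len(U_values, k)
  L_values <- rep_len(L_values, k)
  w <- cause_strengths(model)
  values <- values[cause_labels(model)]
  contrib <- w * values
  linear <- sum(contrib[roles == "generator"]) - sum(contrib[roles == "reducer"])

  disc <- numeric(k)
  for (i in seq_len(k)) {
    m_i <- rebound_model(model, if (has_red) L_values[i] else 0, U_values[i])
    disc[i] <- abs(expected_effect(m_i, values) - linear)
  }
  minb <- if (has_red) pmin(U_values, L_values) else U_values
  monotone <- all(diff(disc[order(minb)]) <= 1e-15)
  C <- max(disc * minb)
  envelope_ok <- all(disc <= C / minb + 1e-15)
  rep <- reduction_report(
    "linear-limit", model_summary_line(model), disc[k], tolerance,
    detail = list(bounds = data.frame(U = U_values, L = if (has_red) L_values else 0,
                                      discrepancy = disc),
                  linear_value = linear, monotone = monotone,
                  envelope_constant = C, envelope_ok = envelope_ok))
  rep$pass <- rep$pass && monotone && envelope_ok
  rep
}

#' Verify convergence to the noisy-addition model
#'
#' For binary generators only, as the upper bound grows the bounded
#' expectation converges to the sum of the active strengths (the
#' noisy-addition model). Exact equality holds at every `U` for a single
#' active cause, since there are no cross-terms.
#'
#' @param model A `capacity_model` whose causes are all binary generators.
#' @param U_values Increasing finite upper bounds to test.
#' @param tolerance Pass tolerance at the largest `U`.
#' @return A `reduction_report` over all binary assignments at each `U`.
#' @export
verify_noisy_addition_limit <- function(model,
                                        U_values = c(10, 100, 1000, 10000),
                                        tolerance = 1e-3) {
  stopifnot(inherits(model, "capacity_model"))
  roles <- cause_roles(model)
  if (any(roles != "generator") || any(cause_max_values(model) != 1)) {
    stop("noisy-addition verification requires all-binary generators only",
         call. = FALSE)
  }
  labels <- cause_labels(model)
  w <- cause_strengths(model)
  asg <- binary_assignments(labels)
  target <- apply(asg, 1, function(r) noisy_addition(w, as.numeric(r)))
  disc_by_U <- vapply(U_values, function(U) {
    m_U <- rebound_model(model, 0, U)
    max(abs(evaluate_model(m_U, asg) - target))
  }, numeric(1))
  rep <- reduction_report(
    "noisy-addition-limit", model_summary_line(model),
    disc_by_U[length(U_values)] , tolerance,
    detail = list(bounds = data.frame(U = U_values, discrepancy = disc_by_U),
                  monotone = all(diff(disc_by_U) <= 1e-15)))
  rep$n_assignments <- nrow(asg)
  rep$pass <- rep$pass && rep$detail$monotone
  rep
}

#' Verify convergence to the blocked linear form
#'
#' With generators, reducers, and blockers all present, growing both bound
#' magnitudes sends the bounded expectation to the blocked linear form: the
#' blocker pass-through times the difference of summed contributions,
#' `prod(1 - w_k b_k) * (sum(w_i g_i) - sum(w_j r_j))`. The blocker factor
#' does not depend on the bounds, so convergence is inherited from the
#' generator/reducer bracket.
#'
#' @param model A `capacity_model`; all three roles allowed.
#' @param values Named assignment of cause values.
#' @param U_values,L_values Increasing finite bound magnitudes.
#' @param tolerance Pass tolerance at the largest bounds.
#' @return A `reduction_report`.
#' @export
verify_blocked_linear_limit <- function(model, values,
                                        U_values = c(10, 100, 1000, 10000),
                                        L_values = c(10, 100, 1000, 10000),
                                        tolerance = 1e-3) {
  stopifnot(inherits(model, "capacity_model"))
  roles <- cause_roles(model)
  k <- max(length(U_values), length(L_values))
  U_values <- rep_len(U_values, k)
  L_values <- rep_len(L_values, k)
  w <- cause_strengths(model)
  values <- values[cause_labels(model)]
  contrib <- w * values
  pass_through <- blocking_passthrough(w[roles == "blocker"],
                                       values[roles == "blocker"])
  limit <- pass_through * (sum(contrib[roles == "generator"]) -
                             sum(contrib[roles == "reducer"]))
  has_red <- any(roles == "reducer")
  disc <- numeric(k)
  for (i in seq_len(k)) {
    m_i <- rebound_model(model, if (has_red) L_values[i] else 0, U_values[i])
    disc[i] <- abs(expected_effect(m_i, values) - limit)
  }
  minb <- if (has_red) pmin(U_values, L_values) else U_values
  reduction_report(
    "blocked-linear-limit", model_summary_line(model), disc[k], tolerance,
    detail = list(bounds = data.frame(U = U_values,
                                      L = if (has_red) L_values else 0,
                                      discrepancy = disc),
                  limit_value = limit,
                  monotone = all(diff(disc[order(minb)]) <= 1e-15)))
}

#' Run all special-case reduction checks
#'
#' Convenience driver used by the command-line interface: builds
#' representative models for each named reduction and returns the list of
#' reports.
#'
#' @param seed Seed for the sampled parts.
#' @return Named list of `reduction_report` objects.
#' @export
verify_all_reductions <- function(seed = 1) {
  set.seed(seed)
  m_bin <- capacity_model(
    effect_range(0, 1),
    list(cause("g1", "generator", 0.2), cause("g2", "generator", 0.5),
         cause("g3", "generator", 0.9),
         cause("b1", "blocker", 0.3), cause("b2", "blocker", 0.7)))
  m_lin <- capacity_model(
    effect_range(10, 10),
    list(cause("g1", "generator", 0.5), cause("g2", "generator", 0.5),
         cause("r1", "reducer", 0.25, max_value = 2)))
  m_add <- capacity_model(
    effect_range(0, 10),
    list(cause("g1", "generator", 0.3), cause("g2", "generator", 0.8)))
  m_blk <- capacity_model(
    effect_range(10, 10),
    list(cause("g1", "generator", 0.6), cause("g2", "generator", 0.5),
         cause("r1", "reducer", 0.5),
         cause("b1", "blocker", 0.5), cause("b2", "blocker", 0.5)))
  list(
    `noisy-or-and` = verify_binary_reduction(m_bin, seed = seed),
    `linear` = verify_linear_limit(m_lin, c(g1 = 1, g2 = 1, r1 = 2)),
    `noisy-addition` = verify_noisy_addition_limit(m_add),
    `blocked-linear` = verify_blocked_linear_limit(
      m_blk, c(g1 = 1, g2 = 1, r1 = 1, b1 = 1, b2 = 1))
  )
}
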