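#' Observation-noise specification
#'
#' The capacity model specifies only the conditional expectation of the
#' effect; to simulate trials an observation-noise family with that mean
#' must be chosen. Three families are supported, each with support matching
#' a class of effect ranges:
#' \describe{
#'   \item{`bernoulli`}{Binary effect on `[0, 1]` (`lower = 0`,
#'     `upper = 1`); the expectation is the success probability.
#'     `dispersion` is ignored.}
#'   \item{`scaled-beta`}{Continuous effect on a finite `[-L, U]`; a Beta
#'     distribution re-parametrized by mean and precision, scaled to the
#'     effect range, so observations respect the bounds by construction.
#'     `dispersion` is the Beta precision (alpha + beta); larger is less
#'     noisy.}
#'   \item{`gaussian`}{Unbounded effect (the linear regime); additive
#'     Gaussian noise with standard deviation `dispersion`.}
#' }
#'
#' @param family One of `"bernoulli"`, `"scaled-beta"`, `"gaussian"`.
#' @param dispersion Positive dispersion (Beta precision or Gaussian sd).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("bernoulli", "scaled-beta", "gaussian"),
                       dispersion = 10) {
  family <- match.arg(family)
  stopifnot(is.numeric(dispersion), length(dispersion) == 1L, dispersion > 0)
  structure(list(family = family, dispersion = dispersion),
            class = "noise_spec")
}

check_noise_compat <- function(model, noise) {
  L <- model$range$lower
  U <- model$range$upper
  switch(noise$family,
    bernoulli = {
      if (L != 0 || U != 1) {
        stop("bernoulli noise requires an effect range of [0, 1]", call. = FALSE)
      }
    },
    `scaled-beta` = {
      if (!is.finite(L) || !is.finite(U)) {
        stop("scaled-beta noise requires finite bounds", call. = FALSE)
      }
    },
    gaussian = {
      if (is.finite(L) && is.finite(U)) {
        stop("gaussian noise is reserved for the unbounded linear regime",
             call. = FALSE)
      }
    })
  invisible(NULL)
}

#' Trial-design samplers
#'
#' A design is a function `function(n, model)` returning a data frame of `n`
#' valid cause assignments (columns = cause labels). `design_bernoulli()`
#' sets each cause independently to its `max_value` with probability `p`
#' (and 0 otherwise) — the standard presence/absence design of
#' causal-learning experiments; causes named in `always_on` are clamped to
#' `max_value` in every trial, the explicit representation of an
#' always-present background cause. `design_uniform()` draws each cause
#' value uniformly on `[0, max_value]`.
#'
#' @param p Presence probability per cause.
#' @param always_on Character vector of cause labels held at `max_value`.
#' @return A design function.
#' @export
design_bernoulli <- function(p = 0.5, always_on = character(0)) {
  force(p); force(always_on)
  function(n, model) {
    labels <- cause_labels(model)
    mx <- cause_max_values(model)
    out <- vapply(seq_along(labels), function(j) {
      if (labels[j] %in% always_on) rep(mx[j], n)
      else mx[j] * stats::rbinom(n, 1, p)
    }, numeric(n))
    as.data.frame(matrix(out, nrow = n, dimnames = list(NULL, labels)))
  }
}

#' @rdname design_bernoulli
#' @export
design_uniform <- function() {
  function(n, model) {
    labels <- cause_labels(model)
    mx <- cause_max_values(model)
    out <- vapply(seq_along(labels), function(j) stats::runif(n, 0, mx[j]),
                  numeric(n))
    as.data.frame(matrix(out, nrow = n, dimnames = list(NULL, labels)))
  }
}

# Draw one observation per mean under the noise family. Means exactly at a
# Beta support endpoint are clamped 1e-9 into the interior: the Beta
# parametrization is degenerate there, and the clamp is below every test
# tolerance.
draw_effects <- function(mu, model, noise) {
  n <- length(mu)
  switch(noise$family,
    bernoulli = stats::rbinom(n, 1, pmin(pmax(mu, 0), 1)),
    `scaled-beta` = {
      L <- model$range$lower; U <- model$range$upper
      m <- (mu + L) / (U + L)
      m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
      phi <- noise$dispersion
      stats::rbeta(n, m * phi, (1 - m) * phi) * (U + L) - L
    },
    gaussian = mu + stats::rnorm(n, 0, noise$dispersion))
}

#' Simulate trial data from a capacity model
#'
#' Draws `n` cause assignments from the design, computes each row's expected
#' effect under the model, and draws one observed effect per row from the
#' noise family with that conditional mean. Identical seeds reproduce
#' identical tables.
#'
#' @param model A `capacity_model` (finite bounds, or infinite bounds with
#'   gaussian noise, in which case the linear form is the mean).
#' @param noise A [noise_spec()] compatible with the model's bounds.
#' @param design A design function (see [design_bernoulli()]) or a data
#'   frame of assignments to use as-is (its rows are recycled to `n`).
#' @param n Number of trials.
#' @param seed Integer seed recorded in the table's metadata.
#' @param regime Optional value-range regime tag (`"binary"`,
#'   `"narrow-continuous"`, `"wide-continuous"`) stored as an attribute.
#' @return A `trial_table`: a data frame with one column per cause plus
#'   `effect`, and attributes `model`, `seed`, `noise`, `regime`.
#' @examples
#' m <- capacity_model(effect_range(0, 1), cause("c", "generator", 0.5))
#' head(simulate_trials(m, noise_spec("bernoulli"), design_bernoulli(1), 5, seed = 1))
#' @export
simulate_trials <- function(model, noise, design = design_bernoulli(),
                            n, seed, regime = NULL) {
  stopifnot(inherits(model, "capacity_model"), inherits(noise, "noise_spec"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  check_noise_compat(model, noise)
  set.seed(seed)
  if (is.data.frame(design)) {
    asg <- design[rep_len(seq_len(nrow(design)), n), , drop = FALSE]
    rownames(asg) <- NULL
  } else {
    asg <- design(n, model)
  }
  mu <- evaluate_model(model, asg)
  asg$effect <- draw_effects(mu, model, noise)
  structure(asg, model = model, seed = seed, noise = noise, regime = regime,
            class = c("trial_table", "data.frame"))
}

#' Generate cause-value sequences under the three value-range regimes
#'
#' Emulates how the same functional information can be numerically framed
#' so as to suggest different variable types: a given binary on/off pattern
#' is rendered as exact `{0, 1}` values (`binary`), as values tightly
#' jittered around 0 and 1 (`narrow-continuous`, e.g.
#' `0.01, -0.02, 1.05, 0.03`), or as near-zero "off" values against widely
#' spread "on" values (`wide-continuous`, e.g. `0.03, 0.07, 17.32, -0.01` —
#' still only two functionally distinct levels). Sequences generated from
#' the same pattern carry the same information: thresholding at half the
#' functional gap recovers the pattern in every regime.
#'
#' @param regime `"binary"`, `"narrow-continuous"`, or `"wide-continuous"`.
#' @param n Sequence length.
#' @param seed Integer seed.
#' @param pattern Optional logical/0-1 vector of length `n` giving the
#'   on/off pattern; by default drawn with on-probability `p_on`.
#' @param p_on Probability of "on" when `pattern` is not supplied.
#' @return Numeric vector of length `n` with attributes `pattern` (the 0/1
#'   pattern), `regime`, and `functional_gap` (the lo/hi level separation).
#' @export
generate_value_sequences <- function(regime = c("binary", "narrow-continuous",
                                                "wide-continuous"),
                                     n, seed, pattern = NULL, p_on = 0.25) {
  regime <- match.arg(regime)
  set.seed(seed)
  if (is.null(pattern)) {
    pattern <- stats::rbinom(n, 1, p_on)
  } else {
    stopifnot(length(pattern) == n, all(pattern %in% c(0, 1)))
    pattern <- as.numeric(pattern)
  }
  out <- switch(regime,
    binary = pattern,
    `narrow-continuous` = pattern + stats::rnorm(n, 0, 0.02),
    `wide-continuous` = {
      hi <- stats::rnorm(n, 15, 2)    # wide "on" level
      lo <- stats::rnorm(n, 0, 0.03)  # near-zero "off" level
      ifelse(pattern == 1, hi, lo)
    })
  gap <- switch(regime, binary = 1, `narrow-continuous` = 1,
                `wide-continuous` = 15)
  structure(out, pattern = pattern, regime = regime, functional_gap = gap)
}

#' 2x2 contingency table of a binary cause and binary effect
#'
#' @param n_ce,n_cn,n_ne,n_nn Nonnegative counts: cause present & effect
#'   present, cause present & effect absent, cause absent & effect present,
#'   cause absent & effect absent.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(n_ce, n_cn, n_ne, n_nn) {
  counts <- c(n_ce = n_ce, n_cn = n_cn, n_ne = n_ne, n_nn = n_nn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "contingency_table")
}

#' Aggregate a binary trial table into a contingency table
#'
#' @param table A `trial_table` (or data frame) with a binary cause column
#'   and binary `effect` column.
#' @param cause_label Name of the cause column.
#' @return A [contingency_table()].
#' @export
as_contingency_table <- function(table, cause_label) {
  c_val <- table[[cause_label]]
  e_val <- table$effect
  if (!all(c_val %in% c(0, 1)) || !all(e_val %in% c(0, 1))) {
    stop("contingency aggregation requires binary cause and effect columns",
         call. = FALSE)
  }
  contingency_table(sum(c_val == 1 & e_val == 1), sum(c_val == 1 & e_val == 0),
                    sum(c_val == 0 & e_val == 1), sum(c_val == 0 & e_val == 0))
}

ct_rates <- function(ct) {
  n_c <- ct$n_ce + ct$n_cn
  n_n <- ct$n_ne + ct$n_nn
  if (n_c == 0 || n_n == 0) {
    stop("contingency table needs at least one cause-present and one ",
         "cause-absent observation", call. = FALSE)
  }
  list(p_e_c = ct$n_ce / n_c, p_e_nc = ct$n_ne / n_n)
}

#' Delta-P contingency estimator
#'
#' The linear model's single-cause judgment:
#' \eqn{\Delta P = P(e \mid c) - P(e \mid \neg c)}.
#'
#' @param ct A [contingency_table()].
#' @return A number in `[-1, 1]`.
#' @examples
#' delta_p(contingency_table(80, 20, 20, 80)) # 0.6
#' @export
delta_p <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  r <- ct_rates(ct)
  r$p_e_c - r$p_e_nc
}

#' Generative causal-power estimator
#'
#' The noisy-OR/AND single-cause strength estimate,
#' \eqn{w = \Delta P / (1 - P(e \mid \neg c))}: the maximum-likelihood
#' solution for the cause's strength in a two-cause noisy-OR model with an
#' always-present background generator. Only the generative case
#' (\eqn{\Delta P \ge 0}) is in scope; a negative contingency is rejected as
#' preventive.
#'
#' @param ct A [contingency_table()] with `P(e | not c) < 1` and
#'   nonnegative delta-P.
#' @return A number in `[0, 1]`.
#' @examples
#' causal_power(contingency_table(80, 20, 20, 80)) # 0.75
#' @export
causal_power <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  r <- ct_rates(ct)
  if (r$p_e_nc >= 1) {
    stop("causal power is undefined when the background rate is 1", call. = FALSE)
  }
  dp <- r$p_e_c - r$p_e_nc
  if (dp < 0) {
    stop("negative contingency: preventive case is outside the generative ",
         "power estimator's scope", call. = FALSE)
  }
  dp / (1 - r$p_e_nc)
}

#' Point judgment predicted under an assumed functional form
#'
#' Returns the single-cause strength judgment a reasoner would produce from
#' a 2x2 contingency table under each assumed functional form: the causal
#' power for the noisy-OR/AND form, delta-P for the linear form. The two
#' agree exactly when (and only when) the background rate
#' `P(e | not c)` is 0.
#'
#' @param ct A [contingency_table()].
#' @param assumed_form `"noisy-or-and"` or `"linear"`.
#' @return A number.
#' @export
predicted_judgment <- function(ct, assumed_form = c("noisy-or-and", "linear")) {
  assumed_form <- match.arg(assumed_form)
  if (assumed_form == "noisy-or-and") causal_power(ct) else delta_p(ct)
}
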