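# Independent brute-force oracles used to derive expected values. These stay
# deliberately naive (exhaustive enumeration, direct arithmetic) and never
# call the code paths they check.

# P(at least one cause fires) by exhaustive enumeration of the independent
# activation outcomes of each present cause.
or_enumerate <- function(strengths, indicators) {
  p_fire <- strengths * indicators
  n <- length(p_fire)
  if (n == 0L) return(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    a <- as.integer(intToBits(mask)[1:n])
    pr <- prod(ifelse(a == 1, p_fire, 1 - p_fire))
    if (any(a == 1)) total <- total + pr
  }
  total
}

# Noisy-OR/AND by enumeration: effect occurs iff some generator fires and no
# preventer fires.
or_and_enumerate <- function(gw, gi, pw, pi) {
  or_enumerate(gw, gi) * prod(1 - pw * pi)
}

# Random valid finite-bound model for property tests.
random_model <- function(n_causes, L = NULL, U = NULL) {
  if (is.null(U)) U <- runif(1, 0.5, 5)
  if (is.null(L)) L <- sample(c(0, runif(1, 0.5, 5)), 1)
  roles <- sample(c("generator", "reducer", "blocker"), n_causes,
                  replace = TRUE)
  if (L == 0) roles[roles == "reducer"] <- "generator"
  causes <- lapply(seq_len(n_causes), function(j) {
    M <- runif(1, 0.5, 2)
    bound <- switch(roles[j], generator = U, reducer = L, blocker = 1)
    cause(paste0("c", j), roles[j], runif(1, 0, bound / M), M)
  })
  capacity_model(effect_range(L, U), causes)
}

random_assignment <- function(model) {
  mx <- vapply(model$causes, `[[`, numeric(1), "max_value")
  stats::setNames(runif(length(mx), 0, mx), names(model$causes))
}

binary_generator_model <- function(strengths, labels = NULL) {
  if (is.null(labels)) labels <- paste0("g", seq_along(strengths))
  capacity_model(effect_range(0, 1),
                 mapply(cause, labels, "generator", strengths,
                        SIMPLIFY = FALSE))
}
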