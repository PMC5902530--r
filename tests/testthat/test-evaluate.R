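test_that("noisy_or matches the exhaustive activation-enumeration oracle", {
  # frozen oracle values: or_enumerate(c(0.5, 0.5), c(1, 1)) == 0.75,
  # or_enumerate(c(0.2, 0.5, 0.9), c(1, 0, 1)) == 0.92
  expect_equal(noisy_or(c(0.5, 0.5), c(1, 1)), 0.75)
  expect_equal(noisy_or(c(0.2, 0.5, 0.9), c(1, 0, 1)), 0.92)
  expect_equal(noisy_or(c(0.2, 0.5, 0.9), c(0, 0, 0)), 0)
  expect_equal(noisy_or(0.37, 1), 0.37)  # single present cause returns w
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    w <- runif(n)
    d <- rbinom(n, 1, 0.5)
    expect_equal(noisy_or(w, d), or_enumerate(w, d), tolerance = 1e-12)
    perm <- sample(n)
    expect_identical(noisy_or(w[perm], d[perm]), noisy_or(w, d))
  }
  expect_error(noisy_or(c(0.5), c(1, 0)), "equal length")
  expect_error(noisy_or(1.2, 1), "\\[0, 1\\]")
})

test_that("noisy_or_and gates the generative bracket by the preventers", {
  expect_equal(noisy_or_and(c(0.5, 0.5), c(1, 1)), 0.75)
  expect_equal(noisy_or_and(0.8, 1, 1.0, 1), 0)   # sure preventer
  # all generators absent: effect stays at baseline regardless of preventers
  for (p1 in 0:1) for (p2 in 0:1) {
    expect_identical(noisy_or_and(c(0.2, 0.5, 0.9), c(0, 0, 0),
                                  c(0.3, 0.7), c(p1, p2)), 0)
  }
  set.seed(43)
  for (i in 1:20) {
    gw <- runif(3); gi <- rbinom(3, 1, 0.5)
    pw <- runif(2); pi_ <- rbinom(2, 1, 0.5)
    expect_equal(noisy_or_and(gw, gi, pw, pi_),
                 or_and_enumerate(gw, gi, pw, pi_), tolerance = 1e-12)
  }
})

test_that("noisy_max and noisy_addition follow their definitions", {
  expect_equal(noisy_max(c(0.3, 0.8), c(1, 1)), 0.8)
  expect_equal(noisy_addition(c(0.3, 0.8), c(1, 1)), 1.1)
  expect_equal(noisy_max(c(0.3, 0.8), c(0, 0)), 0)
  expect_equal(noisy_addition(c(0.3, 0.8), c(0, 0)), 0)
  expect_equal(noisy_max(c(0.3, 0.8), c(0, 1)), 0.8)
  expect_equal(noisy_addition(c(0.3, 0.8), c(0, 1)), 0.8)
  expect_error(noisy_max(c(0.3), c(1, 1)), "equal length")
})

test_that("pairwise_combine is the bounded accumulation rule", {
  expect_equal(pairwise_combine(0, 0.4, 1), 0.4)     # identity partner
  expect_equal(pairwise_combine(1, 0.4, 1), 1)       # saturation
  expect_equal(pairwise_combine(0.5, 0.5, 1), 0.75)  # matches noisy-OR
  expect_equal(pairwise_combine(3, 4, 10), 5.8)
  set.seed(44)
  for (i in 1:20) {
    U <- runif(1, 0.5, 10)
    x <- runif(1, 0, U); y <- runif(1, 0, U)
    v <- pairwise_combine(x, y, U)
    expect_identical(v, pairwise_combine(y, x, U))
    expect_true(v >= max(x, y) - 1e-12 && v <= U + 1e-12)
  }
  expect_error(pairwise_combine(2, 0.5, 1), "\\[0, 1\\]")
})

test_that("blocking_passthrough is the independent-events product", {
  expect_equal(blocking_passthrough(numeric(0), numeric(0)), 1)
  expect_equal(blocking_passthrough(1, 1), 0)
  expect_equal(blocking_passthrough(c(0.5, 0.5), c(1, 1)), 0.25)
  expect_error(blocking_passthrough(2, 1), "\\[0, 1\\]")
})

test_that("expected_effect reproduces its closed-form anchor cases", {
  m <- capacity_model(
    effect_range(2, 10),
    list(cause("g1", "generator", 2, 3), cause("g2", "generator", 1, 5),
         cause("r1", "reducer", 0.5, 4),
         cause("b1", "blocker", 0.5, 1)))
  zero <- c(g1 = 0, g2 = 0, r1 = 0, b1 = 0)
  expect_equal(expected_effect(m, zero), 0)  # no uncaused effects
  # single active generator: w * g
  expect_equal(expected_effect(m, c(g1 = 1.5, g2 = 0, r1 = 0, b1 = 0)), 3)
  # single active reducer: -w * r
  expect_equal(expected_effect(m, c(g1 = 0, g2 = 0, r1 = 2, b1 = 0)), -1)
  # full hand-derived value: pass = 0.5; up = 10(1 - (10-6)/10 * (10-5)/10) = 8;
  # down = 2(1 - (2-1)/2) = 1; 0.5 * (8 - 1) = 3.5
  expect_equal(expected_effect(m, c(g1 = 3, g2 = 5, r1 = 2, b1 = 1)), 3.5)
  # an active sure blocker annihilates everything
  m2 <- capacity_model(
    effect_range(0, 1),
    list(cause("g", "generator", 0.9), cause("b", "blocker", 1)))
  expect_equal(expected_effect(m2, c(g = 1, b = 1)), 0)
  expect_error(
    expected_effect(capacity_model(effect_range(Inf, Inf), list()),
                    stats::setNames(numeric(0), character(0))),
    "finite bounds")
})

test_that("expected_effect stays in bounds and ignores cause order", {
  set.seed(45)
  for (i in 1:60) {
    m <- random_model(sample(1:6, 1))
    a <- random_assignment(m)
    v <- expected_effect(m, a)
    expect_true(v >= -m$range$lower - 1e-9 && v <= m$range$upper + 1e-9)
    perm <- sample(length(m$causes))
    m_perm <- capacity_model(m$range, unname(m$causes)[perm])
    expect_identical(expected_effect(m_perm, a), v)
  }
})

test_that("expected_effect is monotone in each capacity's value", {
  set.seed(46)
  for (i in 1:25) {
    m <- random_model(sample(2:5, 1))
    a <- random_assignment(m)
    v0 <- expected_effect(m, a)
    for (lab in names(m$causes)) {
      cs <- m$causes[[lab]]
      a2 <- a
      a2[lab] <- min(cs$max_value, a[lab] + 0.25 * cs$max_value)
      v1 <- expected_effect(m, a2)
      if (cs$role == "generator") expect_gte(v1, v0 - 1e-9)
      if (cs$role == "reducer") expect_lte(v1, v0 + 1e-9)
      if (cs$role == "blocker") expect_lte(abs(v1), abs(v0) + 1e-9)
    }
  }
})

test_that("generator accumulation equals repeated pairwise combination", {
  set.seed(47)
  for (i in 1:25) {
    U <- runif(1, 0.5, 5)
    n <- sample(2:6, 1)
    w <- runif(n, 0, U)
    m <- capacity_model(
      effect_range(0, U),
      lapply(seq_len(n), function(j) cause(paste0("g", j), "generator", w[j])))
    a <- stats::setNames(rbinom(n, 1, 0.7), paste0("g", seq_len(n)))
    v <- expected_effect(m, a)
    # fold the contributions pairwise in a random association order
    contrib <- sample(w * a)
    folded <- Reduce(function(x, y) pairwise_combine(x, y, U), contrib, 0)
    expect_equal(v, folded, tolerance = 1e-12)
  }
})

test_that("binary models coincide with noisy_or_and to machine precision", {
  set.seed(48)
  for (i in 1:25) {
    n_g <- sample(1:4, 1); n_b <- sample(0:3, 1)
    gw <- runif(n_g); bw <- runif(n_b)
    causes <- c(
      lapply(seq_len(n_g), function(j) cause(paste0("g", j), "generator", gw[j])),
      lapply(seq_len(n_b), function(j) cause(paste0("b", j), "blocker", bw[j])))
    m <- capacity_model(effect_range(0, 1), causes)
    gi <- rbinom(n_g, 1, 0.5); bi <- rbinom(n_b, 1, 0.5)
    a <- stats::setNames(c(gi, bi), names(m$causes))
    expect_equal(expected_effect(m, a), noisy_or_and(gw, gi, bw, bi),
                 tolerance = 1e-15)
  }
})

test_that("linear_expected_effect implements the blocked linear form", {
  m <- capacity_model(
    effect_range(Inf, Inf),
    list(cause("g1", "generator", 1, Inf), cause("g2", "generator", 0.5, Inf),
         cause("r1", "reducer", 0.25, Inf), cause("b1", "blocker", 0.5)))
  expect_equal(
    linear_expected_effect(m, c(g1 = 0, g2 = 0, r1 = 0, b1 = 0)), 0)
  expect_equal(
    linear_expected_effect(m, c(g1 = 1, g2 = 2, r1 = 2, b1 = 0)), 1.5)
  expect_equal(
    linear_expected_effect(m, c(g1 = 1, g2 = 2, r1 = 2, b1 = 1)), 0.75)
  # signed contributions are legitimate in the unbounded regime
  expect_equal(
    linear_expected_effect(m, c(g1 = -2, g2 = 0, r1 = 0, b1 = 0)), -2)
  m_fin <- binary_generator_model(0.5)
  expect_error(linear_expected_effect(m_fin, c(g1 = 1)), "infinite upper")
})

test_that("evaluate_model vectorizes expected_effect row-for-row", {
  set.seed(49)
  m <- random_model(4)
  asg <- as.data.frame(lapply(stats::setNames(
    vapply(m$causes, `[[`, numeric(1), "max_value"), names(m$causes)),
    function(mx) runif(8, 0, mx)))
  v <- evaluate_model(m, asg)
  for (r in seq_len(nrow(asg))) {
    expect_equal(v[r], expected_effect(m, unlist(asg[r, ])), tolerance = 1e-12)
  }
  expect_error(evaluate_model(m, asg[, -1, drop = FALSE]), "missing cause")
})

test_that("interpretation equivalence: strength is the expected single-cause change", {
  # In an all-binary model the Monte-Carlo expected change in the effect
  # from activating one cause alone equals its strength.
  m <- binary_generator_model(c(0.35, 0.8))
  set.seed(50)
  n <- 1e5
  eff_on <- rbinom(n, 1, expected_effect(m, c(g1 = 1, g2 = 0)))
  eff_off <- rbinom(n, 1, expected_effect(m, c(g1 = 0, g2 = 0)))
  change <- mean(eff_on) - mean(eff_off)
  se <- sqrt(0.35 * 0.65 / n) * 2
  expect_lt(abs(change - 0.35), 4 * se + 1e-3)
})

test_that("linearize_cause rescales monotonically and round-trips", {
  expect_equal(linearize_cause(c(0, 1, 2), identity), c(0, 1, 2))
  expect_equal(linearize_cause(c(0, 1, 4, 9), sqrt), c(0, 1, 2, 3))
  set.seed(51)
  v <- runif(20, 0, 5)
  out <- linearize_cause(v, function(x) x^2)
  expect_equal(linearize_cause(out, sqrt), v, tolerance = 1e-9)
  expect_error(linearize_cause(c(0, 1), function(x) x + 1), "0 to 0")
  expect_error(linearize_cause(c(0, 1, 2), function(x) sin(3 * x)),
               "monotone")
})
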