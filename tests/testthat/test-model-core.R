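test_that("mutualist-only states reduce to logistic growth and dead states stay dead", {
  p <- mest_params()
  s <- mest_state(1, 0, 0, 0, theta = c(0.5, 0.25))
  dy <- mest_rhs(s, p)
  expect_equal(unname(dy["F0"]), 1 * (p$r0 - p$alpha0 - p$d0))
  expect_equal(unname(dy[c("F1", "C", "P")]), c(0, 0, 0))
  # the replicator still moves: the F0 gradient w0 = eP*u0*F0 is positive
  w0 <- p$eP * p$u0 * 1
  wbar <- 0.5 * w0
  expect_equal(unname(dy["theta0"]), p$g * 0.5 * (w0 - wbar))

  z <- mest_state(0, 0, 0, 0, theta = c(0.5, 0.5))
  expect_true(all(mest_rhs(z, p) == 0))
})

test_that("vector field matches the term-by-term oracle on 1000 random states", {
  set.seed(11)
  for (rep in 1:1000) {
    n <- sample(1:4, 1)
    p <- mest_params(n = n, ri = runif(n, 0.3, 0.4), ui = runif(n, 0.05, 0.3),
                     beta = runif(1, 0, 0.18), g = runif(1, 0.05, 0.5))
    s <- random_state(n)
    expect_lt(max(abs(as.numeric(mest_rhs(s, p)) - rhs_oracle(s, p))), 1e-12)
  }
})

test_that("hand-evaluated field at a reference four-species state is reproduced", {
  p <- mest_params()  # r1=0.35, u1=0.15, beta=0.18, g=0.28
  s <- mest_state(1.2, 0.6, 0.8, 0.9, theta = c(0.3, 0.5))
  dy <- as.numeric(mest_rhs(s, p))
  # frozen values from independent term-by-term arithmetic
  expect_equal(dy, c(-0.00444, -0.01635, 0.0464, -0.02106,
                     0.0012936, -0.003724), tolerance = 1e-9)
})

test_that("predator fitness matches its definition and the dP/dt identity", {
  p <- mest_params()
  z <- mest_state(0, 0, 0, 0, theta = c(0.5, 0.25))
  expect_equal(predator_fitness(z, p), -p$dP)
  expect_equal(-p$dP, -0.05)

  s <- mest_state(1, 0, 0, 0, theta = c(1, 0))
  expect_equal(predator_fitness(s, p), 0.11 - 0.05)

  set.seed(5)
  for (i in 1:100) {
    s <- random_state(1)
    dy <- mest_rhs(s, p)
    expect_equal(unname(dy["P"]), s$P * predator_fitness(s, p),
                 tolerance = 1e-12)
  }
})

test_that("fitness gradients drive the replicator as prescribed", {
  p <- mest_params()
  z <- mest_state(0, 0, 0, 0, theta = c(0.3, 0.3))
  expect_true(all(fitness_gradients(z, p) == 0))

  # equal gradients across all prey freeze every effort
  peq <- mest_params(u0 = 0.1, ui = 0.1, uC = 0.1)
  s <- mest_state(1, 1, 1, 1, theta = c(0.2, 0.3))
  expect_true(all(abs(mest_rhs(s, peq)[c("theta0", "theta1")]) < 1e-15))

  # hand replicator arithmetic: w = (1, 0, 0), theta = (0.5, 0.5), g = 1
  ph <- mest_params(u0 = 1, ui = 0, uC = 0, g = 1)
  sh <- mest_state(1, 1, 1, 0, theta = c(0.5, 0.5))
  w <- fitness_gradients(sh, ph)
  expect_equal(unname(w[c("F0", "F1", "C")]), c(1, 0, 0))
  dy <- mest_rhs(sh, ph)
  expect_equal(unname(dy["theta0"]), 0.25)
  expect_equal(unname(dy["theta1"]), -0.25)
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(1:3, 1)
    p <- mest_params(n = n, ri = runif(n, 0.3, 0.4), ui = runif(n, 0.05, 0.3),
                     beta = runif(1, 0.01, 0.18), g = runif(1, 0.05, 0.5))
    s <- random_state(n)
    J <- mest_jacobian(p, s, scope = "full")
    Jfd <- fd_jacobian(p, mestweb:::pack_state(s))
    denom <- max(1, max(abs(Jfd)))
    expect_lt(max(abs(J - Jfd)) / denom, 1e-6)
  }
})

test_that("ecological scope is the biomass block of the full Jacobian", {
  p <- mest_params(n = 2)
  s <- random_state(2, seed = 3)
  Jf <- mest_jacobian(p, s, "full")
  Je <- mest_jacobian(p, s, "ecological")
  expect_equal(Je, Jf[1:5, 1:5])
})

test_that("g = 0 freezes preferences and q = 0 removes the mutualist dependence", {
  p0 <- mest_params(g = 0)
  s <- random_state(1, seed = 9)
  dy <- mest_rhs(s, p0)
  expect_true(all(dy[c("theta0", "theta1")] == 0))

  # with q = 0 (and no competition) the exploiter growth no longer sees F0
  pq <- mest_params(q = 0, beta = 0)
  s1 <- mest_state(0.5, 0.7, 0.4, 0.3, theta = c(0.2, 0.3))
  s2 <- mest_state(1.9, 0.7, 0.4, 0.3, theta = c(0.2, 0.3))
  expect_equal(unname(mest_rhs(s1, pq)["F1"]), unname(mest_rhs(s2, pq)["F1"]))
  # with q > 0 it does
  pq2 <- mest_params(q = 0.25, beta = 0)
  expect_false(isTRUE(all.equal(unname(mest_rhs(s1, pq2)["F1"]),
                                unname(mest_rhs(s2, pq2)["F1"]))))
})

test_that("contracts reject malformed parameters and states", {
  expect_error(mest_params(n = -1), "single integer")
  expect_error(mest_params(r0 = -0.1), "nonnegative")
  expect_error(mest_params(eC = 1.5), "efficiencies")
  expect_error(mest_params(n = 2, beta = matrix(0.1, 2, 2)), "matrix")
  expect_error(mest_state(1, 1, 1, 1, theta = c(0.7, 0.6)), "simplex")
  expect_error(mest_state(-1, 1, 1, 1, theta = c(0.2, 0.2)), "nonnegative")
  p <- mest_params(n = 2)
  s <- mest_state(1, 1, 1, 1, theta = c(0.2, 0.2))  # n = 1 state
  expect_error(mest_rhs(s, p), "n = 2")
})

test_that("parameters serialize to a flat list and back losslessly", {
  p <- mest_params(n = 3, ri = c(0.31, 0.35, 0.39), beta = 0.12, g = 0.4)
  expect_identical(as_mest_params(as.list(p)), p)
  expect_error(as_mest_params(list(bogus = 1)), "unknown parameter keys")
  expect_error(as_mest_params(list(g = 0.9), strict = TRUE), "study ranges")
})
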