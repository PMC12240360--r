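test_that("integration recovers the mutualist logistic closed form", {
  p <- mest_params()
  s0 <- mest_state(0.1, 0, 0, 0, theta = c(0, 0))
  sim <- mest_simulate(p, s0, T_total = 500, record_dt = 10)
  expect_equal(final_state(sim)$F0, (p$r0 - p$d0) / p$alpha0, tolerance = 1e-6)
})

test_that("extinction faces are invariant and pruning holds components at zero", {
  p <- mest_params(g = 0.28)
  s0 <- mest_state(0.4, 0, 0.3, 0, theta = c(1, 0))  # F1 and P extinct
  sim <- mest_simulate(p, s0, T_total = 200, record_dt = 5)
  expect_true(all(sim$states[, "F1"] == 0))
  expect_true(all(sim$states[, "P"] == 0))
  expect_true(all(sim$states >= -1e-10))
})

test_that("trajectories stay nonnegative and on the effort simplex", {
  p <- mest_params(g = 0.28)
  sim <- mest_simulate(p, scan_initial_state(p), T_total = 2000, record_dt = 2)
  expect_true(all(sim$states >= -1e-10))
  ssum <- rowSums(sim$states[, c("theta0", "theta1")])
  expect_true(all(ssum <= 1 + 1e-8))
})

test_that("simplex total including the derived effort is conserved to 1e-8", {
  # integrate theta_C as an explicit redundant coordinate and check that the
  # full simplex sum holds along the trajectory
  p <- mest_params(g = 0.28)
  pk <- mestweb:::pack_params(p)
  aug <- function(t, y, parms) {
    dy <- mestweb:::mest_rhs_cpp(y[1:6], pk)
    w0 <- p$eP * p$u0 * y[1]
    w1 <- p$eP * p$ui[1] * y[2]
    wC <- p$eP * p$uC * y[3]
    wbar <- y[5] * w0 + y[6] * w1 + y[7] * wC
    dthC <- p$g * y[7] * (wC - wbar)
    list(c(dy, dthC))
  }
  y0 <- c(0.5, 0.5, 0.5, 0.5, 1 / 3, 1 / 3, 1 / 3)
  out <- deSolve::ode(y0, seq(0, 10000, by = 20), aug, NULL,
                      method = "ode45", rtol = 1e-8, atol = 1e-10)
  total <- out[, 6] + out[, 7] + out[, 8]
  expect_lt(max(abs(total - 1)), 1e-8)
})

test_that("tightening tolerances tenfold leaves the trajectory essentially unchanged", {
  p <- mest_params()  # four-species reference parameters
  s0 <- scan_initial_state(p)
  a <- mest_simulate(p, s0, T_total = 1000, record_dt = 10, prune = FALSE)
  b <- mest_simulate(p, s0, T_total = 1000, record_dt = 10, prune = FALSE,
                     rtol = 1e-9, atol = 1e-11)
  expect_lt(abs(a$states[101, "F1"] - b$states[101, "F1"]), 1e-4)
})

test_that("short-horizon backward integration recovers the initial state", {
  p <- mest_params(g = 0.28)
  s0 <- scan_initial_state(p)
  fwd <- mest_simulate(p, s0, times = seq(0, 10, by = 1), prune = FALSE)
  end <- final_state(fwd)
  bwd <- mest_simulate(p, end, times = seq(10, 0, by = -1), prune = FALSE,
                       method = "lsoda")
  expect_lt(max(abs(mestweb:::pack_state(final_state(bwd)) -
                    mestweb:::pack_state(s0))), 1e-6)
})

test_that("attractor extrema classify constants, sinusoids and clustered peaks", {
  tt <- seq(0, 400, by = 0.1)
  const <- data.frame(time = tt, x = rep(2, length(tt)))
  ex <- attractor_extrema(const, "x", transient = 100)
  expect_true(ex$fixed_point)
  expect_equal(ex$distinct_maxima, 2)

  sine <- data.frame(time = tt, x = sin(tt))
  ex2 <- attractor_extrema(sine, "x", transient = 100)
  expect_false(ex2$fixed_point)
  expect_length(ex2$distinct_maxima, 1)
  expect_equal(ex2$distinct_maxima, 1, tolerance = 1e-4)
  expect_equal(ex2$distinct_minima, -1, tolerance = 1e-4)

  # period-2 signal: alternating peak heights resolve into two branches
  per2 <- data.frame(time = tt, x = sin(tt) + 0.25 * sin(tt / 2))
  ex3 <- attractor_extrema(per2, "x", transient = 100, min_cycles = 10)
  expect_equal(length(ex3$distinct_maxima), 2)

  expect_error(attractor_extrema(sine[1:30, ], "x", transient = 0,
                                 min_cycles = 20), "too short")
})

test_that("bifurcation scan of length one reduces to attractor extrema", {
  p <- mest_params()
  scan <- bifurcation_scan(p, g_grid = 0.48, transient = 1000, record = 1500,
                           min_cycles = 3)
  sim <- mest_simulate({p$g <- 0.48; p}, scan_initial_state(p),
                       T_total = 2500, prune = FALSE)
  direct <- attractor_extrema(sim, "F1", transient = 1000, min_cycles = 3)
  expect_equal(scan$extrema[[1]]$distinct_maxima, direct$distinct_maxima)
})

test_that("Benettin exponents match closed-form linear systems", {
  le <- lyapunov_benettin(function(y) -y, function(y) matrix(-1, 1, 1),
                          y0 = 1, horizon = 200)
  expect_equal(le, -1, tolerance = 0.01)

  harm <- lyapunov_benettin(function(y) c(y[2], -y[1]),
                            function(y) matrix(c(0, -1, 1, 0), 2, 2),
                            y0 = c(1, 0), k = 1, horizon = 500)
  expect_lt(abs(harm[1]), 0.01)
})

test_that("the Lyapunov spectrum of a dissipative attractor sums to <= 0", {
  p <- mest_params(g = 0.48)
  le <- mest_lyapunov(p, scan_initial_state(p), transient = 2000,
                      horizon = 4000)
  expect_lt(sum(le$exponents), 0)
  expect_equal(length(le$exponents), le$k)
})

test_that("dynamics classification follows the extrema/exponent rules", {
  fp <- structure(list(fixed_point = TRUE, distinct_maxima = 1),
                  class = "mest_extrema")
  one <- structure(list(fixed_point = FALSE, distinct_maxima = 1.2),
                   class = "mest_extrema")
  two <- structure(list(fixed_point = FALSE, distinct_maxima = c(1.0, 1.3)),
                   class = "mest_extrema")
  pos <- list(exponents = 0.02)
  neg <- list(exponents = -0.01)
  expect_equal(classify_dynamics(fp), "fixed_point")
  expect_equal(classify_dynamics(one, neg), "periodic")
  expect_equal(classify_dynamics(two, neg), "period_doubled")
  expect_equal(classify_dynamics(two, pos), "chaotic")
  expect_equal(classify_dynamics(one, pos), "unresolved")
})
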