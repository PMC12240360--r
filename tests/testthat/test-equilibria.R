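test_that("mutualist-only community reduces to the logistic equilibrium", {
  p <- mest_params()
  eq <- find_equilibrium(p, mest_mask(1, "F0"),
                         species = c(TRUE, FALSE, FALSE, FALSE),
                         scope = "ecological")
  expect_true(eq$feasible)
  expect_equal(eq$state$F0, (p$r0 - p$d0) / p$alpha0, tolerance = 1e-10)
  expect_equal(eq$Re_lambda_max, -(p$r0 - p$d0), tolerance = 1e-8)
})

test_that("feasible equilibria are genuine roots of the field", {
  p <- mest_params(beta = 0.1)
  for (act in list("F1", c("F0", "F1"), c("F1", "C"), c("F0", "F1", "C"))) {
    eq <- find_equilibrium(p, mest_mask(1, act))
    if (!eq$feasible) next
    expect_lt(eq$residual, 1e-10)
    dy <- mest_rhs(eq$state, p)
    expect_lt(max(abs(dy[1:4])), 1e-10)
    # replicator is stationary too: active gradients equal
    w <- fitness_gradients(eq$state, p)
    wact <- w[act]
    expect_lt(diff(range(wact)), 1e-9)
    # efforts respect the mask
    msk <- mest_mask(1, act)
    th_all <- c(eq$state$theta, 1 - sum(eq$state$theta))
    expect_true(all(th_all[!msk] == 0))
  }
})

test_that("eigenvalues match a characteristic-polynomial root solve", {
  # characteristic polynomial by Newton's identities on matrix-power traces
  # (no eigendecomposition), then polyroot - an independent spectral oracle
  char_roots <- function(J) {
    d <- nrow(J)
    Jp <- diag(d)
    s <- numeric(d)
    for (k in seq_len(d)) {
      Jp <- Jp %*% J
      s[k] <- sum(diag(Jp))
    }
    e <- numeric(d)
    for (k in seq_len(d)) {
      acc <- s[k] * (-1)^(k - 1)
      if (k > 1)
        for (j in seq_len(k - 1)) acc <- acc + (-1)^(j - 1) * e[k - j] * s[j]
      e[k] <- acc / k
    }
    # p(x) = x^d - e1 x^{d-1} + ... + (-1)^d ed; polyroot wants ascending
    coefs <- numeric(d + 1)
    coefs[d + 1] <- 1
    for (k in seq_len(d)) coefs[d + 1 - k] <- (-1)^k * e[k]
    polyroot(coefs)
  }
  set.seed(13)
  for (rep in 1:5) {
    p <- mest_params(beta = runif(1, 0.02, 0.15))
    s <- random_state(1)
    for (scope in c("ecological", "full")) {
      J <- mest_jacobian(p, s, scope)
      ev <- eigen(J, only.values = TRUE)$values
      pr <- char_roots(J)
      expect_equal(sort(Re(ev)), sort(Re(pr)), tolerance = 1e-8)
      expect_equal(sort(abs(Im(ev))), sort(abs(Im(pr))), tolerance = 1e-8)
    }
  }
})

test_that("exchanging symmetric exploiters leaves the spectrum unchanged", {
  p <- mest_params(n = 2, ri = 0.35, ui = 0.15, beta = 0.1)
  s <- random_state(2, seed = 8)
  # symmetrize the state across the two exploiters
  s2 <- mest_state(s$F0, rev(s$F), s$C, s$P,
                   theta = c(s$theta[1], rev(s$theta[-1])))
  ev1 <- sort(Re(eigen(mest_jacobian(p, s, "full"))$values))
  ev2 <- sort(Re(eigen(mest_jacobian(p, s2, "full"))$values))
  expect_equal(ev1, ev2, tolerance = 1e-10)
})

test_that("stability maps are invariant to grid traversal order", {
  p <- mest_params()
  u <- c(0.16, 0.2, 0.24)
  b <- c(0.04, 0.1)
  m1 <- stability_map(p, mest_mask(1, "F1"), u1_grid = u, beta_grid = b)
  m2 <- stability_map(p, mest_mask(1, "F1"), u1_grid = rev(u),
                      beta_grid = rev(b))
  d1 <- as.data.frame(m1)
  d2 <- as.data.frame(m2)
  d2 <- d2[order(d2$beta, d2$u1), ]
  d1 <- d1[order(d1$beta, d1$u1), ]
  expect_equal(d1$feasible, d2$feasible)
  expect_equal(d1$re_lambda_max, d2$re_lambda_max, tolerance = 1e-9)
})

test_that("boundary-structure counting matches exhaustive enumeration", {
  expect_equal(count_boundary_structures(33), 8589934590)
  expect_equal(count_boundary_structures(1), 0)
  expect_equal(count_boundary_structures(3), 6)
  expect_error(count_boundary_structures(0), ">= 1")

  # brute force for m = 3: all proper nonempty subsets of 3 links
  m <- 3
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  proper <- rowSums(subsets) > 0 & rowSums(subsets) < m
  expect_equal(sum(proper), count_boundary_structures(m))

  # m = 12 by explicit enumeration, m = 20 by the binomial identity
  m <- 12
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  expect_equal(sum(rowSums(subsets) %in% 1:(m - 1)),
               count_boundary_structures(12))
  expect_equal(sum(choose(20, 1:19)), count_boundary_structures(20))
})

test_that("infeasible cells are reported as such", {
  p <- mest_params()
  p$ui[1] <- 0  # the predator cannot persist on a worthless single link
  eq <- find_equilibrium(p, mest_mask(1, "F1"))
  expect_false(eq$feasible)
  expect_true(is.na(eq$Re_lambda_max))
})
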