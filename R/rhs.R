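#' Vector field of the adaptive-foraging MEST model
#'
#' Evaluates the coupled biomass/preference derivatives: logistic-mutualist
#' growth of `F0` with competition from the exploiters, mutualist-capacity
#' growth of each exploiter (`F0/q` acts as its carrying capacity, with `F0`
#' clamped from below at 1e-12 inside the capacity only), linear (Holling I)
#' predation by `C` on `F0` and by `P` on all prey weighted by the foraging
#' efforts, and replicator dynamics of the efforts on the full simplex: the
#' mean fitness gradient runs over all of P's prey including `C`, with
#' `theta_C = 1 - sum(theta)`, so that the simplex is conserved exactly.
#'
#' @param state a [mest_state()].
#' @param params a [mest_params()].
#' @return named numeric vector of derivatives over
#'   `(F0, F1..Fn, C, P, theta0..thetan)`.
#' @examples
#' p <- mest_params()
#' s <- mest_state(0.5, 0.5, 0.5, 0.5, theta = c(1/3, 1/3))
#' mest_rhs(s, p)
#' @export
mest_rhs <- function(state, params) {
  validate_params(params)
  validate_state(state, n = params$n)
  dy <- mest_rhs_cpp(pack_state(state), pack_params(params))
  stats::setNames(dy, state_names(params$n))
}

#' Top-predator fitness W_P
#'
#' `W_P = eP * sum_k theta_k u_k F_k + eP * theta_C * uC * C - dP - alphaP * P`,
#' so that `dP/dt = P * W_P`.
#'
#' @inheritParams mest_rhs
#' @return scalar fitness.
#' @export
predator_fitness <- function(state, params) {
  validate_params(params)
  validate_state(state, n = params$n)
  u <- c(params$u0, params$ui)
  Fk <- c(state$F0, state$F)
  thC <- 1 - sum(state$theta)
  params$eP * sum(state$theta * u * Fk) + params$eP * thC * params$uC * state$C -
    params$dP - params$alphaP * state$P
}

#' Fitness gradients of the top predator over its prey
#'
#' Partial derivatives of `W_P` with respect to the foraging efforts:
#' `w_j = eP * u_j * F_j` for prey `F0..Fn` and `w_C = eP * uC * C`. The
#' replicator field moves effort toward prey whose gradient exceeds the
#' effort-weighted mean `sum_k theta_k w_k` (the sum includes `theta_C w_C`).
#'
#' @inheritParams mest_rhs
#' @return named vector of gradients for `(F0, F1..Fn, C)` with the mean
#'   gradient attached as attribute `"mean"`.
#' @export
fitness_gradients <- function(state, params) {
  validate_params(params)
  validate_state(state, n = params$n)
  u <- c(params$u0, params$ui)
  w <- params$eP * u * c(state$F0, state$F)
  wC <- params$eP * params$uC * state$C
  thC <- 1 - sum(state$theta)
  out <- stats::setNames(c(w, wC),
                         c("F0", if (params$n > 0) paste0("F", seq_len(params$n)),
                           "C"))
  attr(out, "mean") <- sum(state$theta * w) + thC * wC
  out
}

#' Analytic Jacobian of the MEST field
#'
#' @param params a [mest_params()].
#' @param state a [mest_state()] (any point, not necessarily an equilibrium).
#' @param scope `"ecological"` for the `(n+3) x (n+3)` Jacobian of the biomass
#'   equations with the foraging efforts frozen at their current values, or
#'   `"full"` for the `(2n+4) x (2n+4)` Jacobian including the independent
#'   effort coordinates `theta_0..theta_n` (`theta_C` eliminated).
#' @return a square matrix with row/column names.
#' @export
mest_jacobian <- function(params, state, scope = c("ecological", "full")) {
  scope <- match.arg(scope)
  validate_params(params)
  validate_state(state, n = params$n)
  J <- mest_jac_cpp(pack_state(state), pack_params(params))
  nm <- state_names(params$n)
  dimnames(J) <- list(nm, nm)
  if (scope == "ecological") {
    keep <- seq_len(params$n + 3L)
    J <- J[keep, keep, drop = FALSE]
  }
  J
}
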