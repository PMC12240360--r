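#' Community state of the MEST model
#'
#' Biomasses of the mutualist `F0`, the exploiters `F1..Fn`, the specialist
#' predator `C` and the top predator `P`, together with the top predator's
#' foraging efforts `theta` over `F0..Fn`. The effort devoted to `C` is always
#' derived, `theta_C = 1 - sum(theta)`, so the efforts live on the simplex.
#'
#' @param F0 mutualist biomass (>= 0).
#' @param F exploiter biomass vector, length `n`.
#' @param C,P specialist and top predator biomasses.
#' @param theta foraging efforts of `P` on `F0..Fn`, length `n + 1`, entries
#'   >= 0 with `sum(theta) <= 1`.
#' @return object of class `mest_state`.
#' @examples
#' s <- mest_state(F0 = 0.5, F = 0.5, C = 0.5, P = 0.5, theta = c(1/3, 1/3))
#' s$thetaC
#' @export
mest_state <- function(F0, F = numeric(), C, P, theta) {
  s <- list(F0 = as.numeric(F0), F = as.numeric(F),
            C = as.numeric(C), P = as.numeric(P), theta = as.numeric(theta))
  class(s) <- "mest_state"
  validate_state(s)
  s$thetaC <- 1 - sum(s$theta)
  s
}

validate_state <- function(s, n = NULL) {
  stopifnot(inherits(s, "mest_state"))
  if (length(s$F0) != 1L || length(s$C) != 1L || length(s$P) != 1L)
    stop("F0, C, P must be scalars", call. = FALSE)
  if (length(s$theta) != length(s$F) + 1L)
    stop("theta must have length n + 1 (efforts on F0..Fn)", call. = FALSE)
  if (!is.null(n) && length(s$F) != n)
    stop(sprintf("state has %d exploiters but params have n = %d",
                 length(s$F), n), call. = FALSE)
  v <- c(s$F0, s$F, s$C, s$P, s$theta)
  if (any(!is.finite(v))) stop("state entries must be finite", call. = FALSE)
  if (any(v < 0)) stop("biomasses and efforts must be nonnegative", call. = FALSE)
  if (sum(s$theta) > 1 + 1e-9)
    stop("sum(theta) exceeds 1: efforts must lie on the simplex", call. = FALSE)
  invisible(s)
}

# packed numeric vector (F0, F1..Fn, C, P, theta0..thetan) for the integrator
pack_state <- function(s) {
  c(s$F0, s$F, s$C, s$P, s$theta)
}

unpack_state <- function(y, n) {
  s <- list(F0 = y[[1L]],
            F = if (n > 0) y[seq(2L, n + 1L)] else numeric(),
            C = y[[n + 2L]], P = y[[n + 3L]],
            theta = y[seq(n + 4L, 2L * n + 4L)])
  s$thetaC <- 1 - sum(s$theta)
  class(s) <- "mest_state"
  s
}

state_names <- function(n) {
  c("F0", if (n > 0) paste0("F", seq_len(n)), "C", "P",
    paste0("theta", 0:n))
}

#' @export
print.mest_state <- function(x, digits = 4, ...) {
  n <- length(x$F)
  cat(sprintf("MEST community state (n = %d exploiters)\n", n))
  cat("  F0 =", signif(x$F0, digits))
  if (n > 0) cat("; F =", paste(signif(x$F, digits), collapse = ", "))
  cat("; C =", signif(x$C, digits), "; P =", signif(x$P, digits), "\n")
  cat("  theta =", paste(signif(x$theta, digits), collapse = ", "),
      sprintf("(thetaC = %s)\n", signif(1 - sum(x$theta), digits)))
  invisible(x)
}
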