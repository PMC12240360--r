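#' Post-transient attractor extrema of one coordinate
#'
#' Discards the transient, locates interior local maxima and minima of the
#' sampled series (refined by parabolic interpolation through the three
#' samples around each discrete peak, so that sampling jitter stays well below
#' the clustering tolerance), and clusters them into distinct values. A series
#' whose post-transient range is below the clustering tolerance is a fixed
#' point and yields a single value.
#'
#' @param sim a `mest_sim` (or a data.frame with a `time` column).
#' @param variable coordinate name, e.g. `"F1"`.
#' @param transient time to discard before measuring.
#' @param cluster_tol absolute tolerance for merging extrema into one distinct
#'   value (default 1e-3, which separates period-2 branches at the scale of
#'   this model without splitting numerically identical ones).
#' @param min_cycles minimum number of maxima required in the window; fewer
#'   (for a non-fixed-point series) is an error ("window too short").
#' @return `mest_extrema` object: raw and clustered maxima/minima and a
#'   fixed-point flag.
#' @export
attractor_extrema <- function(sim, variable = "F1", transient = 5000,
                              cluster_tol = 1e-3, min_cycles = 20) {
  if (inherits(sim, "mest_sim")) {
    tt <- sim$times
    x <- sim$states[, variable]
  } else {
    tt <- sim$time
    x <- sim[[variable]]
  }
  keep <- tt >= transient
  if (sum(keep) < 10L)
    stop("post-transient window too short", call. = FALSE)
  x <- x[keep]
  # fixed point: the tail of the window has collapsed below the clustering
  # tolerance (covers slowly damped approaches as well as exact equilibria)
  tail_x <- x[seq(max(1L, length(x) - max(100L, length(x) %/% 10L)), length(x))]
  if (diff(range(x)) < cluster_tol || diff(range(tail_x)) < cluster_tol) {
    v <- mean(tail_x)
    return(structure(list(variable = variable, fixed_point = TRUE,
                          maxima = v, minima = v,
                          distinct_maxima = v, distinct_minima = v,
                          cluster_tol = cluster_tol),
                     class = "mest_extrema"))
  }
  i <- 2:(length(x) - 1L)
  is_max <- x[i] > x[i - 1L] & x[i] >= x[i + 1L]
  is_min <- x[i] < x[i - 1L] & x[i] <= x[i + 1L]
  refine <- function(j) {
    a <- x[j - 1L]; b <- x[j]; c <- x[j + 1L]
    den <- a - 2 * b + c
    if (den == 0) return(b)
    b - (a - c)^2 / (8 * den)  # parabolic vertex through the three samples
  }
  maxima <- vapply(i[is_max], refine, numeric(1))
  minima <- vapply(i[is_min], refine, numeric(1))
  if (length(maxima) < min_cycles)
    stop(sprintf("window too short: only %d oscillation maxima after transient",
                 length(maxima)), call. = FALSE)
  structure(list(variable = variable, fixed_point = FALSE,
                 maxima = maxima, minima = minima,
                 distinct_maxima = cluster_values(maxima, cluster_tol),
                 distinct_minima = cluster_values(minima, cluster_tol),
                 cluster_tol = cluster_tol),
            class = "mest_extrema")
}

cluster_values <- function(v, tol) {
  v <- sort(v)
  grp <- cumsum(c(TRUE, diff(v) > tol))
  as.numeric(tapply(v, grp, mean))
}

#' @export
print.mest_extrema <- function(x, ...) {
  if (x$fixed_point) {
    cat(sprintf("%s: fixed point at %.6g\n", x$variable, x$maxima))
  } else {
    cat(sprintf("%s: %d maxima in %d distinct branches (tol %g), %d minima in %d\n",
                x$variable, length(x$maxima), length(x$distinct_maxima),
                x$cluster_tol, length(x$minima), length(x$distinct_minima)))
  }
  invisible(x)
}

#' Default initial state for bifurcation-style scans
#'
#' All biomasses 0.5 and the foraging effort spread uniformly over all of P's
#' prey including `C` (`theta_j = 1/(n+2)`); fixed so that scans are
#' reproducible.
#'
#' @param params a [mest_params()].
#' @return a [mest_state()].
#' @export
scan_initial_state <- function(params) {
  n <- params$n
  mest_state(F0 = 0.5, F = rep(0.5, n), C = 0.5, P = 0.5,
             theta = rep(1 / (n + 2), n + 1))
}

#' Bifurcation scan over the adaptation intensity g
#'
#' Integrates the model from a fixed documented initial state
#' ([scan_initial_state()]) for each value of `g`, discards the transient and
#' records the attractor extrema of one coordinate.
#'
#' @param params base [mest_params()]; `g` is overridden per grid point.
#' @param g_grid adaptation intensities (study range [0.05, 0.5]).
#' @param variable coordinate to record.
#' @param transient,record time discarded / recorded per grid point.
#' @param state0 initial state (default [scan_initial_state()]).
#' @param prune apply the extinction rule during integration; off by default
#'   for attractor diagnostics, which study the smooth flow (the four-species
#'   attractors skim effort values many orders below the extinction threshold
#'   and would otherwise be collapsed onto boundary equilibria).
#' @param min_cycles passed to [attractor_extrema()].
#' @param ... passed to [mest_simulate()].
#' @return `mest_bifurcation`: list of `mest_extrema` (one per `g`) with the
#'   grid attached; `as.data.frame()` gives tidy `(g, type, value)` rows.
#' @export
bifurcation_scan <- function(params, g_grid, variable = "F1",
                             transient = 5000, record = 2000,
                             state0 = scan_initial_state(params),
                             prune = FALSE, min_cycles = 20, ...) {
  res <- lapply(g_grid, function(g) {
    p <- params
    p$g <- g
    sim <- mest_simulate(p, state0, T_total = transient + record,
                         prune = prune, ...)
    attractor_extrema(sim, variable = variable, transient = transient,
                      min_cycles = min_cycles)
  })
  structure(list(g = g_grid, extrema = res, variable = variable),
            class = "mest_bifurcation")
}

#' @export
as.data.frame.mest_bifurcation <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$g), function(i) {
    e <- x$extrema[[i]]
    data.frame(g = x$g[i],
               type = rep(c("max", "min"), c(length(e$maxima), length(e$minima))),
               value = c(e$maxima, e$minima))
  }))
}

#' @export
print.mest_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation scan of %s over %d values of g in [%g, %g]\n",
              x$variable, length(x$g), min(x$g), max(x$g)))
  nb <- vapply(x$extrema, function(e)
    if (e$fixed_point) 0L else length(e$distinct_maxima), integer(1))
  print(data.frame(g = x$g, distinct_maxima = nb))
  invisible(x)
}

#' @export
plot.mest_bifurcation <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[df$type == "max", ]
  plot(df$g, df$value, pch = ".", cex = 2, xlab = "adaptation intensity g",
       ylab = paste("local maxima of", x$variable), ...)
  invisible(x)
}

# shared Benettin driver: one deSolve run with a renormalization event at
# every interval; the event does the QR step and accumulates log stretches.
benettin_core <- function(aug_field, y0, d, da, k, parms,
                          renorm_dt, horizon, rtol, atol, method = "ode45") {
  Phi0 <- diag(1, da)[, seq_len(k), drop = FALSE]
  aug0 <- c(y0, as.vector(Phi0))
  times <- seq(0, horizon, by = renorm_dt)
  acc <- new.env(parent = emptyenv())
  acc$logs <- matrix(NA_real_, length(times) - 1L, k)
  acc$i <- 0L
  renorm <- function(t, y, p) {
    if (any(abs(y[seq_len(d)]) > 1e6))
      stop("trajectory unbounded during Lyapunov averaging", call. = FALSE)
    Phi <- matrix(y[(d + 1L):length(y)], da, k)
    qrd <- qr(Phi)
    Q <- qr.Q(qrd)
    R <- qr.R(qrd)
    sgn <- sign(diag(R))
    sgn[sgn == 0] <- 1
    acc$i <- acc$i + 1L
    acc$logs[acc$i, ] <- log(abs(diag(R)))
    y[(d + 1L):length(y)] <- as.vector(sweep(Q, 2, sgn, "*"))
    y
  }
  out <- deSolve::ode(y = aug0, times = times, func = aug_field, parms = parms,
                      method = method, rtol = rtol, atol = atol,
                      events = list(func = renorm, time = times[-1L]))
  if (nrow(out) < length(times))
    stop("integration failed during Lyapunov averaging", call. = FALSE)
  logs <- acc$logs[seq_len(acc$i), , drop = FALSE]
  t_used <- acc$i * renorm_dt
  exponents <- colSums(logs) / t_used
  trace <- apply(logs, 2, cumsum) / (seq_len(acc$i) * renorm_dt)
  list(exponents = exponents, increments = logs, trace = trace,
       t_used = t_used)
}

#' Lyapunov spectrum by tangent-space (Benettin) averaging
#'
#' Integrates the variational system alongside the trajectory with periodic
#' QR orthonormalization and averages the log stretching factors. The tangent
#' space is restricted to the components that survive the transient; the
#' leading exponent carries a bootstrap standard error over the
#' per-interval stretching increments.
#'
#' @param params,state0 model and initial state; a transient with extinction
#'   pruning is integrated first and the spectrum is computed on the attractor.
#' @param k number of exponents (default: full surviving dimension).
#' @param transient discarded lead-in time.
#' @param horizon averaging horizon after the transient.
#' @param renorm_dt reorthonormalization interval.
#' @param rtol,atol integration tolerances.
#' @param prune apply the extinction rule during the transient (off by
#'   default, see [bifurcation_scan()]).
#' @param n_boot bootstrap resamples for the convergence band.
#' @return `mest_lyapunov`: exponents sorted descending, convergence trace,
#'   bootstrap standard error of the leading exponent, dimensions used.
#' @examples
#' \donttest{
#' p <- mest_params(g = 0.28)
#' le <- mest_lyapunov(p, scan_initial_state(p), k = 1, horizon = 2000)
#' }
#' @export
mest_lyapunov <- function(params, state0, k = NULL, transient = 5000,
                          horizon = 20000, renorm_dt = 1,
                          rtol = 1e-8, atol = 1e-10, prune = FALSE,
                          n_boot = 200) {
  validate_params(params)
  validate_state(state0, n = params$n)
  pre <- mest_simulate(params, state0, T_total = transient, record_dt = 10,
                       rtol = rtol, atol = atol, prune = prune)
  y0 <- pack_state(final_state(pre))
  d <- length(y0)
  alive <- which(y0 > 0)
  da <- length(alive)
  if (is.null(k)) k <- da
  k <- min(k, da)
  pk <- pack_params(params)
  idx0 <- as.integer(alive - 1L)
  aug_field <- function(t, y, p) {
    list(mest_rhs_tangent_cpp(y, p, idx0, k))
  }
  res <- benettin_core(aug_field, y0, d, da, k, pk,
                       renorm_dt, horizon, rtol, atol)
  ord <- order(res$exponents, decreasing = TRUE)
  inc <- res$increments[, ord, drop = FALSE]
  boots <- with_seed(1, {
    m <- nrow(inc)
    vapply(seq_len(n_boot), function(b) {
      mean(inc[sample.int(m, m, replace = TRUE), 1L]) / renorm_dt
    }, numeric(1))
  })
  structure(list(exponents = res$exponents[ord],
                 trace = res$trace[, ord, drop = FALSE],
                 leading_se = stats::sd(boots),
                 components = state_names(params$n)[alive],
                 k = k, horizon = res$t_used, renorm_dt = renorm_dt),
            class = "mest_lyapunov")
}

#' Benettin Lyapunov exponents of a user-supplied smooth field
#'
#' Generic tangent-space averaging for an arbitrary ODE `dy/dt = field(y)`
#' with Jacobian `jac(y)`; used for cross-checking against systems with known
#' exponents.
#'
#' @param field function(y) -> dy.
#' @param jac function(y) -> Jacobian matrix.
#' @param y0 initial state (on or near the attractor).
#' @param k number of exponents.
#' @param horizon,renorm_dt,rtol,atol averaging controls.
#' @return numeric vector of exponents, sorted descending.
#' @export
lyapunov_benettin <- function(field, jac, y0, k = length(y0),
                              horizon = 1000, renorm_dt = 1,
                              rtol = 1e-8, atol = 1e-10) {
  d <- length(y0)
  aug_field <- function(t, y, p) {
    yy <- y[seq_len(d)]
    Phi <- matrix(y[-seq_len(d)], d, k)
    list(c(field(yy), as.vector(jac(yy) %*% Phi)))
  }
  res <- benettin_core(aug_field, y0, d, d, k, NULL,
                       renorm_dt, horizon, rtol, atol)
  sort(res$exponents, decreasing = TRUE)
}

#' @export
print.mest_lyapunov <- function(x, ...) {
  cat(sprintf("Lyapunov spectrum (%d of %d directions, horizon %g, QR every %g):\n",
              x$k, length(x$components), x$horizon, x$renorm_dt))
  cat(" ", paste(signif(x$exponents, 4), collapse = ", "), "\n")
  cat(sprintf("  leading exponent %.5f +/- %.5f (bootstrap se)\n",
              x$exponents[1], x$leading_se))
  invisible(x)
}

#' Classify attractor dynamics
#'
#' Chaotic if the leading Lyapunov exponent exceeds `le_tol`; fixed point if
#' the extrema collapse to a single value; otherwise periodic versus
#' period-doubled by the number of distinct maxima branches (1 versus >= 2).
#' A positive leading exponent combined with a single extremum is flagged
#' `"unresolved"`.
#'
#' @param extrema an [attractor_extrema()] result.
#' @param spectrum optional [mest_lyapunov()] result from the same trajectory.
#' @param le_tol threshold on the leading exponent (default 0.005).
#' @return one of `"fixed_point"`, `"periodic"`, `"period_doubled"`,
#'   `"chaotic"`, `"unresolved"`.
#' @export
classify_dynamics <- function(extrema, spectrum = NULL, le_tol = 0.005) {
  stopifnot(inherits(extrema, "mest_extrema"))
  le <- if (!is.null(spectrum)) spectrum$exponents[1] else -Inf
  if (extrema$fixed_point)
    return(if (le > le_tol) "unresolved" else "fixed_point")
  nmax <- length(extrema$distinct_maxima)
  if (le > le_tol) {
    if (nmax <= 1L) return("unresolved")
    return("chaotic")
  }
  if (nmax <= 1L) "periodic" else "period_doubled"
}
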