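#' Integrate an MEST trajectory with extinction pruning
#'
#' Adaptive Runge-Kutta (Dormand-Prince, the nonstiff `"ode45"` method of
#' \pkg{deSolve}) integration of the coupled biomass/preference field. At
#' every recording time an event sets any biomass or foraging effort that has
#' fallen below the extinction threshold to exactly 0, where the field holds
#' it (every component's derivative is proportional to the component itself,
#' so extinction faces are invariant). Pruning an effort leaves the remaining
#' efforts untouched; `theta_C` is always `1 - sum(theta)`.
#'
#' @param params a [mest_params()].
#' @param state0 a [mest_state()] initial condition.
#' @param T_total integration horizon (dimensionless time).
#' @param record_dt spacing of recorded samples (also the pruning cadence).
#' @param times explicit output times overriding `T_total`/`record_dt`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method a \pkg{deSolve} method name; `"lsoda"` is the documented
#'   stiff-capable fallback.
#' @param extinction_threshold biomass/effort cutoff below which a component
#'   is deemed extinct (default 1e-12).
#' @param prune set `FALSE` to integrate the raw field without extinction
#'   events (used e.g. for time-reversal checks).
#' @return `mest_sim` object: recorded `times`, a states matrix (one named
#'   column per coordinate), extinction events (component, time), and the
#'   final [mest_state()].
#' @examples
#' p <- mest_params(g = 0.08)
#' s0 <- mest_state(0.5, 0.5, 0.5, 0.5, theta = c(1/3, 1/3))
#' sim <- mest_simulate(p, s0, T_total = 200)
#' sim
#' @export
mest_simulate <- function(params, state0, T_total = 2000, record_dt = 1,
                          times = NULL, rtol = 1e-8, atol = 1e-10,
                          method = "ode45", extinction_threshold = 1e-12,
                          prune = TRUE) {
  validate_params(params)
  validate_state(state0, n = params$n)
  if (is.null(times)) times <- seq(0, T_total, by = record_dt)
  if (length(times) < 2L) stop("need at least two output times", call. = FALSE)
  pk <- pack_params(params)
  y0 <- pack_state(state0)
  names(y0) <- state_names(params$n)
  thr <- extinction_threshold

  field <- function(t, y, pk) list(mest_rhs_cpp(y, pk))
  ev <- list(func = function(t, y, pk) { y[y < thr] <- 0; y },
             time = times[-1L])
  out <- deSolve::ode(y = y0, times = times, func = field, parms = pk,
                      method = method, rtol = rtol, atol = atol,
                      events = if (prune) ev else NULL)
  if (any(is.nan(out)))
    stop("NaN produced during integration; first bad time: ",
         out[which(rowSums(is.nan(out)) > 0)[1L], 1L], call. = FALSE)
  truncated <- nrow(out) < length(times)
  if (truncated)
    warning("integration stopped early at t = ", out[nrow(out), 1L],
            " (step-size collapse); returning partial trajectory")
  st <- out[, -1L, drop = FALSE]
  if (prune) st[st < thr] <- 0  # recorded samples reflect the held (post-event) state

  # extinction events: first recorded time a previously-positive component is 0
  ev_df <- data.frame(component = character(), time = numeric())
  if (prune && nrow(st) > 1L) {
    for (j in seq_len(ncol(st))) {
      z <- st[, j] == 0
      if (any(z) && !z[1L]) {
        k <- which(z & !c(FALSE, z[-length(z)]))
        if (length(k) && all(st[seq(k[1L], nrow(st)), j] == 0))
          ev_df <- rbind(ev_df, data.frame(component = colnames(st)[j],
                                           time = out[k[1L], 1L]))
      } else if (z[1L]) next
    }
  }
  structure(list(times = out[, 1L], states = st, params = params,
                 extinction_events = ev_df, truncated = truncated,
                 rtol = rtol, atol = atol, method = method,
                 extinction_threshold = thr),
            class = "mest_sim")
}

#' @export
print.mest_sim <- function(x, ...) {
  cat(sprintf("MEST trajectory: %d samples over t in [%g, %g] (%s, rtol %g)\n",
              length(x$times), min(x$times), max(x$times), x$method, x$rtol))
  if (nrow(x$extinction_events))
    cat("  extinctions:",
        paste(sprintf("%s@t=%g", x$extinction_events$component,
                      x$extinction_events$time), collapse = ", "), "\n")
  fs <- final_state(x)
  cat("  final: "); print(fs)
  invisible(x)
}

#' @export
summary.mest_sim <- function(object, ...) {
  rng <- apply(object$states, 2, range)
  rownames(rng) <- c("min", "max")
  cat("Coordinate ranges over the recorded window:\n")
  print(signif(t(rng), 5))
  invisible(t(rng))
}

#' Final community state of a simulated trajectory
#' @param sim a `mest_sim`.
#' @return a [mest_state()].
#' @export
final_state <- function(sim) {
  unpack_state(sim$states[nrow(sim$states), ], sim$params$n)
}

#' @param x a `mest_sim`.
#' @param long if `TRUE`, tidy long format `(time, variable, value)`;
#'   otherwise one column per coordinate.
#' @rdname mest_simulate
#' @export
as.data.frame.mest_sim <- function(x, row.names = NULL, optional = FALSE,
                                   long = FALSE, ...) {
  if (!long)
    return(data.frame(time = x$times, x$states, check.names = FALSE))
  data.frame(time = rep(x$times, ncol(x$states)),
             variable = rep(colnames(x$states), each = length(x$times)),
             value = as.numeric(x$states))
}

#' @export
plot.mest_sim <- function(x, which = c("biomass", "effort"), ...) {
  which <- match.arg(which)
  n <- x$params$n
  idx <- if (which == "biomass") seq_len(n + 3L) else seq(n + 4L, 2L * n + 4L)
  graphics::matplot(x$times, x$states[, idx, drop = FALSE], type = "l",
                    lty = 1, xlab = "time",
                    ylab = if (which == "biomass") "biomass" else "foraging effort",
                    ...)
  graphics::legend("topright", legend = colnames(x$states)[idx],
                   col = seq_along(idx), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

# species survivor mask (biomasses only; pruned efforts do not count against
# species persistence)
species_alive <- function(sim_or_state, n = NULL) {
  if (inherits(sim_or_state, "mest_sim")) {
    s <- final_state(sim_or_state)
  } else s <- sim_or_state
  alive <- c(F0 = s$F0 > 0,
             if (length(s$F)) stats::setNames(s$F > 0, paste0("F", seq_along(s$F))),
             C = s$C > 0, P = s$P > 0)
  alive
}
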