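#' Run one persistence replicate to steady state
#'
#' Integrates the community in windows of `T_check` time units (with
#' extinction pruning at threshold `extinction_threshold`) and stops when the
#' surviving-species count is unchanged across two consecutive windows, or
#' when `T_total` is reached. Persistence is the fraction of the `N = n + 3`
#' species whose biomass remains above the threshold; pruned foraging efforts
#' remove a link but do not count against species persistence.
#'
#' @param params a [mest_params()].
#' @param state0 a [mest_state()].
#' @param T_check,T_total window length and overall cap.
#' @param extinction_threshold extinction cutoff.
#' @param record_dt sample spacing within a window (also the pruning cadence).
#' @param method integrator; community assembly passes through strongly stiff
#'   episodes (mutualist collapse drives the exploiter capacity towards 0), so
#'   the stiff-switching `"lsoda"` is the default here.
#' @param ... further options for [mest_simulate()].
#' @return list: `persistence`, logical `survivors` over `(F0, F1..Fn, C,
#'   P)`, `final_connectance` (surviving predator links over potential
#'   links), `t_end`, and the final state.
#' @export
run_replicate <- function(params, state0, T_check = 2000, T_total = 20000,
                          extinction_threshold = 1e-12, record_dt = 20,
                          method = "lsoda", ...) {
  validate_params(params)
  n <- params$n
  N <- n + 3L
  st <- state0
  t_now <- 0
  prev_count <- NA_integer_
  repeat {
    # project numerical simplex drift back (sum(theta) can creep a few 1e-9
    # above 1 over a window when theta_C = 0)
    sth <- sum(st$theta)
    if (sth > 1) st$theta <- st$theta / sth
    sim <- mest_simulate(params, st, T_total = T_check, record_dt = record_dt,
                         extinction_threshold = extinction_threshold,
                         method = method, ...)
    st <- final_state(sim)
    t_now <- t_now + T_check
    alive <- species_alive(st)
    count <- sum(alive)
    if ((!is.na(prev_count) && count == prev_count) || t_now >= T_total)
      break
    prev_count <- count
  }
  theta_links <- c(st$theta > 0, (1 - sum(st$theta)) > extinction_threshold)
  list(persistence = sum(alive) / N, survivors = alive,
       final_connectance = sum(theta_links) / (n + 2L),
       t_end = t_now, state = st)
}

#' Persistence-versus-connectance surface
#'
#' Full factorial experiment over the connectance grid of an
#' [ensemble_spec()]: for each connectance value, `n_param_draws` parameter
#' sets are drawn, each combined with `n_init_draws` random wirings and
#' initial states, every replicate is integrated to steady state by
#' [run_replicate()], and the mean and standard deviation of persistence are
#' recorded. Everything is reproducible from `base_seed`; the per-replicate
#' seeds and survivor masks are kept in the replicate manifest.
#'
#' @param spec an [ensemble_spec()].
#' @param quiet suppress progress output.
#' @return `persistence_surface`: data.frame `(connectance, beta, g, N,
#'   mean_persistence, sd_persistence, n_replicates)` with the per-replicate
#'   manifest in `attr(, "replicates")`.
#' @export
persistence_surface <- function(spec, quiet = TRUE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n_prey <- spec$N - 1L                 # F0, F1..Fn, C
  reps <- list()
  rows <- list()
  for (ci in seq_along(spec$connectance_grid)) {
    conn <- spec$connectance_grid[ci]
    pvals <- numeric(0)
    for (pi in seq_len(spec$n_param_draws)) {
      seed_p <- replicate_seed(spec$base_seed + 7919 * ci, pi)
      params <- draw_params(spec, seed = seed_p)
      for (ii in seq_len(spec$n_init_draws)) {
        seed_i <- replicate_seed(spec$base_seed + 7919 * ci, pi, ii)
        wiring <- wire_initial_foraging(n_prey, conn, seed = seed_i,
                                        mandatory_links = spec$mandatory_links)
        state0 <- draw_initial_state(params, wiring, seed = seed_i + 1)
        rr <- tryCatch(
          run_replicate(params, state0, T_check = spec$T_check,
                        T_total = spec$T_total,
                        extinction_threshold = spec$extinction_threshold),
          error = function(e) e)
        if (inherits(rr, "error")) {
          reps[[length(reps) + 1L]] <-
            data.frame(connectance = conn, param_draw = pi, init_draw = ii,
                       seed = seed_i, persistence = NA_real_,
                       final_connectance = NA_real_,
                       survivors = NA_character_, error = conditionMessage(rr))
          next
        }
        pvals <- c(pvals, rr$persistence)
        reps[[length(reps) + 1L]] <-
          data.frame(connectance = conn, param_draw = pi, init_draw = ii,
                     seed = seed_i, persistence = rr$persistence,
                     final_connectance = rr$final_connectance,
                     survivors = paste(as.integer(rr$survivors),
                                       collapse = ""),
                     error = NA_character_)
      }
    }
    rows[[ci]] <- data.frame(connectance = conn, beta = spec$beta, g = spec$g,
                             N = spec$N, mean_persistence = mean(pvals),
                             sd_persistence = stats::sd(pvals),
                             n_replicates = length(pvals))
    if (!quiet)
      message(sprintf("connectance %.3f: mean persistence %.3f (%d reps)",
                      conn, mean(pvals), length(pvals)))
  }
  structure(do.call(rbind, rows),
            replicates = do.call(rbind, reps), spec = spec,
            class = c("persistence_surface", "data.frame"))
}

#' @export
print.persistence_surface <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("Persistence surface: N = %d, beta = %g, g = %g (%dx%d replicates)\n",
              s$N, s$beta, s$g, s$n_param_draws, s$n_init_draws))
  print(data.frame(connectance = x$connectance,
                   mean = round(x$mean_persistence, 4),
                   sd = round(x$sd_persistence, 4),
                   n = x$n_replicates))
  cat("pattern:", classify_pattern(x$connectance, x$mean_persistence), "\n")
  invisible(x)
}

#' @export
plot.persistence_surface <- function(x, ...) {
  graphics::plot(x$connectance, x$mean_persistence, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "initial connectance",
                 ylab = "community persistence", ...)
  graphics::arrows(x$connectance, x$mean_persistence - x$sd_persistence,
                   x$connectance, x$mean_persistence + x$sd_persistence,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Classify a connectance-persistence pattern
#'
#' Deterministic rule on the mean-persistence curve: a centred 3-point moving
#' average is taken; if the Spearman correlation with connectance satisfies
#' `|rho| >= rho_min` the pattern is monotonic with the matching sign;
#' otherwise interior local maxima of the smoothed curve with topographic
#' prominence at least `prominence` are counted (1 = peaked, 2 =
#' double-peaked); anything else is unclear.
#'
#' @param connectance,persistence numeric vectors (>= 5 points).
#' @param rho_min Spearman threshold for monotonicity (default 0.8).
#' @param prominence minimum peak prominence in persistence units
#'   (default 0.02).
#' @return one of `"positive_monotonic"`, `"negative_monotonic"`,
#'   `"peaked"`, `"double_peaked"`, `"unclear"`.
#' @export
classify_pattern <- function(connectance, persistence,
                             rho_min = 0.8, prominence = 0.02) {
  if (length(connectance) < 5L || length(persistence) != length(connectance))
    stop("need at least 5 (connectance, persistence) points", call. = FALSE)
  o <- order(connectance)
  x <- connectance[o]
  y <- persistence[o]
  m <- length(y)
  sm <- y
  if (m >= 3L)
    sm[2:(m - 1L)] <- (y[1:(m - 2L)] + y[2:(m - 1L)] + y[3:m]) / 3
  rho <- suppressWarnings(stats::cor(x, sm, method = "spearman"))
  if (!is.na(rho) && abs(rho) >= rho_min)
    return(if (rho > 0) "positive_monotonic" else "negative_monotonic")
  peaks <- interior_peaks(sm)
  npeaks <- sum(peak_prominence(sm, peaks) >= prominence)
  if (npeaks == 1L) return("peaked")
  if (npeaks == 2L) return("double_peaked")
  "unclear"
}

interior_peaks <- function(y) {
  m <- length(y)
  i <- 2:(m - 1L)
  i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
}

# topographic prominence: height above the higher of the two key saddles,
# scanning outward to the nearest strictly higher point or the boundary
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p - 1L)]
    right <- y[seq(p + 1L, length(y))]
    hi_l <- which(left > y[p])
    base_l <- min(if (length(hi_l)) left[seq(max(hi_l), length(left))] else left)
    hi_r <- which(right > y[p])
    base_r <- min(if (length(hi_r)) right[seq_len(min(hi_r))] else right)
    y[p] - max(base_l, base_r)
  }, numeric(1))
}
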