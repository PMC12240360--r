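#' Ensemble specification for persistence experiments
#'
#' Describes one cell (or a connectance grid) of the persistence-versus-
#' connectance design: network size `N` (species count, `n = N - 3`
#' exploiters), shared competition `beta`, adaptation intensity `g`, the
#' initial-connectance grid, replicate counts (`n_param_draws` parameter sets
#' times `n_init_draws` initial wirings/states per set), a base seed, and the
#' integration/stopping controls.
#'
#' @param N total species count (>= 4).
#' @param beta shared interspecific competition coefficient.
#' @param g adaptation intensity.
#' @param connectance_grid initial connectance values in (0, 1].
#' @param n_param_draws,n_init_draws replicate structure (the full design is
#'   20 x 20; reduced counts are the desk-scale default).
#' @param base_seed RNG seed; together with the replicate index it fully
#'   determines parameters, wiring and initial state.
#' @param T_check,T_total steady-state window and overall cap for
#'   [run_replicate()].
#' @param extinction_threshold biomass/effort extinction cutoff.
#' @param mandatory_links wiring policy, see [wire_initial_foraging()].
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(N, beta = 0.1, g = 0.28,
                          connectance_grid = seq(0.2, 1, length.out = 8),
                          n_param_draws = 5, n_init_draws = 5,
                          base_seed = 1, T_check = 2000, T_total = 20000,
                          extinction_threshold = 1e-12,
                          mandatory_links = c("F0", "C")) {
  N <- as.integer(N)
  if (is.na(N) || N < 4L)
    stop("'N' must be >= 4 (at least one exploiter)", call. = FALSE)
  if (any(connectance_grid <= 0 | connectance_grid > 1))
    stop("connectance values must lie in (0, 1]", call. = FALSE)
  if (n_param_draws < 1L || n_init_draws < 1L)
    stop("replicate counts must be >= 1", call. = FALSE)
  structure(list(N = N, beta = beta, g = g,
                 connectance_grid = as.numeric(connectance_grid),
                 n_param_draws = as.integer(n_param_draws),
                 n_init_draws = as.integer(n_init_draws),
                 base_seed = base_seed, T_check = T_check, T_total = T_total,
                 extinction_threshold = extinction_threshold,
                 mandatory_links = mandatory_links),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("Ensemble: N = %d, beta = %g, g = %g; %d connectance values; %dx%d replicates; seed %g\n",
              x$N, x$beta, x$g, length(x$connectance_grid),
              x$n_param_draws, x$n_init_draws, x$base_seed))
  invisible(x)
}

#' Draw a replicate parameter set
#'
#' Exploiter growth rates are i.i.d. uniform on [0.3, 0.4] with `di = 0.05`
#' and `ui = 0.15` for all exploiters; all other parameters take the
#' reference defaults with `beta` and `g` from the spec.
#'
#' @param spec an [ensemble_spec()].
#' @param seed RNG seed for this draw (derive it from
#'   `spec$base_seed` and the replicate index for full reproducibility).
#' @return a [mest_params()].
#' @export
draw_params <- function(spec, seed = spec$base_seed) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$N - 3L
  ri <- with_seed(seed, stats::runif(n, 0.3, 0.4))
  mest_params(n = n, ri = ri, ui = 0.15, di = 0.05,
              beta = spec$beta, g = spec$g)
}

#' Draw a random initial foraging wiring at a prescribed connectance
#'
#' The top predator has `n_prey = n + 2` potential prey (`F0`, `F1..Fn`,
#' `C`). The total link count is `L = round(connectance * n_prey)` (floored
#' at the number of mandatory links). By default the apparent-competition
#' link to the mutualist `F0` and the omnivory link to the specialist `C`
#' are always wired - connectance below 1 means some of the exploiters are
#' not foraged by the top predator - and the remaining `L - 2` links are
#' chosen uniformly at random among the exploiters. Each active link
#' receives equal effort `1/L` (the effort on `C` is carried implicitly via
#' `theta_C = 1 - sum(theta)`), inactive entries are exactly 0.
#'
#' @param n_prey number of potential prey (`n + 2`).
#' @param connectance initial connectance in (0, 1].
#' @param seed RNG seed.
#' @param mandatory_links links always wired: subset of
#'   `c("F0", "C")` (default both); use `character()` for fully random
#'   wiring over all prey.
#' @return list with `theta` (length `n_prey - 1`, efforts on `F0..Fn`),
#'   `active` (logical over `(F0, F1..Fn, C)`), and `L`.
#' @export
wire_initial_foraging <- function(n_prey, connectance, seed = NULL,
                                  mandatory_links = c("F0", "C")) {
  if (connectance <= 0 || connectance > 1)
    stop("connectance must lie in (0, 1]", call. = FALSE)
  n_prey <- as.integer(n_prey)
  n <- n_prey - 2L
  stopifnot(all(mandatory_links %in% c("F0", "C")))
  forced <- c(if ("F0" %in% mandatory_links) 1L,
              if ("C" %in% mandatory_links) n_prey)
  free <- setdiff(seq_len(n_prey), forced)
  L <- max(length(forced), 1L, as.integer(round(connectance * n_prey)))
  extra <- with_seed(seed, free[sample.int(length(free), L - length(forced))])
  active <- seq_len(n_prey) %in% c(forced, extra)
  theta <- numeric(n_prey - 1L)                 # efforts on F0..Fn
  theta[active[-n_prey]] <- 1 / L               # C (last slot) is derived
  names(active) <- c("F0", if (n > 0) paste0("F", seq_len(n)), "C")
  list(theta = theta, active = active, L = L)
}

#' Draw a random initial community state
#'
#' Biomasses are i.i.d. uniform on [0.1, 1.0] (a documented default; the
#' range is configurable), efforts come from the wiring.
#'
#' @param params a [mest_params()].
#' @param wiring result of [wire_initial_foraging()].
#' @param seed RNG seed.
#' @param biomass_range range of the uniform initial biomasses.
#' @return a [mest_state()].
#' @export
draw_initial_state <- function(params, wiring, seed = NULL,
                               biomass_range = c(0.1, 1.0)) {
  n <- params$n
  if (length(wiring$theta) != n + 1L)
    stop("wiring is inconsistent with params$n", call. = FALSE)
  b <- with_seed(seed,
                 stats::runif(n + 3L, biomass_range[1], biomass_range[2]))
  mest_state(F0 = b[1], F = b[seq_len(n) + 1L], C = b[n + 2L], P = b[n + 3L],
             theta = wiring$theta)
}
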