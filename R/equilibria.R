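#' Foraging-structure mask
#'
#' Declares which of the top predator's potential links (to `F0`, `F1..Fn`,
#' `C`) are active in a boundary network structure. Inactive links have their
#' effort pinned at exactly 0; when two or more links are active, the interior
#' replicator condition (equal fitness gradients across active prey)
#' determines the equilibrium efforts.
#'
#' @param n number of exploiters.
#' @param active character vector naming active links among
#'   `"F0"`, `"F1"`, ..., `"C"`, or a logical vector of length `n + 2`.
#' @return named logical vector of class `mest_mask` over `(F0, F1..Fn, C)`.
#' @examples
#' mest_mask(1, c("F1"))        # P consumes only the exploiter
#' mest_mask(1, c("F0", "F1"))  # theta_C = 0, efforts split over F0 and F1
#' @export
mest_mask <- function(n, active) {
  nm <- c("F0", if (n > 0) paste0("F", seq_len(n)), "C")
  if (is.logical(active)) {
    if (length(active) != n + 2L)
      stop("logical mask must have length n + 2", call. = FALSE)
    m <- active
  } else {
    bad <- setdiff(active, nm)
    if (length(bad))
      stop("unknown link names: ", paste(bad, collapse = ", "), call. = FALSE)
    m <- nm %in% active
  }
  names(m) <- nm
  if (!any(m)) stop("at least one link must be active", call. = FALSE)
  structure(m, class = "mest_mask")
}

# bracket (per-capita growth) equations whose zeros define a coexistence
# equilibrium; length n + 3 over (F0, F1..Fn, C, P); thin wrapper over the
# compiled kernel
equilibrium_brackets <- function(params, Fv, C, P, theta) {
  as.numeric(mest_brackets_cpp(c(Fv, C, P, theta), pack_params(params)))
}

# damped Newton with forward-difference Jacobian
newton_solve <- function(fn, x0, tol = 1e-13, maxit = 60) {
  x <- x0
  r <- fn(x)
  if (any(!is.finite(r))) return(list(converged = FALSE))
  for (it in seq_len(maxit)) {
    nr <- max(abs(r))
    if (nr < tol) return(list(x = x, residual = nr, converged = TRUE))
    if (nr > 1e8) return(list(converged = FALSE))
    J <- matrix(0, length(r), length(x))
    for (j in seq_along(x)) {
      h <- 1e-8 * max(1, abs(x[j]))
      xh <- x
      xh[j] <- xh[j] + h
      J[, j] <- (fn(xh) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(list(converged = FALSE))
    lam <- 1
    repeat {
      xn <- x - lam * step
      rn <- fn(xn)
      if (all(is.finite(rn)) && max(abs(rn)) < nr) break
      lam <- lam / 2
      if (lam < 1 / 128) break
    }
    if (lam < 1 / 128 && (any(!is.finite(rn)) || max(abs(rn)) >= nr))
      return(list(x = x, residual = nr, converged = nr < tol))
    x <- xn
    r <- rn
  }
  list(x = x, residual = max(abs(r)), converged = max(abs(r)) < tol)
}

# seeded Latin-hypercube multi-start set shared across all grid cells of a
# stability map, so results do not depend on traversal order
equilibrium_starts <- function(n_present, m_active, n_starts, seed) {
  with_seed(seed, {
    H <- lhs::randomLHS(n_starts, n_present + max(m_active, 1L))
    lapply(seq_len(n_starts), function(i) {
      b <- H[i, seq_len(n_present)] * 5         # biomasses in (0, 5]
      t_raw <- H[i, -seq_len(n_present)][seq_len(m_active)]
      t_all <- t_raw / sum(t_raw)               # interior simplex point
      list(biomass = b,
           effort = if (m_active >= 2L) t_all[-m_active] else numeric())
    })
  })
}

# basis (columns) of the perturbation subspace for the requested Jacobian
# scope, in the packed coordinates (F0..Fn, C, P, theta0..thetan)
scope_basis <- function(scope, pres, act, n) {
  d <- 2L * n + 4L
  cols <- lapply(pres, function(i) { v <- numeric(d); v[i] <- 1; v })
  if (scope != "ecological") {
    c_active <- (n + 2L) %in% act
    if (scope == "full" || c_active) {
      cols <- c(cols, lapply(seq_len(n + 1L), function(j) {
        v <- numeric(d); v[n + 3L + j] <- 1; v
      }))
    } else {
      # theta_C = 0 structure: effort perturbations keep sum(theta) = 1
      r <- max(act)                      # reference active F link
      for (j in setdiff(seq_len(n + 1L), r)) {
        v <- numeric(d)
        v[n + 3L + j] <- 1
        v[n + 3L + r] <- -1
        cols <- c(cols, list(v))
      }
    }
  }
  do.call(cbind, cols)
}

#' Solve a coexistence equilibrium for a prescribed foraging structure
#'
#' Solves the algebraic system consisting of the per-capita (bracket)
#' equations of all modeled species plus, when two or more foraging links are
#' active, equality of the predator's fitness gradients across active prey
#' (the interior replicator fixed-point condition), which pins the equilibrium
#' efforts. Roots are sought by damped Newton iteration from a seeded
#' Latin-hypercube multi-start set; the first feasible root (strictly positive
#' biomasses for modeled species, efforts in [0, 1], residual below 1e-10)
#' is accepted.
#'
#' @param params a [mest_params()].
#' @param mask a [mest_mask()] (which predator links are active).
#' @param species optional named logical over `(F0, F1..Fn, C, P)` selecting
#'   which species are present (absent species are fixed at 0 and their
#'   equations dropped); default all present.
#' @param guess optional `mest_state` used as the first start.
#' @param scope Jacobian scope for the stability assessment. `"full"` (the
#'   default) uses the biomass directions plus all independent effort
#'   coordinates `theta_0..theta_n` (`theta_C` eliminated), so that for a
#'   boundary structure the spectrum includes the replicator invasion
#'   eigenvalues of the unused links - the directions along which adaptive
#'   foraging can rewire the structure. `"ecological"` freezes all efforts
#'   (biomass block only). `"trait"` keeps only effort directions tangent to
#'   the structure's simplex face (effort reallocation that leaves
#'   `theta_C = 0` untouched when the omnivory link is inactive).
#' @param n_starts,seed multi-start count and seed.
#' @param starts precomputed start list (internal, for grid sweeps).
#' @return `mest_equilibrium`: equilibrium state, residual norm, feasibility
#'   flag, `Re_lambda_max` and the full eigenvalue list (NA when infeasible).
#' @examples
#' p <- mest_params(beta = 0.1)
#' eq <- find_equilibrium(p, mest_mask(1, c("F1", "C")))
#' eq
#' @export
find_equilibrium <- function(params, mask, species = NULL, guess = NULL,
                             scope = c("full", "ecological", "trait"),
                             n_starts = 16, seed = 1, starts = NULL) {
  scope <- match.arg(scope)
  validate_params(params)
  n <- params$n
  if (!inherits(mask, "mest_mask")) mask <- mest_mask(n, mask)
  sp_names <- c("F0", if (n > 0) paste0("F", seq_len(n)), "C", "P")
  if (is.null(species)) species <- stats::setNames(rep(TRUE, n + 3L), sp_names)
  if (length(species) != n + 3L)
    stop("'species' must have length n + 3 over (F0, F1..Fn, C, P)",
         call. = FALSE)
  names(species) <- sp_names
  act <- which(unclass(mask))          # indices into (F0, F1..Fn, C)
  m <- length(act)
  pres <- which(species)
  np <- length(pres)

  # assemble full (biomass, theta) coordinates from the unknown vector
  build <- function(x) {
    bio <- numeric(n + 3L)
    bio[pres] <- x[seq_len(np)]
    t_act <- if (m >= 2L) {
      tf <- x[np + seq_len(m - 1L)]
      c(tf, 1 - sum(tf))
    } else 1
    theta <- numeric(n + 1L)           # efforts on F0..Fn; C's effort derived
    on_f <- act[act <= n + 1L]
    theta[on_f] <- t_act[act <= n + 1L]
    list(Fv = bio[seq_len(n + 1L)], C = bio[n + 2L], P = bio[n + 3L],
         theta = theta, t_act = t_act)
  }
  uvec <- c(params$u0, params$ui, params$uC)   # over (F0..Fn, C)
  pk <- pack_params(params)
  resid <- function(x) {
    s <- build(x)
    br <- mest_brackets_cpp(c(s$Fv, s$C, s$P, s$theta), pk)[pres]
    if (m >= 2L) {
      w <- params$eP * uvec[act] * c(s$Fv, s$C)[act]
      br <- c(br, diff(w))             # gradient equality across active prey
    }
    br
  }

  if (is.null(starts))
    starts <- equilibrium_starts(np, m, n_starts, seed)
  if (!is.null(guess)) {
    gx <- c(pack_state(guess)[pres],
            if (m >= 2L) {
              t_full <- c(guess$theta, 1 - sum(guess$theta))[act]
              t_full[-m]
            })
    starts <- c(list(list(biomass = gx[seq_len(np)],
                          effort = gx[-seq_len(np)])), starts)
  }

  best <- NULL
  for (s0 in starts) {
    x0 <- c(s0$biomass, s0$effort)
    sol <- newton_solve(resid, x0)
    if (!isTRUE(sol$converged)) next
    s <- build(sol$x)
    ok <- all(sol$x[seq_len(np)] > 1e-9) &&
      all(s$t_act > 1e-9) && all(s$t_act <= 1 + 1e-12) &&
      sol$residual < 1e-10
    if (ok) { best <- list(sol = sol, s = s); break }
    if (is.null(best)) best <- list(sol = sol, s = s, infeasible = TRUE)
  }

  empty <- structure(list(mask = mask, species = species, scope = scope,
                          feasible = FALSE, residual = NA_real_,
                          Re_lambda_max = NA_real_, eigenvalues = NULL,
                          state = NULL),
                     class = "mest_equilibrium")
  if (is.null(best)) return(empty)
  s <- best$s
  feasible <- is.null(best$infeasible)
  if (!feasible) return(empty)

  st <- mest_state(F0 = s$Fv[1], F = s$Fv[-1], C = s$C, P = s$P,
                   theta = s$theta)
  J <- mest_jacobian(params, st, scope = "full")
  V <- scope_basis(scope, pres, act, n)
  Jr <- solve(crossprod(V), crossprod(V, J %*% V))
  ev <- eigen(Jr, only.values = TRUE)$values
  structure(list(mask = mask, species = species, scope = scope,
                 feasible = TRUE, residual = best$sol$residual,
                 Re_lambda_max = max(Re(ev)), eigenvalues = ev,
                 state = st),
            class = "mest_equilibrium")
}

#' @export
print.mest_equilibrium <- function(x, ...) {
  cat("MEST coexistence equilibrium (links:",
      paste(names(x$mask)[x$mask], collapse = ", "), ")\n")
  if (!x$feasible) {
    cat("  infeasible: no strictly positive root found\n")
    return(invisible(x))
  }
  print(x$state)
  cat(sprintf("  residual %.2e; Re(lambda_max) = %.5f (%s scope)\n",
              x$residual, x$Re_lambda_max, x$scope))
  invisible(x)
}

#' Local-stability map over the (u1, beta) plane
#'
#' For each grid cell the coexistence equilibrium of the prescribed foraging
#' structure is solved ([find_equilibrium()]) and the maximal real part of the
#' Jacobian eigenvalues recorded; infeasible cells (no strictly positive
#' root) are marked. The competition coefficient is applied symmetrically
#' (`beta_10 = beta_01 = beta`). The multi-start set is drawn once for the
#' whole map so the result does not depend on traversal order.
#'
#' @param params base [mest_params()] (four-species by default); `ui[1]` and
#'   `beta` are overridden per cell.
#' @param mask a [mest_mask()].
#' @param u1_grid,beta_grid grids (defaults: `u1` 0..0.3 step 0.005, `beta`
#'   0..0.18 step 0.004).
#' @param scope Jacobian scope (see [find_equilibrium()]; default `"full"`).
#' @param n_starts,seed multi-start controls.
#' @return `mest_stability_map`: data.frame `(u1, beta, feasible,
#'   re_lambda_max)` with the mask and scope attached.
#' @export
stability_map <- function(params, mask,
                          u1_grid = seq(0, 0.3, by = 0.005),
                          beta_grid = seq(0, 0.18, by = 0.004),
                          scope = c("full", "ecological", "trait"),
                          n_starts = 16, seed = 1) {
  scope <- match.arg(scope)
  validate_params(params)
  if (params$n < 1L) stop("stability_map needs at least one exploiter")
  if (!inherits(mask, "mest_mask")) mask <- mest_mask(params$n, mask)
  m <- sum(mask)
  np <- params$n + 3L
  starts <- equilibrium_starts(np, m, n_starts, seed)
  grid <- expand.grid(u1 = u1_grid, beta = beta_grid)
  fe <- logical(nrow(grid))
  rl <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$ui[1] <- grid$u1[i]
    p$beta <- grid$beta[i]
    eq <- find_equilibrium(p, mask, scope = scope, starts = starts)
    fe[i] <- eq$feasible
    rl[i] <- eq$Re_lambda_max
  }
  structure(data.frame(u1 = grid$u1, beta = grid$beta,
                       feasible = fe, re_lambda_max = rl),
            mask = mask, scope = scope, class = c("mest_stability_map",
                                                  "data.frame"))
}

#' @export
print.mest_stability_map <- function(x, ...) {
  msk <- attr(x, "mask")
  cat(sprintf("Stability map (%d cells; links: %s; %s scope)\n",
              nrow(x), paste(names(msk)[msk], collapse = ", "),
              attr(x, "scope")))
  nf <- sum(x$feasible)
  cat(sprintf("  feasible cells: %d (%.1f%%)\n", nf, 100 * nf / nrow(x)))
  if (nf > 0) {
    r <- x$re_lambda_max[x$feasible]
    cat(sprintf("  Re(lambda_max) over feasible cells: [%.5f, %.5f], %d stable (< 0)\n",
                min(r), max(r), sum(r < 0)))
  }
  invisible(x)
}

#' @export
plot.mest_stability_map <- function(x, ...) {
  u <- sort(unique(x$u1))
  b <- sort(unique(x$beta))
  z <- matrix(NA_real_, length(u), length(b))
  z[cbind(match(x$u1, u), match(x$beta, b))] <-
    ifelse(x$feasible, x$re_lambda_max, NA)
  graphics::image(u, b, z, xlab = "u1 (consumption rate of P on F1)",
                  ylab = "beta (interspecific competition)",
                  col = grDevices::hcl.colors(64, "Blue-Red"), ...)
  invisible(x)
}

#' Number of boundary network structures
#'
#' With `m` selectable predator links, the boundary equilibria correspond to
#' all proper nonempty link subsets: `2^m - 2` (the full set and the empty
#' set excluded). For a 35-species community (specialist predator plus 32
#' exploiters selectable, m = 33) this is 2^33 - 2.
#'
#' @param m number of selectable links (>= 1).
#' @return the count as a double (exact for m <= 52).
#' @export
count_boundary_structures <- function(m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m <= 0L)
    stop("'m' must be a single integer >= 1", call. = FALSE)
  2^m - 2
}
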