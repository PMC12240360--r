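#' Model parameters for an adaptive-foraging MEST community
#'
#' Constructs the full parameter set of the mutualist-exploiter-specialist
#' predator-top predator (MEST) model with adaptive foraging of the top
#' predator. Defaults are the dimensionless reference values of the model
#' (four-species setting: one exploiter with `ri = 0.35`, `ui = 0.15`, shared
#' interspecific competition `beta = 0.18`, adaptation intensity `g = 0.28`).
#'
#' The community holds a mutualist `F0`, `n` exploiters `F1..Fn`, a specialist
#' predator `C` feeding on `F0` only, and a top predator `P` that divides its
#' foraging effort `theta` over `F0..Fn` and `C` (with
#' `theta_C = 1 - sum(theta)`).
#'
#' @param n number of exploiter species (>= 0).
#' @param r0 mutualist intrinsic growth rate.
#' @param alpha0,alphaC,alphaP density-dependence coefficients of `F0`, `C`, `P`.
#' @param beta interspecific competition over `{F0, F1..Fn}`: either a single
#'   shared coefficient (`beta_ji = beta` for all `j != i`) or a full
#'   `(n+1) x (n+1)` matrix with entry `[j, i]` the effect of species `j` on
#'   species `i` (diagonal ignored).
#' @param aC consumption rate of `C` on `F0`.
#' @param u0 consumption rate of `P` on `F0`.
#' @param uC consumption rate of `P` on `C`.
#' @param ri,ui,di exploiter growth, predation and mortality rates; scalars are
#'   recycled to length `n`.
#' @param q mutualism scale coefficient: `F0/q` is the exploiter carrying
#'   capacity; `q = 0` removes the mutualistic dependence (unbounded
#'   mutualism-free exploiter growth).
#' @param eC,eP conversion efficiencies of `C` and `P`, in (0, 1].
#' @param d0,dC,dP mortality rates of `F0`, `C`, `P`.
#' @param g adaptation intensity of the foraging-preference replicator
#'   dynamics; `g = 0` freezes the preferences (fixed-preference model).
#'
#' @return An object of class `mest_params` (a validated list).
#' @examples
#' p <- mest_params()                 # four-species reference community
#' p10 <- mest_params(n = 7, beta = 0.1, g = 0.08)
#' @export
mest_params <- function(n = 1,
                        r0 = 0.5, alpha0 = 0.13, alphaC = 0.12, alphaP = 0.1,
                        beta = 0.18, aC = 0.2, u0 = 0.11, uC = 0.2,
                        ri = 0.35, ui = 0.15, di = 0.05,
                        q = 0.25, eC = 1, eP = 1,
                        d0 = 0.05, dC = 0.05, dP = 0.05,
                        g = 0.28) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L)
    stop("'n' must be a single integer >= 0", call. = FALSE)
  ri <- rep_len(as.numeric(ri), n)
  ui <- rep_len(as.numeric(ui), n)
  di <- rep_len(as.numeric(di), n)
  p <- list(n = n, r0 = r0, alpha0 = alpha0, alphaC = alphaC, alphaP = alphaP,
            beta = beta, aC = aC, u0 = u0, uC = uC,
            ri = ri, ui = ui, di = di, q = q, eC = eC, eP = eP,
            d0 = d0, dC = dC, dP = dP, g = g)
  class(p) <- "mest_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "mest_params"))
  n <- p$n
  sc <- c("r0", "alpha0", "alphaC", "alphaP", "aC", "u0", "uC",
          "q", "eC", "eP", "d0", "dC", "dP", "g")
  for (f in sc) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("parameter '%s' must be a single finite nonnegative number", f),
           call. = FALSE)
  }
  if (p$eC > 1 || p$eP > 1 || p$eC <= 0 || p$eP <= 0)
    stop("conversion efficiencies eC, eP must lie in (0, 1]", call. = FALSE)
  for (f in c("ri", "ui", "di")) {
    v <- p[[f]]
    if (length(v) != n || (n > 0 && (any(!is.finite(v)) || any(v < 0))))
      stop(sprintf("'%s' must be a nonnegative vector of length n = %d", f, n),
           call. = FALSE)
  }
  b <- p$beta
  if (is.matrix(b)) {
    if (!all(dim(b) == n + 1L))
      stop("'beta' matrix must be (n+1) x (n+1) over {F0, F1..Fn}", call. = FALSE)
    if (any(!is.finite(b)) || any(b < 0))
      stop("'beta' entries must be finite and nonnegative", call. = FALSE)
  } else if (length(b) != 1L || !is.finite(b) || b < 0) {
    stop("'beta' must be a nonnegative scalar or an (n+1) x (n+1) matrix",
         call. = FALSE)
  }
  invisible(p)
}

# flat numeric pack consumed by the compiled field; layout documented in
# src/rhs.cpp
pack_params <- function(p) {
  validate_params(p)
  head <- c(p$n, p$r0, p$alpha0, p$alphaC, p$alphaP, p$aC, p$u0, p$uC,
            p$q, p$eC, p$eP, p$d0, p$dC, p$dP, p$g)
  if (is.matrix(p$beta)) {
    b <- p$beta
    diag(b) <- 0
    c(head, p$ri, p$ui, p$di, 1, as.numeric(b))
  } else {
    c(head, p$ri, p$ui, p$di, 0, p$beta)
  }
}

# beta as a full (n+1)x(n+1) matrix regardless of storage
beta_matrix <- function(p) {
  if (is.matrix(p$beta)) {
    b <- p$beta
  } else {
    b <- matrix(p$beta, p$n + 1L, p$n + 1L)
  }
  diag(b) <- 0
  b
}

#' @export
print.mest_params <- function(x, ...) {
  cat(sprintf("MEST model parameters (n = %d exploiters, %d species)\n",
              x$n, x$n + 3L))
  cat(sprintf("  mutualist:  r0 = %g, alpha0 = %g, d0 = %g, q = %g\n",
              x$r0, x$alpha0, x$d0, x$q))
  if (x$n > 0)
    cat(sprintf("  exploiters: ri in [%g, %g], ui in [%g, %g], di = %s\n",
                min(x$ri), max(x$ri), min(x$ui), max(x$ui),
                paste(unique(x$di), collapse = ", ")))
  cat(sprintf("  specialist: aC = %g, eC = %g, dC = %g, alphaC = %g\n",
              x$aC, x$eC, x$dC, x$alphaC))
  cat(sprintf("  predator:   u0 = %g, uC = %g, eP = %g, dP = %g, alphaP = %g\n",
              x$u0, x$uC, x$eP, x$dP, x$alphaP))
  bdesc <- if (is.matrix(x$beta)) "matrix" else sprintf("%g (shared)", x$beta)
  cat(sprintf("  competition beta = %s; adaptation intensity g = %g\n",
              bdesc, x$g))
  invisible(x)
}

#' @export
coef.mest_params <- function(object, ...) {
  unlist(unclass(object)[setdiff(names(object), "n")])
}

#' Extract parameters as a flat key-value list
#'
#' Serializable representation with documented keys
#' (`n, r0, alpha0, alphaC, alphaP, beta, aC, u0, uC, ri, ui, di, q, eC, eP,
#' d0, dC, dP, g`); the inverse of [as_mest_params()].
#'
#' @param x a `mest_params` object.
#' @return a plain named list.
#' @export
as.list.mest_params <- function(x, ...) {
  out <- unclass(x)
  if (is.matrix(out$beta)) out$beta <- as.numeric(out$beta)  # column-major
  out
}

#' Build parameters from a flat key-value list
#'
#' @param x named list with any subset of the `mest_params` keys; absent keys
#'   take the reference defaults. Unknown keys are an error.
#' @param strict if `TRUE`, additionally require values inside the documented
#'   study ranges (`beta <= 0.18`, `g` in [0.05, 0.5], `ui <= 0.3`,
#'   `ri` in [0.3, 0.4]).
#' @return a `mest_params` object.
#' @export
as_mest_params <- function(x, strict = FALSE) {
  stopifnot(is.list(x))
  known <- names(formals(mest_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter keys: ", paste(bad, collapse = ", "), call. = FALSE)
  n <- if (!is.null(x$n)) as.integer(x$n) else 1L
  if (!is.null(x$beta) && length(x$beta) > 1L)
    x$beta <- matrix(as.numeric(x$beta), n + 1L, n + 1L)
  p <- do.call(mest_params, x)
  if (strict) check_study_ranges(p)
  p
}

check_study_ranges <- function(p) {
  err <- character()
  bmax <- max(beta_matrix(p))
  if (bmax > 0.18) err <- c(err, sprintf("beta = %g outside [0, 0.18]", bmax))
  if (p$g < 0.05 || p$g > 0.5)
    err <- c(err, sprintf("g = %g outside [0.05, 0.5]", p$g))
  if (p$n > 0) {
    if (any(p$ui > 0.3))
      err <- c(err, "ui outside [0, 0.3]")
    if (any(p$ri < 0.3 | p$ri > 0.4))
      err <- c(err, "ri outside [0.3, 0.4]")
  }
  if (length(err))
    stop("parameters outside study ranges: ", paste(err, collapse = "; "),
         call. = FALSE)
  invisible(p)
}
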