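# Independent term-by-term oracle for the vector field, written directly from
# the model equations (plain R sums; no shared code with the compiled kernel).
rhs_oracle <- function(state, params) {
  p <- params
  n <- p$n
  F0 <- state$F0; Fv <- state$F; C <- state$C; P <- state$P
  th <- state$theta
  thC <- 1 - sum(th)
  bm <- if (is.matrix(p$beta)) p$beta else matrix(p$beta, n + 1, n + 1)
  diag(bm) <- 0
  allF <- c(F0, Fv)

  growth <- F0 * p$r0
  dd <- -p$alpha0 * F0^2
  comp <- -F0 * sum(bm[-1, 1] * Fv)
  byC <- -p$aC * C * F0
  byP <- -th[1] * p$u0 * P * F0
  mort <- -p$d0 * F0
  dF0 <- growth + dd + comp + byC + byP + mort

  dF <- numeric(n)
  K <- max(F0, 1e-12) / p$q
  for (i in seq_len(n)) {
    g_mut <- p$ri[i] * Fv[i] * (1 - Fv[i] / K)
    cmp <- -sum(bm[-(i + 1), i + 1] * allF[-(i + 1)]) * Fv[i]
    prd <- -th[i + 1] * p$ui[i] * Fv[i] * P
    dth <- -p$di[i] * Fv[i]
    # per-capita decline capped at 1000 (numerical regularization)
    percap <- (g_mut + cmp + prd + dth) / Fv[i]
    if (Fv[i] > 0 && percap < -1000) {
      dF[i] <- -1000 * Fv[i]
    } else dF[i] <- g_mut + cmp + prd + dth
  }

  dC <- C * (p$eC * p$aC * F0 - thC * p$uC * P - p$dC - p$alphaC * C)
  u <- c(p$u0, p$ui)
  WP <- p$eP * sum(th * u * allF) + p$eP * thC * p$uC * C - p$dP - p$alphaP * P
  dP <- P * WP

  w <- p$eP * u * allF
  wC <- p$eP * p$uC * C
  wbar <- sum(th * w) + thC * wC
  dth <- p$g * th * (w - wbar)
  c(dF0, dF, dC, dP, dth)
}

# central finite-difference Jacobian of the packed field
fd_jacobian <- function(params, y, h = 1e-6) {
  pk <- mestweb:::pack_params(params)
  d <- length(y)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    yp <- y; ym <- y
    yp[j] <- yp[j] + h
    ym[j] <- ym[j] - h
    J[, j] <- (mestweb:::mest_rhs_cpp(yp, pk) - mestweb:::mest_rhs_cpp(ym, pk)) / (2 * h)
  }
  J
}

# random strictly positive state on the interior of the effort simplex
random_state <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- runif(n + 2, 0.05, 1)
  th <- th / sum(th)
  mest_state(F0 = runif(1, 0.1, 2), F = runif(n, 0.1, 2),
             C = runif(1, 0.1, 2), P = runif(1, 0.1, 2),
             theta = th[seq_len(n + 1)])
}

# exhaustive simple-cycle enumeration by checking every node subset and every
# rotation-fixed permutation (independent of the package's DFS)
brute_force_cycles <- function(graph, max_length = 12) {
  nodes <- graph$nodes
  key <- paste(graph$edges$from, graph$edges$to)
  sgn <- stats::setNames(graph$edges$sign, key)
  has <- function(a, b) paste(a, b) %in% key
  out <- list()
  nn <- length(nodes)
  for (len in 2:min(max_length, nn)) {
    subs <- utils::combn(nn, len, simplify = FALSE)
    for (sub in subs) {
      first <- sub[1]
      rest <- sub[-1]
      perms <- all_perms(rest)
      for (pp in perms) {
        cyc <- nodes[c(first, pp)]
        edges_ok <- all(vapply(seq_len(len), function(k) {
          has(cyc[k], cyc[if (k == len) 1 else k + 1])
        }, logical(1)))
        if (edges_ok) {
          s <- prod(vapply(seq_len(len), function(k) {
            sgn[[paste(cyc[k], cyc[if (k == len) 1 else k + 1])]]
          }, numeric(1)))
          out[[length(out) + 1]] <- list(nodes = cyc, sign = s, length = len)
        }
      }
    }
  }
  out
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (tail in all_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], tail)
  out
}

random_signed_digraph <- function(n_nodes = 5, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p_edge
  e <- pairs[keep, ]
  if (!nrow(e)) e <- pairs[1, ]
  e$sign <- sample(c(-1, 1), nrow(e), replace = TRUE)
  signed_digraph(e, nodes = nodes)
}
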