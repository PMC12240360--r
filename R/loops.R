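#' Signed interaction digraph
#'
#' A directed graph whose edges carry signs in {+1, -1} ("+" promotion, "-"
#' inhibition); feedback loops are simple directed cycles and the sign of a
#' loop is the product of its edge signs (negative loops dampen, positive
#' loops amplify perturbations).
#'
#' @param edges data.frame with columns `from`, `to` (character) and `sign`
#'   (+1 or -1); at most one edge per ordered pair, no self-loops.
#' @param nodes optional node names (defaults to those appearing in `edges`).
#' @return object of class `signed_digraph`.
#' @export
signed_digraph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "sign") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(edges$sign %in% c(-1, 1)))
    stop("edge signs must be +1 or -1", call. = FALSE)
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed", call. = FALSE)
  if (anyDuplicated(edges[c("from", "to")]))
    stop("at most one edge per ordered node pair", call. = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("Signed digraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat(paste(sprintf("  %s -%s-> %s", x$edges$from,
                    ifelse(x$edges$sign > 0, "+", "-"), x$edges$to),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Signed digraph of the four-species MEST community
#'
#' Species-species edges follow the interaction terms of the model: predation
#' contributes "+" to the consumer and "-" to the resource; interspecific
#' competition between `F0` and `F1` is "-" both ways (when `beta = 0` the
#' mutualist-capacity facilitation gives a single "+" edge from `F0` to `F1`
#' instead); `C` is a specialist on `F0`; `P` preys on `F1` and `C` (and
#' optionally `F0`). Adaptive foraging can be added as a qualitative `AF`
#' node receiving a "+" edge from `P`, whose outgoing edge signs to `C` and
#' `F1` encode the foraging strategy:
#' \describe{
#'   \item{`inhibitC_promoteF1`}{increase predation on `C`, reduce it on `F1`.}
#'   \item{`promoteC_inhibitF1`}{reduce predation on `C`, increase it on `F1`.}
#'   \item{`both_promote`}{the increased-predation case of shifting effort
#'     onto both prey.}
#'   \item{`both_inhibit`}{the decreased-predation case.}
#'   \item{`none`}{no AF node.}
#' }
#'
#' @param include_AF add the adaptive-foraging node.
#' @param af_strategy one of the strategies above.
#' @param predator_on_F0 include the direct `P`-`F0` predation pair (does not
#'   change the maximal-loop census).
#' @param beta competition coefficient deciding the `F0`/`F1` edge signs.
#' @return a [signed_digraph()].
#' @export
mest_digraph <- function(include_AF = FALSE,
                         af_strategy = c("none", "inhibitC_promoteF1",
                                         "promoteC_inhibitF1", "both_promote",
                                         "both_inhibit"),
                         predator_on_F0 = FALSE, beta = 0.18) {
  af_strategy <- match.arg(af_strategy)
  if (include_AF && af_strategy == "none")
    stop("include_AF = TRUE requires an AF strategy", call. = FALSE)
  e <- list()
  add <- function(from, to, sign) {
    e[[length(e) + 1L]] <<- data.frame(from = from, to = to, sign = sign)
  }
  if (beta > 0) {
    add("F0", "F1", -1)          # competition
    add("F1", "F0", -1)
  } else {
    add("F0", "F1", +1)          # mutualist capacity facilitation
    add("F1", "F0", -1)
  }
  add("F0", "C", +1); add("C", "F0", -1)   # C consumes F0
  add("F1", "P", +1); add("P", "F1", -1)   # P consumes F1
  add("C", "P", +1);  add("P", "C", -1)    # P consumes C
  if (predator_on_F0) { add("F0", "P", +1); add("P", "F0", -1) }
  nodes <- c("F0", "F1", "C", "P")
  if (include_AF) {
    nodes <- c(nodes, "AF")
    add("P", "AF", +1)
    sgn <- switch(af_strategy,
                  inhibitC_promoteF1 = c(C = -1, F1 = +1),
                  promoteC_inhibitF1 = c(C = +1, F1 = -1),
                  both_promote = c(C = +1, F1 = +1),
                  both_inhibit = c(C = -1, F1 = -1))
    add("AF", "C", sgn[["C"]])
    add("AF", "F1", sgn[["F1"]])
  }
  signed_digraph(do.call(rbind, e), nodes = nodes)
}

#' Enumerate simple feedback loops with signs
#'
#' Depth-first enumeration of all simple directed cycles up to `max_length`
#' (cycles are rooted at their smallest node index so each is found once).
#' Every loop is returned in canonical form (rotation starting at the
#' lexicographically smallest node) with its edge-sign sequence and sign
#' product; the list is ordered by (length, node sequence).
#'
#' @param graph a [signed_digraph()].
#' @param max_length cap on cycle length (default 12).
#' @return list of loops, each a list with `nodes` (cycle order, first node
#'   not repeated), `signs` (edge signs along the cycle), `sign` (product)
#'   and `length`; class `mest_loops`.
#' @export
enumerate_loops <- function(graph, max_length = 12) {
  stopifnot(inherits(graph, "signed_digraph"))
  if (max_length < 2) stop("max_length must be >= 2", call. = FALSE)
  nodes <- graph$nodes
  nn <- length(nodes)
  adj <- lapply(seq_len(nn), function(i) {
    ei <- graph$edges[graph$edges$from == nodes[i], ]
    list(to = match(ei$to, nodes), sign = ei$sign)
  })
  loops <- list()
  path <- integer(max_length)
  onpath <- logical(nn)
  dfs <- function(root, v, depth) {
    nb <- adj[[v]]
    for (j in seq_along(nb$to)) {
      w <- nb$to[j]
      if (w == root && depth >= 2L) {
        cyc <- path[seq_len(depth)]
        signs <- vapply(seq_len(depth), function(k) {
          a <- cyc[k]; b <- cyc[if (k == depth) 1L else k + 1L]
          nb2 <- adj[[a]]
          nb2$sign[match(b, nb2$to)]
        }, numeric(1))
        loops[[length(loops) + 1L]] <<-
          list(nodes = nodes[cyc], signs = signs,
               sign = prod(signs), length = depth)
      } else if (w > root && !onpath[w] && depth < max_length) {
        path[depth + 1L] <<- w
        onpath[w] <<- TRUE
        dfs(root, w, depth + 1L)
        onpath[w] <<- FALSE
      }
    }
  }
  for (r in seq_len(nn)) {
    path[1L] <- r
    onpath[r] <- TRUE
    dfs(r, r, 1L)
    onpath[r] <- FALSE
  }
  # canonical rotation: start each cycle at its lexicographically smallest node
  loops <- lapply(loops, function(lp) {
    k <- which.min(match(lp$nodes, sort(lp$nodes)))
    idx <- ((seq_len(lp$length) + k - 2L) %% lp$length) + 1L
    lp$nodes <- lp$nodes[idx]
    lp$signs <- lp$signs[idx]
    lp
  })
  ord <- order(vapply(loops, `[[`, numeric(1), "length"),
               vapply(loops, function(l) paste(l$nodes, collapse = "\r"),
                      character(1)))
  structure(loops[ord], class = "mest_loops")
}

#' @export
print.mest_loops <- function(x, ...) {
  if (!length(x)) {
    cat("no feedback loops\n")
    return(invisible(x))
  }
  for (lp in x) cat(format_loop(lp), "\n")
  invisible(x)
}

format_loop <- function(lp) {
  arrows <- ifelse(lp$signs > 0, "+", "-")
  paste0(paste0(lp$nodes, " →", arrows, " ", collapse = ""),
         lp$nodes[1], "   [", if (lp$sign > 0) "positive" else "negative",
         ", length ", lp$length, "]")
}

#' Maximal feedback loops and their sign census
#'
#' Filters an [enumerate_loops()] result to the loops of maximal length and
#' counts positive versus negative ones.
#'
#' @param loops a `mest_loops` list.
#' @return list: `loops` (the maximal ones), `length`, `n_positive`,
#'   `n_negative`.
#' @export
maximal_loops <- function(loops) {
  if (!length(loops)) stop("no loops to filter", call. = FALSE)
  len <- vapply(loops, `[[`, numeric(1), "length")
  keep <- loops[len == max(len)]
  sgn <- vapply(keep, `[[`, numeric(1), "sign")
  list(loops = structure(keep, class = "mest_loops"), length = max(len),
       n_positive = sum(sgn > 0), n_negative = sum(sgn < 0))
}

#' Export a signed digraph in DOT format
#'
#' @param graph a [signed_digraph()].
#' @param path optional file to write to.
#' @return the DOT text, invisibly if written to a file.
#' @export
digraph_dot <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "signed_digraph"))
  lines <- c("digraph mest {",
             sprintf("  \"%s\";", graph$nodes),
             sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                     graph$edges$from, graph$edges$to,
                     ifelse(graph$edges$sign > 0, "+", "-")),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
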