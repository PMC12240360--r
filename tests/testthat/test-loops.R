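test_that("the four-species community has one positive and one negative maximal loop", {
  g <- mest_digraph()
  loops <- enumerate_loops(g)
  mx <- maximal_loops(loops)
  expect_equal(mx$length, 4)
  expect_equal(mx$n_positive, 1)
  expect_equal(mx$n_negative, 1)
  # the printed cycles: F0 ->+ C ->+ P ->- F1 ->- F0 (positive) and
  # F0 ->- F1 ->+ P ->- C ->- F0 (negative)
  seqs <- vapply(mx$loops, function(l) paste(l$nodes, collapse = ">"),
                 character(1))
  expect_setequal(seqs, c("C>P>F1>F0", "C>F0>F1>P"))
  pos <- mx$loops[[which(vapply(mx$loops, `[[`, numeric(1), "sign") > 0)]]
  expect_equal(pos$sign, prod(pos$signs))

  # direct P-F0 predation edges do not change the maximal-loop census
  g2 <- mest_digraph(predator_on_F0 = TRUE)
  mx2 <- maximal_loops(enumerate_loops(g2))
  expect_equal(c(mx2$length, mx2$n_positive, mx2$n_negative), c(4, 1, 1))
})

test_that("adaptive-foraging strategies set the maximal-loop signs", {
  census <- function(strategy) {
    g <- mest_digraph(include_AF = TRUE, af_strategy = strategy)
    mx <- maximal_loops(enumerate_loops(g))
    c(len = mx$length, pos = mx$n_positive, neg = mx$n_negative)
  }
  # increase predation on C, reduce it on F1: two negative feedback loops
  expect_equal(census("inhibitC_promoteF1"), c(len = 5, pos = 0, neg = 2))
  # reduce predation on C, increase it on F1: two positive feedback loops
  expect_equal(census("promoteC_inhibitF1"), c(len = 5, pos = 2, neg = 0))
  # shift onto (or off) both prey: one positive and one negative loop
  expect_equal(census("both_promote"), c(len = 5, pos = 1, neg = 1))
  expect_equal(census("both_inhibit"), c(len = 5, pos = 1, neg = 1))
  expect_error(mest_digraph(include_AF = TRUE, af_strategy = "none"),
               "requires an AF strategy")
})

test_that("simple motifs enumerate correctly", {
  pp <- signed_digraph(data.frame(from = c("N", "P"), to = c("P", "N"),
                                  sign = c(1, -1)))
  loops <- enumerate_loops(pp)
  expect_length(loops, 1)
  expect_equal(loops[[1]]$sign, -1)
  expect_equal(loops[[1]]$length, 2)

  dag <- signed_digraph(data.frame(from = c("A", "A", "B"),
                                   to = c("B", "C", "C"),
                                   sign = c(1, -1, 1)))
  expect_length(enumerate_loops(dag), 0)
  expect_error(maximal_loops(enumerate_loops(dag)), "no loops")
})

test_that("enumeration matches brute-force permutation search on random graphs", {
  for (seed in 1:10) {
    g <- random_signed_digraph(5, p_edge = 0.45, seed = seed)
    mine <- enumerate_loops(g)
    ref <- brute_force_cycles(g)
    expect_equal(length(mine), length(ref))
    if (!length(mine)) next
    keyify <- function(nodes) {   # rotation-invariant cycle key
      k <- which.min(match(nodes, sort(nodes)))
      idx <- ((seq_along(nodes) + k - 2L) %% length(nodes)) + 1L
      paste(nodes[idx], collapse = ">")
    }
    k1 <- sort(paste(vapply(mine, function(l) keyify(l$nodes), character(1)),
                     vapply(mine, `[[`, numeric(1), "sign")))
    k2 <- sort(paste(vapply(ref, function(l) keyify(l$nodes), character(1)),
                     vapply(ref, `[[`, numeric(1), "sign")))
    expect_identical(k1, k2)
  }
})

test_that("loop signs are rotation-invariant products and flip with one edge", {
  g <- mest_digraph(include_AF = TRUE, af_strategy = "both_promote")
  loops <- enumerate_loops(g)
  for (l in loops) {
    expect_equal(l$sign, prod(l$signs))
    expect_true(l$sign %in% c(-1, 1))
  }
  # flipping one edge sign flips exactly the loops that traverse it
  e <- g$edges
  flip <- which(e$from == "F0" & e$to == "C")
  e$sign[flip] <- -e$sign[flip]
  g2 <- signed_digraph(e, nodes = g$nodes)
  l1 <- enumerate_loops(g)
  l2 <- enumerate_loops(g2)
  key <- function(l) paste(l$nodes, collapse = ">")
  s1 <- stats::setNames(vapply(l1, `[[`, numeric(1), "sign"),
                        vapply(l1, key, character(1)))
  s2 <- stats::setNames(vapply(l2, `[[`, numeric(1), "sign"),
                        vapply(l2, key, character(1)))
  for (k in names(s1)) {
    uses_edge <- grepl("F0>C", paste0(k, ">", sub(">.*", "", k)))
    expect_equal(unname(s2[k]), unname(if (uses_edge) -s1[k] else s1[k]))
  }
})

test_that("digraph validation and DOT export behave", {
  expect_error(signed_digraph(data.frame(from = "A", to = "A", sign = 1)),
               "self-loops")
  expect_error(signed_digraph(data.frame(from = "A", to = "B", sign = 2)),
               "signs")
  expect_error(signed_digraph(data.frame(from = c("A", "A"), to = c("B", "B"),
                                         sign = c(1, -1))), "one edge")
  g <- mest_digraph()
  dot <- digraph_dot(g)
  expect_match(dot, "digraph")
  expect_match(dot, "\"F0\" -> \"C\"", fixed = TRUE)
  f <- tempfile(fileext = ".dot")
  digraph_dot(g, f)
  expect_true(file.exists(f))
})
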