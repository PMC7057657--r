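test_that("graph edges use strict 1.4 mm threshold and deduplicate", {
  cl <- point_cloud(cbind(c(0, 1, 2), 0, 0))
  e <- build_graph(cl, 1.4)
  expect_equal(cbind(e$i, e$j), cbind(c(1L, 2L), c(2L, 3L)), ignore_attr = TRUE)
  # exactly at the threshold: no edge
  e2 <- build_graph(point_cloud(cbind(c(0, 1.4), 0, 0)), 1.4)
  expect_equal(nrow(e2), 0)
})

test_that("data term costs are non-negative and sum to R_S - R_L", {
  span <- log(1 / 3) - log(0.015)
  d1 <- data_term(log(0.015))
  expect_equal(unname(d1[1, ]), c(0, span))
  expect_lt(abs(span - 3.10109), 1e-5)
  d2 <- data_term(log(1 / 3))
  expect_equal(unname(d2[1, ]), c(span, 0))
  mid <- (log(0.015) + log(1 / 3)) / 2
  d3 <- data_term(mid)
  expect_equal(unname(d3[1, 1]), unname(d3[1, 2]))
  rs <- data_term(runif(50, log(0.015), log(1 / 3)))
  expect_true(all(rs >= 0))
  expect_equal(unname(rowSums(rs)), rep(span, 50))
  expect_error(data_term(0.5), "R_L")
})

test_that("smoothness penalty is the clamped max reciprocal curvature", {
  expect_equal(smoothness_term(1 / 3, 1 / 3), 3)
  expect_equal(smoothness_term(0, 1 / 3), 1 / 0.015, tolerance = 1e-12)
  expect_lt(abs(smoothness_term(0, 1 / 3) - 66.667), 1e-2)
  expect_equal(smoothness_term(0.1, 0.05), 20)
})

test_that("single node and two-node fixtures minimize as expected", {
  # isolated perfectly flat node: label L at zero energy
  pr <- mrf_problem(data_term(log(0.015)), matrix(0L, 0, 2), numeric(0),
                    w_D = 1, w_V = 1)
  sol <- minimize_energy(pr)
  expect_equal(sol$labels, "L")
  expect_equal(sol$energy, 0)
  # opposing unaries, expensive edge: agree on one label, energy 3.1
  pr2 <- mrf_problem(rbind(c(0, 3.1), c(3.1, 0)), cbind(1L, 2L), 10,
                     w_D = 1, w_V = 1)
  sol2 <- minimize_energy(pr2)
  expect_equal(length(unique(sol2$labels)), 1)
  expect_equal(sol2$energy, 3.1)
  expect_equal(brute_min_energy(pr2), 3.1)
})

test_that("min-cut energy equals exhaustive enumeration on random problems", {
  set.seed(20)
  for (rep in 1:60) {
    pr <- random_mrf_problem(max_nodes = 10)
    sol <- minimize_energy(pr)
    expect_equal(sol$energy, brute_min_energy(pr), tolerance = 1e-12)
    expect_equal(sol$flow, sol$energy, tolerance = 1e-9)
  }
})

test_that("solver flow matches an independent max-flow implementation", {
  skip_if_not_installed("igraph")
  set.seed(21)
  coords <- matrix(runif(900, 0, 15), ncol = 3)
  cl <- point_cloud(coords)
  d <- point_descriptors(cl, 2.5)
  e <- build_graph(cl, 2.5)
  pr <- mrf_problem(data_term(d$flatness), e,
                    smoothness_term(d$curvature[e$i], d$curvature[e$j]))
  sol <- minimize_energy(pr)
  n <- pr$n_nodes
  s <- n + 1L; t <- n + 2L
  from <- c(rep(s, n), 1:n, pr$edges[, 1], pr$edges[, 2])
  to <- c(1:n, rep(t, n), pr$edges[, 2], pr$edges[, 1])
  cap <- c(pr$w_D * pr$unary[, 2], pr$w_D * pr$unary[, 1],
           rep(pr$w_V * pr$pairwise, 2))
  g <- igraph::make_graph(rbind(from, to), n = t, directed = TRUE)
  f <- igraph::max_flow(g, s, t, capacity = cap)
  expect_equal(sol$flow, f$value, tolerance = 1e-9)
  expect_equal(sol$energy, f$value, tolerance = 1e-9)
})

test_that("increasing w_V never increases label disagreements", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 8
    pairs <- t(utils::combn(n, 2))
    edges <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    un <- matrix(runif(2 * n, 0, 3.2), n, 2)
    pw <- runif(nrow(edges), 0, 5)
    disagreements <- vapply(c(0, 0.05, 0.2, 1, 5), function(wv) {
      sol <- minimize_energy(mrf_problem(un, edges, pw, w_D = 1, w_V = wv))
      sum(sol$labels[edges[, 1]] != sol$labels[edges[, 2]])
    }, numeric(1))
    expect_true(all(diff(disagreements) <= 0))
  }
})

test_that("degenerate weight limits behave as expected", {
  set.seed(23)
  n <- 12
  un <- matrix(runif(2 * n, 0, 3), n, 2)
  edges <- cbind(1:(n - 1), 2:n)
  pw <- runif(n - 1, 0.5, 3)
  # w_V = 0: independent per-node argmin
  sol0 <- minimize_energy(mrf_problem(un, edges, pw, w_D = 1, w_V = 0))
  expect_equal(sol0$labels, ifelse(un[, 1] <= un[, 2], "L", "S"))
  expect_equal(sol0$energy, sum(pmin(un[, 1], un[, 2])))
  # w_D = 0: a constant labeling on the (connected) graph has energy 0
  solc <- minimize_energy(mrf_problem(un, edges, pw, w_D = 0, w_V = 1))
  expect_equal(solc$energy, 0)
  expect_equal(length(unique(solc$labels)), 1)
})

test_that("reported energy is recomputable from the labeling", {
  set.seed(24)
  for (rep in 1:20) {
    pr <- random_mrf_problem(max_nodes = 12)
    sol <- minimize_energy(pr)
    expect_equal(sol$energy, mrf_energy(pr, sol$labels),
                 tolerance = 1e-9)
  }
})

test_that("unsupervised segmentation labels sheets leaf and tubes stem", {
  sheet <- sheet_cloud(side = 15, step = 0.5)
  seg_sheet <- segment_lfpc_u(sheet)
  expect_true(all(seg_sheet$pred == organ_code("leaf")))
  tube <- tube_cloud(r = 1, len = 25, step = 0.45)
  seg_tube <- segment_lfpc_u(tube)
  expect_gt(mean(seg_tube$pred == organ_code("stem")), 0.5)
})

test_that("mrf_problem validates edges and pairwise signs", {
  un <- matrix(1, 3, 2)
  expect_error(mrf_problem(un, cbind(1L, 4L), 1), "out of range")
  expect_error(mrf_problem(un, rbind(c(1L, 2L), c(2L, 1L)), 1), "duplicated")
  expect_error(mrf_problem(un, cbind(2L, 2L), 1), "self-loop")
  expect_error(mrf_problem(un, cbind(1L, 2L), -0.1), "non-negative")
})
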