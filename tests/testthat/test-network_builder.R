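# brute-force count of vertex pairs within the cutoff radius
lattice_edge_oracle <- function(rows, cols, radius = sqrt(2)) {
  pos <- expand.grid(x = 0:(cols - 1), y = 0:(rows - 1))
  cnt <- 0L
  for (i in seq_len(nrow(pos) - 1))
    for (j in (i + 1):nrow(pos))
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= radius + 1e-9) cnt <- cnt + 1L
  cnt
}

test_that("lattice edge counts match the brute-force distance oracle", {
  expect_equal(nrow(undirected_edges(build_regular_lattice(10, 10))), 342L)
  expect_equal(nrow(undirected_edges(build_regular_lattice(2, 2))), 6L)
  expect_equal(nrow(undirected_edges(build_regular_lattice(3, 3))), 20L)
  for (dims in list(c(2, 5), c(4, 4), c(5, 7), c(12, 12))) {
    net <- build_regular_lattice(dims[1], dims[2])
    expect_equal(nrow(undirected_edges(net)),
                 lattice_edge_oracle(dims[1], dims[2]))
  }
})

test_that("lattice is fully recurrent, zero-diagonal, and rejects bad dims", {
  net <- build_regular_lattice(4, 6)
  expect_true(all(net$adjacency == t(net$adjacency)))
  expect_true(all(diag(net$adjacency) == 0))
  expect_error(build_regular_lattice(1, 5))
  expect_error(build_regular_lattice(3, 0))
  expect_error(build_regular_lattice(3, 3, radius = -1))
})

test_that("rewiring preserves the undirected edge count and recurrence", {
  set.seed(1)
  net <- build_regular_lattice(10, 10)
  expect_identical(rewire_small_world(net, 0)$adjacency, net$adjacency)
  for (p in c(0.3, 1)) {
    rw <- rewire_small_world(net, p)
    expect_true(all(rw$adjacency == t(rw$adjacency)))
    expect_true(all(diag(rw$adjacency) == 0))
    expect_equal(nrow(undirected_edges(rw)), 342L)
  }
})

test_that("mean rewired-edge count matches the binomial expectation", {
  set.seed(99)
  net <- build_regular_lattice(10, 10)
  moved <- replicate(200, {
    rw <- rewire_small_world(net, 0.4)
    sum(pmax(net$adjacency - rw$adjacency, 0)) / 2
  })
  # binomial mean 0.4 * 342 = 136.8, sd of the mean ~ 0.64; allow 4 sigma
  # (a rewiring draw can land back on the original pair, slightly lowering
  #  the observed count, so compare with generous width)
  expect_gt(mean(moved), 130)
  expect_lt(mean(moved), 140)
})

test_that("recurrence reduction deletes an exact count with canonical direction", {
  set.seed(2)
  net <- rewire_small_world(build_regular_lattice(10, 10), 0.4)
  expect_identical(reduce_recurrence(net, 0)$adjacency, net$adjacency)
  for (p_r in c(0.25, 0.4, 0.7, 1)) {
    red <- reduce_recurrence(net, p_r)
    expect_equal(sum(red$adjacency), 2 * 342 - round(p_r * 342))
    expect_true(all(diag(red$adjacency) == 0))
    # recurrent pair count drops by exactly the selected count
    expect_equal(sum(red$adjacency * t(red$adjacency)) / 2,
                 342 - round(p_r * 342))
  }
})

test_that("p_r = 0.4 leaves 60% of synaptic connections recurrent", {
  set.seed(3)
  net <- rewire_small_world(build_regular_lattice(10, 10), 0.4)
  red <- reduce_recurrence(net, 0.4)
  # proportion of the 342 connected pairs that remain recurrent:
  # (342 - round(0.4 * 342)) / 342 = 205/342, i.e. 60% to printed precision
  n_recurrent_pairs <- sum(red$adjacency * t(red$adjacency)) / 2
  expect_equal(n_recurrent_pairs, 342 - round(0.4 * 342))
  expect_equal(round(100 * n_recurrent_pairs / 342), 60)
})

test_that("full recurrence reduction with p_d 0 or 1 yields an acyclic digraph", {
  set.seed(4)
  net <- rewire_small_world(build_regular_lattice(8, 8), 0.4)
  for (p_d in c(0, 1)) {
    red <- reduce_recurrence(net, 1, p_d)
    expect_true(igraph::is_dag(as_igraph(red)))
  }
})

test_that("type and weight assignment follows the stated distributions", {
  set.seed(5)
  net <- build_structural_network()
  expect_equal(sum(net$neuron_type == "inhibitory"), 20L)
  inh <- which(net$neuron_type == "inhibitory")
  inh_w <- net$weights[, inh][net$adjacency[, inh] == 1]
  expect_true(all(inh_w == -1.5))
  exc <- which(net$neuron_type == "excitatory")
  exc_w <- net$weights[, exc][net$adjacency[, exc] == 1]
  expect_true(all(exc_w > 0))
  expect_error(assign_types_and_weights(net, inhibitory_fraction = 1.2))
})

test_that("excitatory weight sampler has the right mean over many edges", {
  set.seed(6)
  big <- build_regular_lattice(40, 40)          # 6162 undirected edges
  big <- assign_types_and_weights(big, inhibitory_fraction = 0)
  w <- big$weights[big$adjacency == 1]
  expect_gt(length(w), 1e4)
  expect_lt(abs(mean(w) - 3.1), 0.01)
  expect_lt(abs(sd(w) - 0.1), 0.01)
})

test_that("edge-list CSV round-trips the adjacency and weights", {
  set.seed(7)
  net <- build_structural_network(rows = 4, cols = 4)
  path <- tempfile(fileext = ".csv")
  write_edgelist_csv(net, path)
  back <- read_edgelist_csv(path, net$n)
  expect_identical(back$adjacency, net$adjacency)
  expect_equal(back$weights, net$weights)
})
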