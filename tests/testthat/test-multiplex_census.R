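random_digraph <- function(n, p = 0.2) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

test_that("supra-adjacency is the documented block matrix", {
  set.seed(41)
  S <- random_digraph(3); F_ <- random_digraph(3)
  M <- build_multiplex(S, F_)
  sup <- supra_adjacency(M)
  expect_equal(dim(sup), c(6L, 6L))
  expect_equal(sup[1:3, 1:3], S, ignore_attr = TRUE)
  expect_equal(sup[4:6, 4:6], F_, ignore_attr = TRUE)
  expect_equal(sup[1:3, 4:6], diag(1L, 3), ignore_attr = TRUE)
  expect_equal(sup[4:6, 1:3], diag(1L, 3), ignore_attr = TRUE)
  expect_error(build_multiplex(random_digraph(3), random_digraph(4)))
})

test_that("dyad classification counts edges", {
  empty <- matrix(0L, 2, 2)
  single <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  mutual <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_equal(classify_dyad(empty), 1L)
  expect_equal(classify_dyad(single), 2L)
  expect_equal(classify_dyad(mutual), 3L)
})

test_that("the 64 labeled 3-vertex digraphs partition into 16 classes of known sizes", {
  classes <- vapply(0:63, function(code)
    classify_triad(spikemotif:::triad_code_to_matrix(code)), integer(1))
  expect_equal(length(unique(classes)), 16L)
  expect_equal(tabulate(classes, 16),
               c(1, 6, 3, 3, 3, 6, 6, 6, 6, 2, 3, 3, 3, 6, 6, 1))
  expect_equal(classify_triad(matrix(0L, 3, 3)), 1L)
  expect_equal(classify_triad(matrix(1L, 3, 3) - diag(1L, 3)), 16L)
})

test_that("triad classification is invariant under vertex permutation", {
  set.seed(42)
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  for (code in sample(0:63, 20)) {
    m <- spikemotif:::triad_code_to_matrix(code)
    cl <- classify_triad(m)
    for (p in perms) expect_equal(classify_triad(m[p, p]), cl)
  }
})

test_that("triad classes agree with the igraph census on random digraphs", {
  set.seed(43)
  for (rep in 1:5) {
    A <- random_digraph(20, 0.15)
    g <- igraph::graph_from_adjacency_matrix(t(A), mode = "directed")
    ours <- tabulate(spikemotif:::triad_class_vector(A, 20L), 16)
    expect_equal(ours, as.vector(igraph::triad_census(g)))
  }
})

test_that("the dyadic transformation reduction yields exactly 10 classes", {
  states <- expand.grid(s = 0:3, f = 0:3)
  cls <- spikemotif:::dyad_pair_class(states$s, states$f)
  expect_equal(length(unique(cls)), 10L)
  # swap-equivalence: exchanging directions 1<->2 in BOTH layers preserves class
  swp <- c(0L, 2L, 1L, 3L)
  expect_equal(spikemotif:::dyad_pair_class(swp[states$s + 1], swp[states$f + 1]),
               cls)
  # direction preservation vs reversal are distinct classes
  expect_false(spikemotif:::dyad_pair_class(1, 1) ==
                 spikemotif:::dyad_pair_class(1, 2))
})

test_that("censuses conserve totals and concentrate on the diagonal when F = S", {
  set.seed(44)
  n <- 30
  S <- random_digraph(n, 0.2)
  M_id <- build_multiplex(S, S)
  dy <- dyadic_census(M_id)
  expect_equal(sum(dy), choose(n, 2))
  expect_equal(sum(dy[c("1->1", "2->2", "3->3")]), choose(n, 2))
  tri <- triadic_census(M_id)
  expect_equal(dim(tri), c(16L, 16L))
  expect_equal(sum(tri), choose(n, 3))
  expect_equal(sum(diag(tri)), choose(n, 3))
  # a distinct functional layer still conserves totals
  M2 <- build_multiplex(S, random_digraph(n, 0.2))
  expect_equal(sum(dyadic_census(M2)), choose(n, 2))
  expect_equal(sum(triadic_census(M2)), choose(n, 3))
})

test_that("census counts are invariant under simultaneous relabeling", {
  set.seed(45)
  n <- 15
  S <- random_digraph(n); F_ <- random_digraph(n)
  p <- sample(n)
  M1 <- build_multiplex(S, F_)
  M2 <- build_multiplex(S[p, p], F_[p, p])
  expect_equal(dyadic_census(M1), dyadic_census(M2))
  expect_equal(triadic_census(M1), triadic_census(M2))
})

test_that("dyadic census equals the triadic census pair-marginal", {
  set.seed(46)
  n <- 20
  M <- build_multiplex(random_digraph(n), random_digraph(n))
  dy <- dyadic_census(M)
  # each unordered pair lies in n - 2 triples; recount pairs by brute force
  # over triples and compare against (n - 2) * dyadic counts
  brute <- setNames(numeric(10), names(dy))
  for (tr in utils::combn(n, 3, simplify = FALSE)) {
    for (pr in list(tr[1:2], tr[2:3], tr[c(1, 3)])) {
      x <- pr[1]; y <- pr[2]
      s <- M$structural[y, x] + 2L * M$structural[x, y]
      f <- M$functional[y, x] + 2L * M$functional[x, y]
      cl <- as.character(spikemotif:::dyad_pair_class(s, f))
      brute[cl] <- brute[cl] + 1
    }
  }
  expect_equal(brute / (n - 2), as.numeric(dy), ignore_attr = TRUE)
})

test_that("edge discrepancies are the exact set differences", {
  S <- matrix(0L, 3, 3); S[2, 1] <- 1L            # x -> y
  F_ <- matrix(0L, 3, 3); F_[2, 1] <- 1L; F_[3, 2] <- 1L  # adds y -> z
  d <- edge_discrepancies(build_multiplex(S, F_))
  expect_equal(nrow(d$false_negatives), 0L)
  expect_equal(d$false_positives,
               data.frame(source = 2L, target = 3L), ignore_attr = TRUE)
  # F = S leaves both sets empty; FP + TP partitions the functional edges
  set.seed(47)
  A <- random_digraph(10); B <- random_digraph(10)
  M <- build_multiplex(A, B)
  d2 <- edge_discrepancies(M)
  expect_equal(nrow(d2$false_positives) + sum(A & B), sum(B))
  d3 <- edge_discrepancies(build_multiplex(A, A))
  expect_equal(nrow(d3$false_positives) + nrow(d3$false_negatives), 0L)
})

test_that("adding one FP changes n - 2 triple classes and one pair class", {
  set.seed(48)
  n <- 12
  S <- random_digraph(n, 0.15)
  F1 <- S
  spot <- which(S == 0 & row(S) != col(S))[5]
  F2 <- F1; F2[spot] <- 1L
  t1 <- spikemotif:::triad_class_vector(F1, n)
  t2 <- spikemotif:::triad_class_vector(F2, n)
  expect_equal(sum(t1 != t2), n - 2L)
  d1 <- dyadic_census(build_multiplex(S, F1))
  d2 <- dyadic_census(build_multiplex(S, F2))
  expect_equal(sum(abs(d2 - d1)), 2)  # one pair moved between two classes
})

test_that("census CSV export has the tidy shape", {
  set.seed(49)
  M <- build_multiplex(random_digraph(8), random_digraph(8))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_census_csv(dyadic_census(M), p1)
  write_census_csv(triadic_census(M), p2)
  expect_equal(nrow(utils::read.csv(p1)), 10L)
  tri <- utils::read.csv(p2)
  expect_equal(nrow(tri), 256L)
  expect_equal(sum(tri$count), choose(8, 3))
})
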