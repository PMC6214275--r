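#' Multiplex pairing of structural and functional layers and the
#' subgraph-transformation census
#'
#' The structural layer S and functional layer F share one vertex set;
#' the supra-adjacency view is the 2n x 2n block matrix with A_s and A_f
#' on the diagonal and identity off-diagonal blocks (interlayer edges
#' join each vertex to its own copy).  Dyads fall into 3 isomorphism
#' classes and triads into 16; a structural-to-functional transformation
#' is the pair of classes observed on the same vertices across layers:
#' 10 nonisomorphic dyadic transformations (under simultaneous vertex
#' swap) and 256 triadic pairs.
#'
#' @name multiplex_census
NULL

# ---- class tables -------------------------------------------------------

#' Names of the ten dyadic transformation classes
#' @export
dyadic_class_names <- function() {
  c("1->1", "1->2", "1->3", "2->1", "2->2", "2->2*", "2->3",
    "3->1", "3->2", "3->3")
}

# dyad pair state on an unordered pair (x < y): 0 empty, 1 x->y, 2 y->x,
# 3 mutual. Simultaneous swap of both layers exchanges states 1 and 2.
dyad_pair_class <- function(s, f) {
  sc <- c(1L, 2L, 2L, 3L)[s + 1L]
  fc <- c(1L, 2L, 2L, 3L)[f + 1L]
  lab <- ifelse(sc == 2L & fc == 2L,
                ifelse(s == f, "2->2", "2->2*"),
                paste0(sc, "->", fc))
  factor(lab, levels = dyadic_class_names())
}

# 6-bit triad code from a 3x3 adjacency (A[i,j] = 1 iff j -> i):
# bits (x->y, x->z, y->x, y->z, z->x, z->y)
triad_code <- function(m) {
  m[2, 1] + 2L * m[3, 1] + 4L * m[1, 2] + 8L * m[3, 2] +
    16L * m[1, 3] + 32L * m[2, 3]
}

triad_code_to_matrix <- function(code) {
  b <- as.integer(intToBits(code))[1:6]
  m <- matrix(0L, 3, 3)
  m[2, 1] <- b[1]; m[3, 1] <- b[2]; m[1, 2] <- b[3]
  m[3, 2] <- b[4]; m[1, 3] <- b[5]; m[2, 3] <- b[6]
  m
}

# canonical representatives of the 16 triad classes (vertices x, y, z):
# 1 empty; 2 x->y; 3 x<->y; 4 out-hub {x->y, x->z}; 5 in-star {y->x, z->x};
# 6 chain {x->y, y->z}; 7 {x<->y, z->x}; 8 {x<->y, x->z};
# 9 feed-forward; 10 cycle; 11 {x<->y, x<->z}; 12 {x<->y, z->x, z->y};
# 13 {x<->y, x->z, y->z}; 14 {x<->y, x->z, z->y}; 15 {x<->y, x->z, y<->z};
# 16 complete. This is the standard directed triad census ordering.
triad_representatives <- function() {
  edges <- list(
    list(),
    list(c(1, 2)),
    list(c(1, 2), c(2, 1)),
    list(c(1, 2), c(1, 3)),
    list(c(2, 1), c(3, 1)),
    list(c(1, 2), c(2, 3)),
    list(c(1, 2), c(2, 1), c(3, 1)),
    list(c(1, 2), c(2, 1), c(1, 3)),
    list(c(1, 2), c(2, 3), c(1, 3)),
    list(c(1, 2), c(2, 3), c(3, 1)),
    list(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),
    list(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),
    list(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),
    list(c(1, 2), c(2, 1), c(1, 3), c(3, 2)),
    list(c(1, 2), c(2, 1), c(1, 3), c(2, 3), c(3, 2)),
    list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  vapply(edges, function(es) {
    m <- matrix(0L, 3, 3)
    for (e in es) m[e[2], e[1]] <- 1L   # e = (from, to) -> A[to, from]
    triad_code(m)
  }, integer(1))
}

# lookup[code + 1] = triad class of the labeled 3-vertex digraph `code`,
# built once by canonicalizing all 64 codes over the 6 vertex permutations
.spikemotif_env <- new.env(parent = emptyenv())

triad_lookup <- function() {
  if (!is.null(.spikemotif_env$triad_lookup)) return(.spikemotif_env$triad_lookup)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  canon <- vapply(0:63, function(code) {
    m <- triad_code_to_matrix(code)
    min(vapply(perms, function(p) triad_code(m[p, p]), integer(1)))
  }, integer(1))
  reps <- triad_representatives()
  class_of_canon <- canon[reps + 1L]
  if (anyDuplicated(class_of_canon))
    stop("internal error: triad representatives are not pairwise nonisomorphic")
  lookup <- match(canon, class_of_canon)
  if (anyNA(lookup))
    stop("internal error: triad canonicalization missed a class")
  .spikemotif_env$triad_lookup <- as.integer(lookup)
  .spikemotif_env$triad_lookup
}

#' Classify a dyad
#'
#' @param a_pair 2x2 binary adjacency of the vertex pair.
#' @return class 1 (empty), 2 (single directed edge) or 3 (recurrent).
#' @export
classify_dyad <- function(a_pair) {
  stopifnot(all(dim(a_pair) == c(2, 2)))
  ne <- a_pair[1, 2] + a_pair[2, 1]
  as.integer(ne + 1L)
}

#' Classify a triad
#'
#' Canonical-form lookup of a 3-vertex directed adjacency into the 16
#' isomorphism classes (standard directed triad census ordering; class 4
#' is the out-hub, 5 the in-star, 6 the chain, 16 the complete triad).
#'
#' @param a_triple 3x3 binary adjacency (\code{[i, j] = 1} iff j -> i).
#' @return class label in 1..16.
#' @export
classify_triad <- function(a_triple) {
  stopifnot(all(dim(a_triple) == c(3, 3)))
  triad_lookup()[triad_code(a_triple) + 1L]
}

# ---- multiplex ----------------------------------------------------------

#' Pair a structural and a functional layer into a multiplex network
#'
#' @param S structural layer (\code{structural_network} or binary matrix).
#' @param F_ functional layer (\code{functional_network} or binary matrix).
#' @return a \code{multiplex_network}: list with \code{structural},
#'   \code{functional} (adjacency matrices) and \code{n}.
#' @export
build_multiplex <- function(S, F_) {
  As <- if (is.list(S)) S$adjacency else S
  Af <- if (is.list(F_)) F_$adjacency else F_
  if (!all(dim(As) == dim(Af)))
    stop("structural and functional layers must share the vertex set")
  structure(list(structural = As, functional = Af, n = nrow(As),
                 kappa = if (is.list(F_)) F_$kappa else NA,
                 method = if (is.list(F_)) F_$method else NA),
            class = "multiplex_network")
}

#' Supra-adjacency matrix of a multiplex network
#'
#' 2n x 2n block matrix: structural vertices first (rows/cols 1..n),
#' functional copies second; identity off-diagonal blocks.
#'
#' @param M a \code{multiplex_network}.
#' @export
supra_adjacency <- function(M) {
  n <- M$n
  rbind(cbind(M$structural, diag(1L, n)),
        cbind(diag(1L, n), M$functional))
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("<multiplex_network> ", x$n, " vertices; |E_s| = ",
      sum(x$structural), ", |E_f| = ", sum(x$functional), "\n", sep = "")
  invisible(x)
}

# cached unordered pair/triple linear-index sets per vertex count
pair_indices <- function(n) {
  key <- paste0("pairs", n)
  if (is.null(.spikemotif_env[[key]])) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # x = row < y = col
    x <- idx[, 1]; y <- idx[, 2]
    .spikemotif_env[[key]] <- list(
      fwd = (x - 1L) * n + y,   # A[y, x]: edge x -> y
      rev = (y - 1L) * n + x)   # A[x, y]: edge y -> x
  }
  .spikemotif_env[[key]]
}

triple_indices <- function(n) {
  key <- paste0("triples", n)
  if (is.null(.spikemotif_env[[key]])) {
    tr <- t(utils::combn(n, 3))
    x <- tr[, 1]; y <- tr[, 2]; z <- tr[, 3]
    lin <- function(r, c) (c - 1L) * n + r
    .spikemotif_env[[key]] <- list(
      b = list(lin(y, x), lin(z, x), lin(x, y),
               lin(z, y), lin(x, z), lin(y, z)))
  }
  .spikemotif_env[[key]]
}

triad_class_vector <- function(A, n) {
  b <- triple_indices(n)$b
  code <- A[b[[1]]] + 2L * A[b[[2]]] + 4L * A[b[[3]]] +
    8L * A[b[[4]]] + 16L * A[b[[5]]] + 32L * A[b[[6]]]
  triad_lookup()[code + 1L]
}

#' Dyadic transformation census
#'
#' Counts, over every unordered vertex pair, the (structural state,
#' functional state) combination reduced under simultaneous vertex swap
#' to one of the 10 dyadic transformation classes.  Counts sum to
#' \code{choose(n, 2)}.
#'
#' @param M a \code{multiplex_network}.
#' @return named integer vector over \code{\link{dyadic_class_names}}.
#' @export
dyadic_census <- function(M) {
  pi_ <- pair_indices(M$n)
  s <- M$structural[pi_$fwd] + 2L * M$structural[pi_$rev]
  f <- M$functional[pi_$fwd] + 2L * M$functional[pi_$rev]
  table(dyad_pair_class(s, f)) |> c()
}

#' Triadic transformation census
#'
#' Counts, over every unordered vertex triple, the pair
#' (structural triad class, functional triad class); a 16 x 16 table
#' whose entries sum to \code{choose(n, 3)}.
#'
#' @param M a \code{multiplex_network}.
#' @return 16 x 16 integer matrix, rows = structural class, cols =
#'   functional class.
#' @export
triadic_census <- function(M) {
  cs <- triad_class_vector(M$structural, M$n)
  cf <- triad_class_vector(M$functional, M$n)
  counts <- tabulate((cs - 1L) * 16L + cf, nbins = 256L)
  matrix(counts, 16, 16, byrow = TRUE,
         dimnames = list(structural = 1:16, functional = 1:16))
}

#' False positives and false negatives of a functional reconstruction
#'
#' FP = directed edges present in the functional layer but absent from
#' the structural layer; FN = structural edges missing functionally.
#'
#' @param M a \code{multiplex_network}.
#' @return list of two data frames (\code{false_positives},
#'   \code{false_negatives}) with 1-based \code{source}, \code{target}.
#' @export
edge_discrepancies <- function(M) {
  as_pairs <- function(idx) {
    data.frame(source = idx[, 2], target = idx[, 1])
  }
  fp <- which(M$functional == 1L & M$structural == 0L, arr.ind = TRUE)
  fn <- which(M$structural == 1L & M$functional == 0L, arr.ind = TRUE)
  list(false_positives = as_pairs(fp), false_negatives = as_pairs(fn))
}

#' Write a census table as tidy CSV
#'
#' Dyadic censuses get columns \code{transformation,count}; triadic
#' censuses \code{structural_class,functional_class,count} (256 rows).
#'
#' @param census output of \code{\link{dyadic_census}} or
#'   \code{\link{triadic_census}}.
#' @param path output file.
#' @export
write_census_csv <- function(census, path) {
  df <- if (is.matrix(census)) {
    data.frame(structural_class = rep(1:16, each = 16),
               functional_class = rep(1:16, times = 16),
               count = as.vector(t(census)))
  } else {
    data.frame(transformation = names(census), count = as.vector(census))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
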