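#' Structural spiking-network constructors
#'
#' A structural network is a directed graph of synaptic connections among
#' neurons placed on a 2-D grid.  Construction proceeds in four stages:
#' a distance-based regular lattice (fully recurrent), Watts-Strogatz
#' rewiring of undirected edges, recurrence reduction (deleting one
#' direction of a controlled proportion of undirected edges), and
#' excitatory/inhibitory type and synaptic-weight assignment.
#'
#' The adjacency convention throughout the package is \code{A[i, j] == 1}
#' iff there is a directed edge from neuron \code{j} to neuron \code{i}.
#' An \emph{undirected} (recurrent) edge is a reciprocal pair of directed
#' edges.
#'
#' @name structural_network
NULL

new_structural_network <- function(n, adjacency, positions,
                                   neuron_type = NULL, weights = NULL,
                                   params = list()) {
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  structure(
    list(n = n,
         adjacency = adjacency,
         positions = positions,
         neuron_type = neuron_type,
         weights = weights,
         params = params),
    class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  ne <- sum(x$adjacency)
  nu <- nrow(undirected_edges(x))
  cat("<structural_network> ", x$n, " neurons, ", ne, " directed edges (",
      sum(x$adjacency * t(x$adjacency)) / 2, " recurrent pairs, ",
      nu, " undirected units)\n", sep = "")
  if (!is.null(x$neuron_type))
    cat("  types: ", sum(x$neuron_type == "excitatory"), " excitatory / ",
        sum(x$neuron_type == "inhibitory"), " inhibitory\n", sep = "")
  invisible(x)
}

#' Build a regular 2-D lattice network
#'
#' Places \code{rows * cols} neurons on an integer grid and connects every
#' pair of neurons at Euclidean distance \code{<= radius} by an undirected
#' edge (a reciprocal pair of directed edges).  No periodic boundaries:
#' interior neurons have eight neighbours at the default radius, boundary
#' neurons five, corner neurons three.  A 10 x 10 grid at radius
#' \code{sqrt(2)} has 342 undirected edges.
#'
#' @param rows,cols grid dimensions (each >= 2).
#' @param radius Euclidean neighbour cutoff; default \code{sqrt(2)} links
#'   rook and bishop neighbours.
#' @return A \code{structural_network}, fully recurrent.
#' @export
build_regular_lattice <- function(rows, cols, radius = sqrt(2)) {
  if (length(rows) != 1L || length(cols) != 1L ||
      !is.finite(rows) || !is.finite(cols) || rows < 2 || cols < 2)
    stop("rows and cols must be >= 2")
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be > 0")
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  # neuron i at (x, y), column-major over x = 0..cols-1, y = 0..rows-1
  pos <- cbind(x = rep(0:(cols - 1L), each = rows),
               y = rep(0:(rows - 1L), times = cols))
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  A <- matrix(0L, n, n)
  A[d2 <= radius^2 + 1e-9] <- 1L
  diag(A) <- 0L
  new_structural_network(n, A, pos,
                         params = list(rows = rows, cols = cols,
                                       radius = radius))
}

#' Undirected edge list of a network
#'
#' Returns the undirected-edge view used by the rewiring and
#' recurrence-reduction stages: one row per vertex pair connected in at
#' least one direction, in canonical order (lower index first).
#'
#' @param net a \code{structural_network}.
#' @param recurrent_only if TRUE, only reciprocal (recurrent) pairs.
#' @return two-column integer matrix (\code{from < to}).
#' @export
undirected_edges <- function(net, recurrent_only = FALSE) {
  A <- net$adjacency
  M <- if (recurrent_only) A * t(A) else pmax(A, t(A))
  idx <- which(upper.tri(M) & M == 1L, arr.ind = TRUE)
  cbind(from = idx[, 1], to = idx[, 2])
}

#' Watts-Strogatz rewiring of a recurrent lattice
#'
#' Each undirected edge is independently rewired with probability
#' \code{p_rw}: one endpoint (chosen uniformly) is kept, the other is
#' replaced by a vertex drawn uniformly at random, redrawing on self-loops
#' and already-connected pairs.  Edges are rewired as undirected units, so
#' the network stays fully recurrent and the undirected edge count is
#' unchanged.  \code{p_rw = 0} leaves the network untouched; \code{p_rw = 1}
#' randomizes it completely.
#'
#' Uses the R random number generator; seed with \code{set.seed()}.
#'
#' @param net fully recurrent \code{structural_network}.
#' @param p_rw rewiring probability in [0, 1].
#' @return the rewired \code{structural_network}.
#' @export
rewire_small_world <- function(net, p_rw) {
  stopifnot(p_rw >= 0, p_rw <= 1)
  A <- net$adjacency
  if (any(A != t(A)))
    stop("rewire_small_world() expects a fully recurrent network")
  n <- net$n
  edges <- undirected_edges(net)
  do_rw <- stats::runif(nrow(edges)) < p_rw
  for (e in which(do_rw)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    keep <- if (stats::runif(1) < 0.5) u else v
    drop <- if (keep == u) v else u
    repeat {
      w <- sample.int(n, 1L)
      if (w != keep && w != drop && A[w, keep] == 0L) break
    }
    A[v, u] <- A[u, v] <- 0L
    A[w, keep] <- A[keep, w] <- 1L
    edges[e, ] <- c(min(keep, w), max(keep, w))
  }
  out <- net
  out$adjacency <- A
  out$params$p_rw <- p_rw
  out
}

#' Reduce recurrence by deleting one direction of selected edges
#'
#' Chooses exactly \code{round(p_r * E)} of the \code{E} undirected edges
#' without replacement and deletes one direction of each: the canonical
#' direction (lower index to higher index) with probability \code{p_d},
#' the reverse otherwise.  The directed edge count afterwards is exactly
#' \code{2 * E - round(p_r * E)}.  With \code{p_r = 0} the network stays
#' fully recurrent; with \code{p_r = 1} and \code{p_d} 0 or 1 the result
#' is acyclic.
#'
#' @param net recurrent \code{structural_network}.
#' @param p_r proportion of undirected edges made unidirectional.
#' @param p_d probability that the canonical (low-to-high) direction is
#'   the deleted one; default 0.5 (no preference).
#' @return the reduced \code{structural_network}.
#' @export
reduce_recurrence <- function(net, p_r, p_d = 0.5) {
  stopifnot(p_r >= 0, p_r <= 1, p_d >= 0, p_d <= 1)
  A <- net$adjacency
  edges <- undirected_edges(net, recurrent_only = TRUE)
  E <- nrow(edges)
  m <- round(p_r * E)
  if (m > 0) {
    chosen <- sample.int(E, m, replace = FALSE)
    del_canonical <- stats::runif(m) < p_d
    for (s in seq_len(m)) {
      u <- edges[chosen[s], 1]; v <- edges[chosen[s], 2]  # u < v
      if (del_canonical[s]) A[v, u] <- 0L else A[u, v] <- 0L
    }
  }
  out <- net
  out$adjacency <- A
  out$params$p_r <- p_r
  out$params$p_d <- p_d
  out
}

#' Assign excitatory/inhibitory types and synaptic weights
#'
#' Flags \code{round(inhibitory_fraction * n)} neurons (placed uniformly
#' at random) as inhibitory.  Each directed edge leaving an excitatory
#' neuron receives an independent Gaussian synaptic amplitude
#' (mean 3.1 mV, sd 0.1 mV by default, drawn per directed synapse);
#' every edge leaving an inhibitory neuron gets the fixed amplitude
#' \code{v_inh} (-1.5 mV).
#'
#' @param net \code{structural_network} with finalized adjacency.
#' @param inhibitory_fraction fraction of inhibitory neurons (default 0.2).
#' @param weight_mean,weight_sd excitatory amplitude distribution (mV).
#' @param v_inh inhibitory amplitude (mV, negative).
#' @return the typed, weighted \code{structural_network}.
#' @export
assign_types_and_weights <- function(net, inhibitory_fraction = 0.2,
                                     weight_mean = 3.1, weight_sd = 0.1,
                                     v_inh = -1.5) {
  if (inhibitory_fraction < 0 || inhibitory_fraction > 1)
    stop("inhibitory_fraction must lie in [0, 1]")
  n <- net$n
  n_inh <- round(inhibitory_fraction * n)
  type <- rep("excitatory", n)
  if (n_inh > 0) type[sample.int(n, n_inh)] <- "inhibitory"
  A <- net$adjacency
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    post <- which(A[, j] == 1L)
    if (!length(post)) next
    W[post, j] <- if (type[j] == "inhibitory") v_inh
                  else stats::rnorm(length(post), weight_mean, weight_sd)
  }
  out <- net
  out$neuron_type <- type
  out$weights <- W
  out$params$inhibitory_fraction <- inhibitory_fraction
  out$params$weight_mean <- weight_mean
  out$params$weight_sd <- weight_sd
  out$params$v_inh <- v_inh
  out
}

#' One-call structural network construction
#'
#' Runs the four construction stages in order: lattice, small-world
#' rewiring, recurrence reduction, type/weight assignment.
#'
#' @inheritParams build_regular_lattice
#' @inheritParams rewire_small_world
#' @inheritParams reduce_recurrence
#' @inheritParams assign_types_and_weights
#' @return a finalized \code{structural_network}.
#' @export
build_structural_network <- function(rows = 10, cols = 10, radius = sqrt(2),
                                     p_rw = 0.4, p_r = 0.4, p_d = 0.5,
                                     inhibitory_fraction = 0.2,
                                     weight_mean = 3.1, weight_sd = 0.1,
                                     v_inh = -1.5) {
  net <- build_regular_lattice(rows, cols, radius)
  net <- rewire_small_world(net, p_rw)
  net <- reduce_recurrence(net, p_r, p_d)
  assign_types_and_weights(net, inhibitory_fraction,
                           weight_mean, weight_sd, v_inh)
}

#' Convert a network layer to an igraph object
#'
#' @param x a \code{structural_network} or \code{functional_network}.
#' @return a directed \code{igraph} graph (edge j -> i for A[i, j] = 1).
#' @export
as_igraph <- function(x) {
  A <- x$adjacency
  # our convention is column -> row; igraph's from_adjacency is row -> col
  g <- igraph::graph_from_adjacency_matrix(t(A), mode = "directed")
  if (!is.null(x$neuron_type))
    igraph::V(g)$neuron_type <- x$neuron_type
  if (!is.null(x$positions)) {
    igraph::V(g)$x <- x$positions[, 1]
    igraph::V(g)$y <- x$positions[, 2]
  }
  g
}

#' Write / read a network as a directed edge-list CSV
#'
#' Columns \code{source,target,weight} with 0-based vertex indices.
#'
#' @param net network object with an \code{adjacency} (and optionally
#'   \code{weights}) field.
#' @param path output file.
#' @export
write_edgelist_csv <- function(net, path) {
  A <- net$adjacency
  idx <- which(A == 1L, arr.ind = TRUE)
  w <- if (!is.null(net$weights)) net$weights[idx] else rep(1, nrow(idx))
  df <- data.frame(source = idx[, 2] - 1L, target = idx[, 1] - 1L, weight = w)
  df <- df[order(df$source, df$target), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_csv
#' @param n_neurons vertex count (isolated vertices are not recoverable
#'   from the edge list alone).
#' @export
read_edgelist_csv <- function(path, n_neurons) {
  df <- utils::read.csv(path)
  A <- matrix(0L, n_neurons, n_neurons)
  W <- matrix(0, n_neurons, n_neurons)
  A[cbind(df$target + 1L, df$source + 1L)] <- 1L
  W[cbind(df$target + 1L, df$source + 1L)] <- df$weight
  new_structural_network(n_neurons, A, positions = NULL, weights = W)
}

#' Write a network as GraphML (with neuron type and position attributes)
#'
#' @inheritParams write_edgelist_csv
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
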