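#' Randomized null ensembles and transformation Z-scores
#'
#' Null model one randomizes the structural layer while preserving the
#' in-, out- and recurrent-degree sequences (vertex permutation followed
#' by degree-preserving double-edge swaps); the randomized layers are
#' paired with the fixed functional network.  Null model two keeps the
#' structural layer and randomizes the placement of the observed numbers
#' of false positives and false negatives.  Z-scores compare observed
#' transformation counts with the ensemble mean and standard deviation.
#'
#' @name null_models
NULL

#' Degree-preserving randomization of a structural network
#'
#' Applies a uniform random vertex permutation, then \code{n_iterations}
#' double-edge-swap attempts.  Each attempt picks two edges from the pool
#' of recurrent pairs (handled as undirected units) and unidirectional
#' directed edges; it is discarded unless both are of the same kind,
#' vertex-disjoint, and the swapped edges land on vertex pairs with no
#' existing connection (so no self-loops, multi-edges, or accidental
#' recurrent pairs arise).  Sources stay sources and sinks stay sinks, so
#' the in-, out- and recurrent-degree sequences are preserved exactly.
#'
#' @param S a \code{structural_network} (weights/types are not carried
#'   into the randomized topology).
#' @param n_iterations number of swap attempts (default 100).
#' @param permute apply the initial vertex permutation (default TRUE).
#' @return a \code{structural_network} with randomized adjacency.
#' @export
randomize_structure <- function(S, n_iterations = 100, permute = TRUE) {
  A <- if (is.list(S)) S$adjacency else S
  n <- nrow(A)
  if (permute) {
    p <- sample.int(n)
    A <- A[p, p]
  }
  rec <- which(upper.tri(A) & A == 1L & t(A) == 1L, arr.ind = TRUE)
  uni_idx <- which(A == 1L & t(A) == 0L, arr.ind = TRUE)
  # directed edge j -> i at A[i, j]: source = col, sink = row
  uni <- cbind(src = uni_idx[, 2], snk = uni_idx[, 1])
  n_rec <- nrow(rec); n_uni <- nrow(uni)
  pool <- n_rec + n_uni
  for (iter in seq_len(n_iterations)) {
    if (pool < 2) break
    e <- sample.int(pool, 2L)
    both_rec <- all(e <= n_rec)
    both_uni <- all(e > n_rec)
    if (!both_rec && !both_uni) next
    if (both_rec) {
      e1 <- rec[e[1], ]; e2 <- rec[e[2], ]
      # choose uniformly which endpoint of each undirected edge is swapped
      if (stats::runif(1) < 0.5) e1 <- rev(e1)
      if (stats::runif(1) < 0.5) e2 <- rev(e2)
      a <- e1[1]; b <- e1[2]; c_ <- e2[1]; d <- e2[2]
      if (length(unique(c(a, b, c_, d))) < 4) next
      # new undirected pairs {c,b} and {a,d} must be fully unconnected
      if (A[b, c_] != 0L || A[c_, b] != 0L || A[d, a] != 0L || A[a, d] != 0L) next
      A[b, a] <- A[a, b] <- 0L; A[d, c_] <- A[c_, d] <- 0L
      A[b, c_] <- A[c_, b] <- 1L; A[d, a] <- A[a, d] <- 1L
      rec[e[1], ] <- c(min(c_, b), max(c_, b))
      rec[e[2], ] <- c(min(a, d), max(a, d))
    } else {
      i1 <- e[1] - n_rec; i2 <- e[2] - n_rec
      a <- uni[i1, 1]; b <- uni[i1, 2]   # a -> b
      c_ <- uni[i2, 1]; d <- uni[i2, 2]  # c -> d
      if (length(unique(c(a, b, c_, d))) < 4) next
      # new edges c -> b and a -> d; target pairs must be unconnected in
      # either direction (else a recurrent pair would appear)
      if (A[b, c_] != 0L || A[c_, b] != 0L || A[d, a] != 0L || A[a, d] != 0L) next
      A[b, a] <- 0L; A[d, c_] <- 0L
      A[b, c_] <- 1L; A[d, a] <- 1L
      uni[i1, ] <- c(c_, b)
      uni[i2, ] <- c(a, d)
    }
  }
  new_structural_network(n, A, positions = NULL,
                         params = list(null_model = "structure",
                                       n_iterations = n_iterations))
}

#' Discrepancy-randomizing null for the functional layer
#'
#' Copies the structural adjacency, deletes \code{n_fn} uniformly chosen
#' existing directed edges and adds \code{n_fp} uniformly chosen absent
#' ordered pairs (never on the diagonal, never on structural edges), so
#' the FP/FN counts relative to S equal (\code{n_fp}, \code{n_fn}) by
#' construction.
#'
#' @param S a \code{structural_network} or adjacency matrix.
#' @param n_fp,n_fn number of false positives / false negatives to plant.
#' @return a \code{functional_network}-shaped randomized layer.
#' @export
randomize_discrepancies <- function(S, n_fp, n_fn) {
  A <- if (is.list(S)) S$adjacency else S
  n <- nrow(A)
  edges <- which(A == 1L)
  nonedges <- which(A == 0L & row(A) != col(A))
  if (n_fn > length(edges))
    stop("n_fn exceeds the number of structural edges")
  if (n_fp > length(nonedges))
    stop("n_fp exceeds the number of absent ordered pairs")
  Af <- A
  if (n_fn > 0) Af[sample(edges, n_fn)] <- 0L
  if (n_fp > 0) Af[sample(nonedges, n_fp)] <- 1L
  structure(list(adjacency = Af, retained_values = NULL,
                 kappa = NA, method = "discrepancy_null",
                 thresholds = NULL),
            class = "functional_network")
}

#' Null ensemble of transformation counts
#'
#' Draws \code{N} randomized multiplex networks under the chosen null
#' model, runs the dyadic or triadic census on each, and summarizes the
#' per-transformation count distribution (mean and N-sample population
#' standard deviation).
#'
#' @param M the observed \code{multiplex_network}.
#' @param null_model \code{"structure"} (null model one: randomized
#'   structural layer vs. fixed F) or \code{"discrepancy"} (null model
#'   two: fixed S vs. FP/FN-randomized layer).
#' @param level \code{"dyadic"} or \code{"triadic"} census.
#' @param N ensemble size (default 100).
#' @param swap_iterations swap attempts per structure randomization.
#' @return a \code{null_ensemble}: list with \code{samples} (N x 10 or
#'   N x 256 count matrix), \code{mu}, \code{sigma}, \code{kind},
#'   \code{level}.
#' @export
null_ensemble <- function(M, null_model = c("structure", "discrepancy"),
                          level = c("dyadic", "triadic"), N = 100,
                          swap_iterations = 100) {
  null_model <- match.arg(null_model)
  level <- match.arg(level)
  stopifnot(N >= 2)
  census_fun <- if (level == "dyadic") dyadic_census else
    function(m) as.vector(t(triadic_census(m)))
  disc <- if (null_model == "discrepancy") {
    d <- edge_discrepancies(M)
    c(fp = nrow(d$false_positives), fn = nrow(d$false_negatives))
  }
  samples <- t(vapply(seq_len(N), function(s) {
    Mr <- if (null_model == "structure") {
      build_multiplex(randomize_structure(M$structural, swap_iterations),
                      M$functional)
    } else {
      build_multiplex(M$structural,
                      randomize_discrepancies(M$structural,
                                              disc[["fp"]], disc[["fn"]]))
    }
    as.numeric(census_fun(Mr))
  }, numeric(if (level == "dyadic") 10L else 256L)))
  mu <- colMeans(samples)
  sigma <- sqrt(colMeans(samples^2) - mu^2)
  sigma[sigma < 0] <- 0
  if (level == "dyadic") names(mu) <- names(sigma) <- dyadic_class_names()
  structure(list(samples = samples, mu = mu, sigma = sigma,
                 kind = null_model, level = level, N = N),
            class = "null_ensemble")
}

#' Transformation Z-scores against a null ensemble
#'
#' \code{Z = (observed - mu) / sigma} per transformation.  Cells with
#' \code{sigma = 0} are flagged undefined (\code{NA}) unless the observed
#' count equals the null mean, in which case Z = 0.
#'
#' @param observed observed census (vector of 10 or 16 x 16 matrix).
#' @param ensemble a \code{\link{null_ensemble}}.
#' @return list with \code{z} (same shape as \code{observed}) and logical
#'   \code{defined}.
#' @export
zscores <- function(observed, ensemble) {
  obs <- if (is.matrix(observed)) as.vector(t(observed)) else as.numeric(observed)
  stopifnot(length(obs) == length(ensemble$mu))
  z <- (obs - ensemble$mu) / ensemble$sigma
  defined <- ensemble$sigma > 0 | obs == ensemble$mu
  z[ensemble$sigma == 0 & obs == ensemble$mu] <- 0
  z[!defined] <- NA_real_
  if (is.matrix(observed)) {
    z <- matrix(z, 16, 16, byrow = TRUE,
                dimnames = dimnames(observed))
    defined <- matrix(defined, 16, 16, byrow = TRUE,
                      dimnames = dimnames(observed))
  } else {
    names(z) <- names(defined) <- names(ensemble$mu)
  }
  list(z = z, defined = defined)
}

#' Summarize an ensemble comparison to tidy CSV
#'
#' One row per transformation: observed count, null mean/sd, Z, defined
#' flag.
#'
#' @param observed observed census (vector or matrix).
#' @param ensemble a \code{\link{null_ensemble}}.
#' @param path output file.
#' @export
write_zscore_csv <- function(observed, ensemble, path) {
  zs <- zscores(observed, ensemble)
  obs <- if (is.matrix(observed)) as.vector(t(observed)) else as.numeric(observed)
  labels <- if (is.matrix(observed)) {
    paste0(rep(1:16, each = 16), "->", rep(1:16, times = 16))
  } else dyadic_class_names()
  df <- data.frame(transformation = labels, observed = obs,
                   mu = ensemble$mu, sigma = ensemble$sigma,
                   z = if (is.matrix(zs$z)) as.vector(t(zs$z)) else zs$z,
                   defined = if (is.matrix(zs$defined))
                     as.vector(t(zs$defined)) else zs$defined)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
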