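#' Per-neuron statistical thresholding of a correlation matrix
#'
#' Every neuron j gets an outward threshold
#' \code{gamma_out(j) = mu_out(j) + kappa * sigma_out(j)} over its n-1
#' outgoing values and an inward threshold likewise over its incoming
#' values.  A directed correlation j -> i is statistically significant
#' with respect to kappa iff it is >= both the source's outward and the
#' target's inward threshold.
#'
#' @name thresholding
NULL

values_of <- function(C) {
  V <- if (inherits(C, "correlation_matrix")) C$values else C
  n_na <- sum(is.na(V))
  if (n_na > 0) {
    message(n_na, " undefined correlation entries treated as 0")
    V[is.na(V)] <- 0
  }
  V
}

#' Per-neuron inward/outward thresholds
#'
#' Means and population standard deviations (divide by the n-1 values)
#' over each neuron's off-diagonal outgoing and incoming correlation
#' values; \code{gamma = mu + kappa * sigma}.
#'
#' @param C a \code{correlation_matrix} or plain numeric matrix with the
#'   j -> i value at \code{[i, j]}.
#' @param kappa threshold parameter.
#' @return data frame with per-neuron \code{mu_out}, \code{sigma_out},
#'   \code{gamma_out}, \code{mu_in}, \code{sigma_in}, \code{gamma_in}.
#' @export
neuron_thresholds <- function(C, kappa) {
  V <- values_of(C)
  n <- nrow(V)
  stopifnot(n >= 2)
  off <- row(V) != col(V)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mu_out <- sig_out <- mu_in <- sig_in <- numeric(n)
  for (j in seq_len(n)) {
    out_vals <- V[, j][off[, j]]   # j -> i entries live in column j
    in_vals  <- V[j, ][off[j, ]]
    mu_out[j] <- mean(out_vals); sig_out[j] <- pop_sd(out_vals)
    mu_in[j]  <- mean(in_vals);  sig_in[j]  <- pop_sd(in_vals)
  }
  data.frame(mu_out = mu_out, sigma_out = sig_out,
             gamma_out = mu_out + kappa * sig_out,
             mu_in = mu_in, sigma_in = sig_in,
             gamma_in = mu_in + kappa * sig_in)
}

#' Threshold a correlation matrix into a functional network
#'
#' Retains the directed edge j -> i iff
#' \code{C[i, j] >= max(gamma_out(j), gamma_in(i))} (non-strict, so
#' equal-valued degenerate cases pass).  Retained entries keep their raw
#' correlation value; all others are zeroed.
#'
#' @inheritParams neuron_thresholds
#' @return a \code{functional_network}: list with binary \code{adjacency},
#'   \code{retained_values}, \code{kappa}, \code{method},
#'   \code{thresholds}.
#' @export
apply_threshold <- function(C, kappa) {
  V <- values_of(C)
  n <- nrow(V)
  th <- neuron_thresholds(V, kappa)
  # cutoff[i, j] = max(gamma_out(j), gamma_in(i))
  cutoff <- pmax(matrix(th$gamma_out, n, n, byrow = TRUE),
                 matrix(th$gamma_in, n, n))
  A <- matrix(0L, n, n)
  A[V >= cutoff] <- 1L
  diag(A) <- 0L
  structure(list(adjacency = A,
                 retained_values = V * A,
                 kappa = kappa,
                 method = if (inherits(C, "correlation_matrix")) C$method else NA,
                 thresholds = th),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat("<functional_network> ", nrow(x$adjacency), " neurons, ",
      sum(x$adjacency), " edges (kappa = ", x$kappa,
      if (!is.na(x$method)) paste0(", ", toupper(x$method)), ")\n", sep = "")
  invisible(x)
}
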