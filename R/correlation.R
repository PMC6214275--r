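#' Directed pairwise dependency measures from binned spike trains
#'
#' Two model-free measures fill an n x n directed matrix with entry
#' \code{[i, j]} = dependency of j on i's future (j -> i), maximized over a
#' delay grid: higher-order transfer entropy (TE, bits) on the binary
#' trains, and the Pearson correlation of Gaussian-convolved firing-rate
#' signals (CC, dimensionless) at delayed alignments.
#'
#' @name correlation
NULL

#' Plug-in higher-order transfer entropy at a single delay
#'
#' Empirical word-frequency estimate of the transfer entropy from train
#' \code{s_j} to train \code{s_i} with history orders \code{k} (target)
#' and \code{l} (source) at delay \code{d} ms (1-ms bins).  Probabilities
#' are raw frequencies, 0 log 0 terms contribute 0.
#'
#' @param s_i,s_j equal-length binary (0/1) vectors.
#' @param k,l history orders (bins).
#' @param d delay (bins).
#' @return transfer entropy in bits (>= 0).
#' @export
transfer_entropy <- function(s_i, s_j, k = 5, l = 5, d = 0) {
  if (length(s_i) != length(s_j))
    stop("spike trains must have equal length")
  if (length(s_i) <= k + d + 1)
    stop("train too short for the requested order and delay")
  transfer_entropy_cpp(as.integer(s_i), as.integer(s_j),
                       as.integer(k), as.integer(l), as.integer(d))
}

#' Transfer entropy maximized over a delay range
#'
#' Evaluates \code{\link{transfer_entropy}} at every delay 0..\code{d_max}
#' and returns the maximum and its delay (smallest on ties).
#'
#' @inheritParams transfer_entropy
#' @param d_max largest delay (bins), default 30.
#' @return list with \code{te} (bits) and \code{best_delay} (ms).
#' @export
hote_max <- function(s_i, s_j, k = 5, l = 5, d_max = 30) {
  stopifnot(d_max >= 0)
  vals <- vapply(0:d_max, function(d) transfer_entropy(s_i, s_j, k, l, d),
                 numeric(1))
  best <- which.max(vals)  # first max -> smallest delay
  list(te = vals[best], best_delay = best - 1L)
}

#' Convolve a binned spike train with a Gaussian kernel
#'
#' Produces the continuous firing-rate signal: discrete convolution with a
#' zero-mean Gaussian of standard deviation \code{sigma} (seconds on a
#' 1-ms sampled axis), truncated at 4 sigma and normalized to unit sum, in
#' "same" alignment (output length = input length).
#'
#' @param s binned spike train (numeric vector, 1-ms bins).
#' @param sigma kernel standard deviation in seconds (default 0.2).
#' @param dt_sample sampling interval in seconds (default 0.001 = 1 ms).
#' @return numeric vector, same length as \code{s}.
#' @export
gaussian_convolve <- function(s, sigma = 0.2, dt_sample = 0.001) {
  stopifnot(sigma > 0, dt_sample > 0)
  sd_samples <- sigma / dt_sample
  half <- ceiling(4 * sd_samples)
  kern <- stats::dnorm(seq(-half, half), sd = sd_samples)
  kern <- kern / sum(kern)
  conv_same(as.numeric(s), kern)
}

# full linear convolution via FFT, trimmed to "same" alignment
conv_same <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  full <- stats::convolve(x, rev(kern), type = "open")
  full[(half + 1L):(half + length(x))]
}

#' Delayed Pearson correlation
#'
#' Pearson coefficient between \code{x_i[t]} and \code{x_j[t - d]} over
#' the overlapping samples (overlap truncation, no wraparound).  Returns
#' \code{NA} if either signal is constant on the overlap.
#'
#' @param x_i,x_j equal-length numeric signals.
#' @param d delay in samples (>= 0).
#' @export
delayed_pearson <- function(x_i, x_j, d) {
  stopifnot(length(x_i) == length(x_j), d >= 0, d < length(x_i))
  T <- length(x_i)
  a <- x_i[(d + 1):T]
  b <- x_j[1:(T - d)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Directed correlation matrix over all neuron pairs
#'
#' Fills every ordered pair (j -> i stored at \code{values[i, j]}) with
#' the max-over-delay dependency and its best delay; zero diagonal.
#' Method \code{"te"} uses higher-order transfer entropy on the binary
#' trains over delays 0..\code{d_max}; \code{"cc"} Gaussian-convolves the
#' trains and maximizes the delayed Pearson correlation over
#' \code{delays}.  Undefined CC entries (zero variance at every delay)
#' are stored as \code{NA} with a warning.
#'
#' @param trains a \code{spike_train_set} or binary matrix (neurons x bins).
#' @param method \code{"te"} or \code{"cc"}.
#' @param k,l,d_max TE history orders and delay cap.
#' @param sigma CC kernel standard deviation (seconds).
#' @param delays CC delay grid (ms), default 1:30.
#' @return a \code{correlation_matrix}: list with \code{values},
#'   \code{best_delay}, \code{method}, \code{params}.
#' @export
correlation_matrix <- function(trains, method = c("te", "cc"),
                               k = 5, l = 5, d_max = 30,
                               sigma = 0.2, delays = 1:30) {
  method <- match.arg(method)
  binned <- if (inherits(trains, "spike_train_set")) trains$binned else trains
  storage.mode(binned) <- "integer"
  n <- nrow(binned)
  stopifnot(n >= 2)
  if (method == "te") {
    res <- hote_matrix_cpp(binned, as.integer(k), as.integer(l),
                           as.integer(d_max))
    values <- res$values
    best <- res$best_delay
    params <- list(k = k, l = l, d_max = d_max)
  } else {
    X <- t(apply(binned, 1, gaussian_convolve, sigma = sigma))
    T <- ncol(X)
    values <- matrix(-Inf, n, n)
    best <- matrix(NA_integer_, n, n)
    for (d in delays) {
      A <- X[, (d + 1):T, drop = FALSE]
      B <- X[, 1:(T - d), drop = FALSE]
      A <- A - rowMeans(A); B <- B - rowMeans(B)
      na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
      M <- tcrossprod(A, B) / outer(na, nb)   # M[i, j] = cor(x_i[t], x_j[t-d])
      M[!is.finite(M)] <- NA
      upd <- !is.na(M) & M > values
      values[upd] <- M[upd]
      best[upd] <- d
    }
    undef <- !is.finite(values)
    if (any(undef[row(values) != col(values)])) {
      warning(sum(undef[row(values) != col(values)]),
              " undefined CC entries (zero variance at all delays)")
      values[undef] <- NA_real_
    }
    params <- list(sigma = sigma, delays = delays)
  }
  diag(values) <- 0
  diag(best) <- 0L
  structure(list(values = values, best_delay = best,
                 method = method, params = params),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", nrow(x$values), " neurons, method ",
      toupper(x$method), "\n", sep = "")
  invisible(x)
}

#' Write / read a correlation matrix as dense CSV plus a YAML manifest
#'
#' @param cm a \code{correlation_matrix}.
#' @param path CSV output path; the manifest is written next to it with a
#'   \code{.manifest.yml} suffix.
#' @export
write_correlation_csv <- function(cm, path) {
  utils::write.table(cm$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(c(list(method = cm$method), cm$params),
                   paste0(path, ".manifest.yml"))
  invisible(path)
}

#' @rdname write_correlation_csv
#' @export
read_correlation_csv <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  man <- yaml::read_yaml(paste0(path, ".manifest.yml"))
  structure(list(values = values, best_delay = NULL,
                 method = man$method,
                 params = man[setdiff(names(man), "method")]),
            class = "correlation_matrix")
}
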