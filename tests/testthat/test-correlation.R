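# independent brute-force plug-in TE: explicit word strings and a hash of
# counts, summing the definition term by term
te_oracle <- function(si, sj, k, l, d) {
  T <- length(si)
  cnt <- new.env(parent = emptyenv())
  bump <- function(key) assign(key, (if (exists(key, cnt)) get(key, cnt) else 0) + 1, cnt)
  N <- 0
  for (t in max(k, d + l - 1):(T - 1)) {
    a <- paste(si[(t - k + 1):t], collapse = "")
    b <- paste(sj[(t + 1 - d - l + 1):(t + 1 - d)], collapse = "")
    y <- si[t + 1]
    for (key in c(paste("yab", y, a, b), paste("ab", a, b),
                  paste("ya", y, a), paste("a", a))) bump(key)
    N <- N + 1
  }
  te <- 0
  for (key in ls(cnt)) {
    parts <- strsplit(key, " ")[[1]]
    if (parts[1] != "yab") next
    c_yab <- get(key, cnt)
    c_ab <- get(paste("ab", parts[3], parts[4]), cnt)
    c_ya <- get(paste("ya", parts[2], parts[3]), cnt)
    c_a <- get(paste("a", parts[3]), cnt)
    te <- te + (c_yab / N) * log2((c_yab * c_a) / (c_ab * c_ya))
  }
  te
}

test_that("plug-in TE equals the brute-force word-count oracle", {
  set.seed(21)
  for (rep in 1:6) {
    T <- sample(300:2000, 1)
    si <- rbinom(T, 1, 0.2); sj <- rbinom(T, 1, 0.3)
    k <- sample(1:3, 1); l <- sample(1:3, 1); d <- sample(0:5, 1)
    expect_equal(transfer_entropy(si, sj, k, l, d),
                 te_oracle(si, sj, k, l, d), tolerance = 1e-12)
  }
})

test_that("TE degenerate and independence limits", {
  set.seed(22)
  si <- rbinom(5000, 1, 0.3)
  expect_equal(transfer_entropy(si, rep(0L, 5000), k = 5, l = 5, d = 3), 0)
  a <- rbinom(1e5, 1, 0.1); b <- rbinom(1e5, 1, 0.1)
  expect_lt(transfer_entropy(a, b, k = 1, l = 1, d = 0), 0.01)
  expect_error(transfer_entropy(a, b[-1], 1, 1, 0))
})

test_that("TE on a copy channel recovers ~1 bit at the embedded delay", {
  set.seed(23)
  d0 <- 7
  sj <- rbinom(1e5, 1, 0.5)
  si <- c(rep(0L, d0), sj[1:(1e5 - d0)])   # s_i(t) = s_j(t - d0)
  res <- hote_max(si, sj, k = 1, l = 1, d_max = 15)
  expect_equal(res$best_delay, d0)
  expect_lt(abs(res$te - 1), 0.05)
  # max dominates every individual delay, and d_max = 0 is the single TE
  te_each <- sapply(0:15, function(d) transfer_entropy(si, sj, 1, 1, d))
  expect_true(all(res$te >= te_each))
  expect_equal(hote_max(si, sj, 1, 1, d_max = 0)$te,
               transfer_entropy(si, sj, 1, 1, 0))
})

test_that("shuffling a train collapses both measures toward zero", {
  set.seed(24)
  sj <- rbinom(30000, 1, 0.3)
  si <- c(0L, sj[-30000])
  true_te <- hote_max(si, sj, 1, 1, 5)$te
  xi <- gaussian_convolve(si, sigma = 0.02)
  xj <- gaussian_convolve(sj, sigma = 0.02)
  true_cc <- max(sapply(1:5, function(d) delayed_pearson(xi, xj, d)))
  sh_te <- sh_cc <- numeric(20)
  for (r in 1:20) {
    perm <- sample.int(30000)
    sh_te[r] <- hote_max(si, sj[perm], 1, 1, 5)$te
    xs <- gaussian_convolve(sj[perm], sigma = 0.02)
    sh_cc[r] <- max(sapply(1:5, function(d) delayed_pearson(xi, xs, d)))
  }
  expect_lt(quantile(sh_te, 0.95), 0.1 * true_te)
  expect_lt(quantile(sh_cc, 0.95), 0.1 * true_cc)
})

test_that("Gaussian convolution is a normalized symmetric smoother", {
  s <- rep(0, 3000); s[1500] <- 1
  x <- gaussian_convolve(s, sigma = 0.2)
  expect_equal(length(x), 3000)
  expect_equal(which.max(x), 1500)
  expect_equal(max(x), dnorm(0, sd = 200) /
                 sum(dnorm(-800:800, sd = 200)), tolerance = 1e-9)
  expect_equal(gaussian_convolve(rep(0, 100), 0.2), rep(0, 100),
               tolerance = 1e-12)
  set.seed(25)
  s10 <- rep(0, 5000); s10[sample(1000:4000, 10)] <- 1
  expect_equal(sum(gaussian_convolve(s10, 0.2)), 10, tolerance = 1e-6)
})

test_that("delayed Pearson matches hand values and flags degenerate overlap", {
  expect_equal(delayed_pearson(c(1, 2, 3, 4), c(4, 3, 2, 1), 0), -1)
  set.seed(26)
  xj <- rnorm(500)
  xi <- c(rep(0, 3), xj[1:497])
  expect_equal(delayed_pearson(xi, xj, 3), 1, tolerance = 1e-9)
  expect_equal(delayed_pearson(-xi, xj, 3), -1, tolerance = 1e-9)
  expect_true(is.na(delayed_pearson(rep(1, 100), rnorm(100), 2)))
})

test_that("correlation_matrix fills all ordered pairs with a zero diagonal", {
  set.seed(27)
  n <- 6; T <- 3000
  binned <- matrix(rbinom(n * T, 1, 0.1), n, T)
  binned[2, ] <- c(rep(0L, 3), binned[1, 1:(T - 3)])  # neuron 1 -> neuron 2, lag 3
  te <- correlation_matrix(binned, "te", k = 2, l = 2, d_max = 6)
  cc <- correlation_matrix(binned, "cc", sigma = 0.005, delays = 1:6)
  for (cm in list(te, cc)) {
    expect_true(all(diag(cm$values) == 0))
    expect_equal(sum(row(cm$values) != col(cm$values)), n * (n - 1))
  }
  expect_true(all(te$values >= 0))
  expect_true(all(cc$values >= -1 & cc$values <= 1))
  # the planted pair dominates both matrices and its delay is recovered
  # (with l = 2 the order-2 source word still covers the true lag at d = 2,
  #  so the smallest-delay tie-break lands one bin early for TE)
  off <- row(te$values) != col(te$values)
  expect_equal(which(te$values == max(te$values[off])), 2L)  # entry [2, 1]
  expect_true(te$best_delay[2, 1] %in% c(2L, 3L))
  expect_equal(cc$best_delay[2, 1], 3L)
  expect_equal(unname(which.max(cc$values * off)), 2L)
})

test_that("correlation CSV round-trips values and manifest", {
  set.seed(28)
  binned <- matrix(rbinom(4 * 500, 1, 0.2), 4, 500)
  cm <- correlation_matrix(binned, "te", k = 1, l = 1, d_max = 3)
  path <- tempfile(fileext = ".csv")
  write_correlation_csv(cm, path)
  back <- read_correlation_csv(path)
  expect_equal(back$values, cm$values, tolerance = 1e-12)
  expect_equal(back$method, "te")
})
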