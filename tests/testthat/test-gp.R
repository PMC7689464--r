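# independent dense multivariate-normal oracle for the GP marginal likelihood
oracle_logml <- function(x, y, hp) {
  n <- length(x)
  K <- hp$sigma_f2 * exp(-outer(x, x, `-`)^2 / (2 * hp$length_scale^2)) +
    diag(hp$sigma_n2 + 1e-8 * hp$sigma_f2, n)
  Kinv <- solve(K)
  as.numeric(-0.5 * t(y) %*% Kinv %*% y -
               0.5 * determinant(K, logarithm = TRUE)$modulus -
               0.5 * n * log(2 * pi))
}

test_that("GP marginal likelihood matches closed forms and the dense oracle", {
  hp <- gp_hyperparams(2, 1.5, 0.3)
  # single observation: log N(y; 0, sigma_f2 + sigma_n2) (+ jitter)
  y1 <- 0.7
  expect_equal(gp_log_marginal_likelihood(3, y1, hp),
               dnorm(y1, 0, sqrt(2 + 0.3 + 1e-8 * 2), log = TRUE),
               tolerance = 1e-9)
  # five fixed points against the explicitly constructed Gram matrix
  x <- c(1, 2, 3, 4, 5)
  y <- c(0.2, -0.1, 0.4, 0.0, -0.3)
  expect_equal(gp_log_marginal_likelihood(x, y, hp), oracle_logml(x, y, hp),
               tolerance = 1e-9)
  # 100 random instances, n <= 50
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:50, 1L)
    x <- sort(runif(n, 0, 10))
    y <- rnorm(n)
    hp_i <- gp_hyperparams(exp(runif(1, -2, 2)), exp(runif(1, -1.5, 1.5)),
                           exp(runif(1, -3, 1)))
    expect_equal(gp_log_marginal_likelihood(x, y, hp_i),
                 oracle_logml(x, y, hp_i), tolerance = 1e-6)
  }
})

test_that("the vanishing-signal limit reduces to iid Gaussian noise", {
  set.seed(4)
  x <- 1:10
  y <- rnorm(10, 0, 1)
  hp <- gp_hyperparams(1e-12, 1e6, 0.8)
  expect_equal(gp_log_marginal_likelihood(x, y, hp),
               sum(dnorm(y, 0, sqrt(0.8), log = TRUE)), tolerance = 1e-6)
})

test_that("hyperparameter optimisation is deterministic and sane", {
  set.seed(8)
  x <- rep(1:9, each = 3)
  y <- sin(x / 2) + rnorm(length(x), 0, 0.05)
  y <- y - mean(y)
  h1 <- optimise_hyperparams(x, y)
  h2 <- optimise_hyperparams(x, y)
  expect_identical(h1, h2)
  # smooth signal, low noise: fitted noise far below signal variance
  expect_lt(h1$sigma_n2, h1$sigma_f2 / 5)
})

test_that("pure white noise yields noise-variance estimates near the truth", {
  set.seed(15)
  ratio <- replicate(30, {
    y <- rnorm(30)
    hp <- optimise_hyperparams(1:30, y - mean(y))
    hp$sigma_n2
  })
  # middle of the sampling band; individual fits may wander
  expect_gt(median(ratio), 0.5)
  expect_lt(median(ratio), 2.0)
})

test_that("a duplicated condition never supports the independent model", {
  set.seed(20)
  cp <- matrix(rnorm(27, 0, 0.2), 3, 9) +
    matrix(sin(1:9 / 2), 3, 9, byrow = TRUE)
  bf <- log_bayes_factor(cp, cp)
  expect_lte(bf$logBF, 0)
  expect_equal(bf$logBF, bf$logML_M1 - bf$logML_M0, tolerance = 1e-9)
})

test_that("the Bayes factor is symmetric in condition labels and shift-invariant", {
  set.seed(21)
  cp <- matrix(rnorm(27, 0, 0.3), 3, 9)
  tp <- matrix(rnorm(27, 0, 0.3), 3, 9) + 0.5
  b1 <- log_bayes_factor(cp, tp)
  b2 <- log_bayes_factor(tp, cp)
  expect_equal(b1$logBF, b2$logBF, tolerance = 1e-6)
  b3 <- log_bayes_factor(cp + 3.7, tp + 3.7)
  expect_equal(b1$logBF, b3$logBF, tolerance = 1e-6)
})

test_that("profile shifts large relative to noise exceed the hit threshold", {
  set.seed(22)
  noise_sd <- 0.15
  base <- matrix(0, 3, 10)
  shift <- c(rep(10 * noise_sd, 5), rep(0, 5))
  cp <- base + matrix(rnorm(30, 0, noise_sd), 3, 10)
  tp <- base + matrix(shift, 3, 10, byrow = TRUE) +
    matrix(rnorm(30, 0, noise_sd), 3, 10)
  bf <- log_bayes_factor(cp, tp)
  expect_gt(bf$logBF, 14)
})

test_that("the Bayes factor grows with the magnitude of the profile shift", {
  noise_sd <- 0.15
  shifts <- c(0, 0.25, 0.5, 1, 2)
  bfs <- vapply(seq_along(shifts), function(i) {
    set.seed(100)  # same noise realisation across the shift grid
    cp <- matrix(rnorm(30, 0, noise_sd), 3, 10)
    tp <- matrix(rnorm(30, 0, noise_sd), 3, 10) +
      matrix(c(rep(shifts[i], 5), rep(0, 5)), 3, 10, byrow = TRUE)
    log_bayes_factor(cp, tp)$logBF
  }, numeric(1L))
  expect_true(all(diff(bfs) >= 0))
})

test_that("dataset-level Bayes factors mirror the per-protein computation", {
  sim <- small_sim(n = 160L, seed = 30L)
  cds <- normalise_rows(sim$control)
  tds <- normalise_rows(sim$treatment)
  acc <- rownames(cds$values)[c(1L, 50L)]
  res <- bf_test(cds, tds, proteins = acc)
  expect_equal(res$accession, acc)
  expect_true(all(is.finite(res$logBF)))
  alr_of <- function(ds, a) t(sapply(ds$scheme$replicates, function(r) {
    alr_transform(ds$values[a, mitoshift:::.block_index(ds$scheme, r)])
  }))
  direct <- log_bayes_factor(alr_of(cds, acc[1L]), alr_of(tds, acc[1L]))
  expect_equal(res$logBF[1L], direct$logBF, tolerance = 1e-9)
  # mismatched dimensionality is rejected
  expect_error(log_bayes_factor(matrix(0, 3, 9), matrix(0, 3, 8)),
               "dimensions differ")
})
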