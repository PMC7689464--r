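# small labelled Gaussian mixture for allocation tests
gauss_mix <- function(n_per, centres, sd = 0.5, seed = 1L) {
  set.seed(seed)
  K <- nrow(centres)
  p <- ncol(centres)
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(rnorm(n_per * p, 0, sd), n_per, p) +
      matrix(centres[k, ], n_per, p, byrow = TRUE)
  }))
  rownames(X) <- sprintf("G%03d", seq_len(K * n_per))
  list(X = X, z = rep(seq_len(K), each = n_per))
}

test_that("default priors instantiate the documented data-derived formulas", {
  set.seed(1)
  X <- matrix(rnorm(200L), 100L, 2L)
  rownames(X) <- sprintf("P%03d", 1:100)
  mm <- marker_map(sprintf("P%03d", 1:8), rep(c("a", "b", "c", "d"), 2L))
  pr <- default_priors(X, mm)
  expect_equal(pr$beta0, rep(1, 4L))
  expect_equal(pr$mu0, colMeans(X))
  expect_equal(pr$M, colMeans(X))
  expect_equal(pr$S0, diag(apply(X, 2L, var), 2L) / 4, tolerance = 1e-12)
  expect_equal(pr$nu0, 4)  # dimension + 2
  expect_equal(pr$kappa, 4)
})

test_that("K=1 with no outlier component recovers the conjugate posterior-mode mean", {
  set.seed(2)
  X <- matrix(rnorm(50L * 3L, mean = 2), 50L, 3L)
  rownames(X) <- sprintf("P%03d", 1:50)
  mm <- marker_map(c("P001", "P002"), c("only", "only"))
  fit <- fit_tagm_map(X, mm, epsilon = 0, max_iter = 100L)
  pr <- fit$priors
  n <- nrow(X)
  expected <- (pr$lambda0 * pr$mu0 + n * colMeans(X)) / (pr$lambda0 + n)
  expect_equal(unname(fit$mu[1L, ]), unname(expected), tolerance = 1e-8)
})

test_that("EM log-posterior trace is monotone non-decreasing", {
  sim <- small_sim(n = 250L, seed = 6L)
  ds <- normalise_rows(sim$control)
  fit <- suppressWarnings(
    fit_tagm_map(concatenate_replicates(ds), sim$markers))
  tr <- fit$log_posterior
  expect_gt(length(tr), 2L)
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
})

test_that("well-separated clusters are allocated with near-certain posteriors", {
  centres <- rbind(c(0, 0), c(20, 0), c(0, 20))  # 20+ sds apart at sd = 1
  gm <- gauss_mix(150L, centres, sd = 1, seed = 3L)
  m_idx <- c(1:15, 151:165, 301:315)
  mm <- marker_map(rownames(gm$X)[m_idx],
                   c("a", "b", "c")[gm$z[m_idx]])
  unk <- setdiff(rownames(gm$X), names(mm))
  truth <- c("a", "b", "c")[gm$z[match(unk, rownames(gm$X))]]
  # without the outlier component the posteriors are essentially certain
  fit0 <- fit_tagm_map(gm$X, mm, epsilon = 0)
  post0 <- posterior_localisation(fit0, gm$X[unk, ])
  expect_true(all(post0$map_class == truth))
  expect_true(all(apply(post0$prob, 1L, max) > 0.999))
  # with the learned outlier weight, allocation stays perfect and the
  # heavy-tailed component takes at most a trace of posterior mass
  fit <- fit_tagm_map(gm$X, mm)
  post <- posterior_localisation(fit, gm$X[unk, ])
  expect_true(all(post$map_class == truth))
  expect_true(all(apply(post$prob, 1L, max) > 0.99))
  # probabilities plus outlier mass normalise to 1
  expect_lt(max(abs(rowSums(post$prob) + post$outlier_prob - 1)), 1e-9)
})

test_that("a protein far outside every cluster is called an outlier", {
  centres <- rbind(c(0, 0), c(6, 0))
  gm <- gauss_mix(50L, centres, sd = 0.5, seed = 4L)
  mm <- marker_map(rownames(gm$X)[c(1:10, 51:60)],
                   rep(c("a", "b"), each = 10L))
  fit <- fit_tagm_map(gm$X, mm)
  far <- matrix(c(3, 15), 1L, 2L,
                dimnames = list("FAR", NULL))  # ~10x cluster spread away
  post <- posterior_localisation(fit, far)
  expect_gt(post$outlier_prob[["FAR"]], 0.5)
  expect_equal(unname(post$map_class), "outlier")
})

test_that("with no outliers in the data the fitted outlier weight stays small", {
  # at the default study scale; small-n fits legitimately inflate epsilon
  tm <- default_templates(seed = 11L)
  cfg <- sim_config(n_proteins = 2000L, outlier_fraction = 0,
                    reloc_fraction = 0, seed = 13L)
  sim <- simulate_dataset(cfg, tm)
  ds <- normalise_rows(sim$control)
  fit <- suppressWarnings(
    fit_tagm_map(concatenate_replicates(ds), sim$markers))
  expect_lte(fit$epsilon, 0.05)
  # and organelle assignment against generating truth is accurate
  post <- posterior_localisation(fit, concatenate_replicates(ds))
  tr <- sim$truth
  expect_gt(mean(post$map_class[tr$accession] == tr$class), 0.95)
})

test_that("relabelling marker classes permutes outputs identically", {
  centres <- rbind(c(0, 0), c(8, 0), c(0, 8))
  gm <- gauss_mix(30L, centres, sd = 0.6, seed = 5L)
  m_idx <- c(1:6, 31:36, 61:66)
  lab1 <- c("a", "b", "c")
  lab2 <- c("zeta", "alpha", "mid")   # same partition, different labels
  mm1 <- marker_map(rownames(gm$X)[m_idx], lab1[gm$z[m_idx]])
  mm2 <- marker_map(rownames(gm$X)[m_idx], lab2[gm$z[m_idx]])
  f1 <- fit_tagm_map(gm$X, mm1)
  f2 <- fit_tagm_map(gm$X, mm2)
  p1 <- posterior_localisation(f1, gm$X)
  p2 <- posterior_localisation(f2, gm$X)
  relabel <- setNames(lab2, lab1)
  expect_identical(unname(relabel[p1$map_class[p1$map_class != "outlier"]]),
                   unname(p2$map_class[p2$map_class != "outlier"]))
  expect_equal(unname(p2$prob[, unname(relabel[colnames(p1$prob)])]),
               unname(p1$prob), tolerance = 1e-9)
})

test_that("pre-filter discards predicted residents but keeps other markers", {
  centres <- rbind(c(0, 0), c(10, 0))
  gm <- gauss_mix(30L, centres, sd = 0.5, seed = 6L)
  mm <- marker_map(rownames(gm$X)[c(1:8, 31:38)],
                   rep(c("mitochondria", "golgi"), each = 8L))
  fit <- fit_tagm_map(gm$X, mm)
  post <- posterior_localisation(fit, gm$X)
  kept <- prefilter_discard(post, "mitochondria", mm)
  # cluster 1 (mitochondrial) gone, cluster 2 retained
  expect_false(any(rownames(gm$X)[1:30] %in% kept))
  expect_setequal(kept, rownames(gm$X)[31:60])
  # empty discard set is the identity
  expect_setequal(prefilter_discard(post, character()), rownames(gm$X))
  expect_error(prefilter_discard(post, "lysosome"), "unknown discard class")
})

test_that("discard classes are matched by compartment label patterns", {
  cls <- c("mitochondria", "Nucleus/chromatin", "golgi", "ER", "nucleolus")
  expect_setequal(match_discard_classes(cls),
                  c("mitochondria", "Nucleus/chromatin", "nucleolus"))
})
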