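test_that("read_dataset parses TSVs, drops incomplete rows, rejects duplicates", {
  vals <- matrix(seq_len(18), 3, 6,
                 dimnames = list(c("P01", "P02", "P03"), NULL))
  path <- write_tiny_tsv(vals)
  ds <- read_dataset(path, tiny_scheme())
  expect_equal(dim(ds), c(3L, 6L))
  expect_equal(rownames(ds$values), c("P01", "P02", "P03"))

  vals_na <- vals
  vals_na[2L, 4L] <- NA
  path_na <- write_tiny_tsv(vals_na)
  expect_message(ds_na <- read_dataset(path_na, tiny_scheme()),
                 "1 protein\\(s\\) dropped")
  expect_equal(nrow(ds_na$values), 2L)
  expect_false("P02" %in% rownames(ds_na$values))

  vals_dup <- vals
  rownames(vals_dup) <- c("P01", "P01", "P03")
  df <- read.delim(write_tiny_tsv(vals), check.names = FALSE)
  df$accession <- c("P01", "P01", "P03")
  path_dup <- tempfile(fileext = ".tsv")
  write.table(df, path_dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(path_dup, tiny_scheme()), "duplicate")

  # column/scheme mismatch
  wrong <- fraction_scheme(c("F1", "F2", "F9"), c("rep1", "rep2"))
  expect_error(read_dataset(path, wrong), "schema error")
})

test_that("column order in the file does not matter (scheme ordering wins)", {
  set.seed(1)
  vals <- matrix(runif(18), 3, 6,
                 dimnames = list(c("P01", "P02", "P03"), NULL))
  ds1 <- read_dataset(write_tiny_tsv(vals), tiny_scheme())
  ds2 <- read_dataset(write_tiny_tsv(vals, shuffle_cols = TRUE), tiny_scheme())
  expect_equal(concatenate_replicates(ds1), concatenate_replicates(ds2))
})

test_that("contaminant filter removes frequent proteins but never markers", {
  vals <- matrix(1, 4, 6,
                 dimnames = list(c("CONT1", "MARK1", "LOW1", "KRT1"), NULL))
  ds <- tiny_dataset(vals)
  contam <- c(CONT1 = 0.15, MARK1 = 0.15, LOW1 = 0.05)
  mm <- marker_map("MARK1", "mitochondria")
  out <- suppressMessages(
    filter_contaminants(ds, contam, mm, threshold = 0.1,
                        blocklist = "KRT1"))
  expect_setequal(rownames(out$values), c("MARK1", "LOW1"))
  # removal count = |freq >= threshold| + blocklist - marker overlap
  expect_equal(nrow(ds$values) - nrow(out$values), 2L)
})

test_that("the shipped blocklist parses to keratin/albumin/trypsin accessions", {
  bl <- default_blocklist()
  expect_true(all(c("P04264", "P02768", "P00761") %in% bl))
  expect_false(any(grepl("#|\\s", bl)))
})

test_that("normalise_rows makes each replicate block a composition", {
  vals <- rbind(P01 = c(2, 2, 4, 1, 1, 2))
  ds <- normalise_rows(tiny_dataset(vals))
  expect_equal(unname(ds$values[1L, 1:3]), c(0.25, 0.25, 0.5))
  expect_equal(unname(ds$values[1L, 4:6]), c(0.25, 0.25, 0.5))
  # idempotent
  expect_equal(normalise_rows(ds)$values, ds$values)
  # degenerate all-zero block names the protein
  bad <- tiny_dataset(rbind(P01 = c(0, 0, 0, 1, 1, 1)))
  expect_error(normalise_rows(bad), "P01")
})

test_that("ALR transform matches analytic values and inverts exactly", {
  expect_equal(alr_transform(rep(0.25, 4)), c(0, 0, 0))
  expect_equal(alr_transform(c(0.5, 0.25, 0.25)), c(log(2), 0))
  expect_error(alr_transform(1), "at least 2")
  set.seed(7)
  X <- random_compositions(1000L, 5L)
  back <- inverse_alr(alr_transform(X))
  expect_lt(max(abs(back - X)), 1e-9)
  # zeros get a half-minimum pseudo-count and stay finite
  z <- alr_transform(c(0.5, 0.5, 0))
  expect_true(all(is.finite(z)))
})

test_that("normalise + ALR + inverse reconstructs every replicate block", {
  set.seed(3)
  vals <- matrix(rgamma(60, 2), 10, 6)
  rownames(vals) <- sprintf("P%02d", 1:10)
  ds <- normalise_rows(tiny_dataset(vals))
  for (r in c(1, 2)) {
    block <- ds$values[, (r - 1) * 3 + 1:3]
    expect_lt(max(abs(inverse_alr(alr_transform(block)) - block)), 1e-9)
  }
})

test_that("PCA projection is deterministic, sign-fixed and permutation-stable", {
  set.seed(5)
  t_line <- seq(-1, 1, length.out = 50L)
  X_line <- cbind(t_line, 2 * t_line)
  p <- pca_projection(X_line, 2L)
  expect_equal(p$explained_variance[1L], 1, tolerance = 1e-12)

  X <- matrix(rnorm(200L), 50L, 4L)
  p1 <- pca_projection(X, 2L)
  p2 <- pca_projection(X, 2L)
  expect_identical(p1, p2)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  }
  # row permutation permutes scores identically
  perm <- sample(50L)
  p3 <- pca_projection(X[perm, ], 2L)
  expect_equal(p3$scores, p1$scores[perm, ], tolerance = 1e-9)
})

test_that("isotropic clouds spread variance evenly across components", {
  set.seed(9)
  X <- matrix(rnorm(10000L * 3L), 10000L, 3L)
  p <- pca_projection(X, 3L)
  expect_true(all(abs(p$explained_variance - 1 / 3) < 0.02))
})

test_that("supervised classification assigns well-separated classes and keeps marker labels", {
  set.seed(21)
  sim <- small_sim(n = 300L, reloc = 0, outlier_fraction = 0)
  ds <- normalise_rows(sim$control)
  res <- classify_supervised(ds, sim$markers, fdr = 0.05, seed = 3L)
  # markers retain curated labels
  m_acc <- names(sim$markers)
  expect_equal(res[m_acc, "class"], unname(unclass(sim$markers)[m_acc]))
  # assigned unknowns are overwhelmingly correct
  truth <- sim$truth$class[match(res$accession, sim$truth$accession)]
  unk <- !res$is_marker & res$class != "unassigned"
  expect_gt(mean(res$class[unk] == truth[unk]), 0.95)
  expect_gt(mean(unk[!res$is_marker]), 0.5)
})

test_that("undersized marker classes are excluded with a warning", {
  set.seed(22)
  sim <- small_sim(n = 300L, reloc = 0)
  ds <- normalise_rows(sim$control)
  mm <- sim$markers
  small_cls <- unclass(mm) == "ER"
  keep <- c(names(mm)[!small_cls], names(mm)[small_cls][1:3])
  mm2 <- marker_map(keep, unclass(mm)[keep])
  expect_warning(classify_supervised(ds, mm2, seed = 3L), "ER")
})
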