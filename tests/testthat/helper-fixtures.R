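# Fixtures built in code, shared across test files.

# tiny 2-replicate x 3-fraction scheme
tiny_scheme <- function(condition = "control") {
  fraction_scheme(c("F1", "F2", "F3"), c("rep1", "rep2"), condition)
}

# a small profile dataset with given values (proteins x 6)
tiny_dataset <- function(values, condition = "control", marker = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  }
  meta <- data.frame(accession = rownames(values),
                     stringsAsFactors = FALSE)
  if (!is.null(marker)) meta$marker <- marker
  profile_dataset(values, tiny_scheme(condition), meta)
}

# write a quantitation TSV for tiny_scheme and return the path
write_tiny_tsv <- function(values, path = tempfile(fileext = ".tsv"),
                           condition = "control", shuffle_cols = FALSE) {
  sch <- tiny_scheme(condition)
  cols <- as.vector(vapply(sch$replicates, function(r) {
    paste(condition, r, sch$fractions, sep = "_")
  }, character(3L)))
  df <- data.frame(accession = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- cols
  if (shuffle_cols) df <- df[, c(1L, 1L + sample(ncol(values)))]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random compositions (rows) via normalised Gamma draws
random_compositions <- function(n, D) {
  g <- matrix(rgamma(n * D, shape = 2), n, D)
  g / rowSums(g)
}

# small simulated study used by several pipeline-level tests
small_sim <- function(n = 400L, reloc = 0.025, seed = 42L, ...) {
  tm <- default_templates(seed = 11L)
  cfg <- sim_config(n_proteins = n, n_markers_per_class = 15L,
                    reloc_fraction = reloc, seed = seed, ...)
  simulate_dataset(cfg, tm)
}
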