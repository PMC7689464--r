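#' Define a fractionation scheme
#'
#' A fractionation scheme fixes the ordered set of differential-centrifugation
#' fractions, the replicate labels and the condition label of a LOPIT-style
#' experiment. The fraction order is the coordinate system every downstream
#' statistic works in, so it must be identical across replicates and across
#' the conditions being compared.
#'
#' @param fractions Character vector of ordered fraction labels
#'   (e.g. `c("NUC", paste0("P", 1:9))`). At least 3 are required so that the
#'   additive log-ratio transform has at least 2 output dimensions.
#' @param replicates Character vector of ordered replicate labels.
#' @param condition Single condition label (e.g. `"control"`).
#' @return An object of class `fraction_scheme`.
#' @export
fraction_scheme <- function(fractions, replicates, condition = "control") {
  fractions <- as.character(fractions)
  replicates <- as.character(replicates)
  if (length(fractions) < 3L) {
    stop("a fraction scheme needs at least 3 fractions")
  }
  if (anyDuplicated(fractions) || anyDuplicated(replicates)) {
    stop("fraction and replicate labels must be unique")
  }
  structure(
    list(fractions = fractions, replicates = replicates,
         condition = as.character(condition)[1L]),
    class = "fraction_scheme"
  )
}

#' @export
print.fraction_scheme <- function(x, ...) {
  cat("Fraction scheme [", x$condition, "]: ",
      length(x$fractions), " fractions x ",
      length(x$replicates), " replicates\n", sep = "")
  cat("  fractions:", paste(x$fractions, collapse = ", "), "\n")
  invisible(x)
}

# Abundance column names for a scheme, replicate-major:
# <condition>_<rep>_<fraction> for rep1 f1..fD, rep2 f1..fD, ...
.scheme_columns <- function(scheme) {
  as.vector(vapply(scheme$replicates, function(r) {
    paste(scheme$condition, r, scheme$fractions, sep = "_")
  }, character(length(scheme$fractions))))
}

# Column indices of one replicate's fraction block.
.block_index <- function(scheme, r) {
  D <- length(scheme$fractions)
  which(scheme$replicates == r) * D - D + seq_len(D)
}

#' Construct a profile dataset
#'
#' Container for a proteins x (replicate, fraction) reporter-ion abundance
#' matrix with per-protein metadata. Columns are stored replicate-major in
#' scheme order regardless of input order.
#'
#' @param values Numeric matrix, one row per protein, `R * D` columns
#'   (replicate-major), non-negative. Row names are protein accessions.
#' @param scheme A [fraction_scheme()].
#' @param meta Data frame with at least an `accession` column; a `gene` and a
#'   `marker` column (organelle class or `"unknown"`) are added if absent.
#' @return An object of class `profile_dataset`.
#' @export
profile_dataset <- function(values, scheme, meta = NULL) {
  values <- as.matrix(values)
  D <- length(scheme$fractions)
  R <- length(scheme$replicates)
  if (ncol(values) != R * D) {
    stop("values has ", ncol(values), " columns; scheme implies ", R * D)
  }
  if (is.null(rownames(values))) {
    stop("values must carry protein accessions as row names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate protein accessions in dataset")
  }
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  colnames(values) <- .scheme_columns(scheme)
  if (is.null(meta)) {
    meta <- data.frame(accession = rownames(values),
                       stringsAsFactors = FALSE)
  }
  if (!"gene" %in% names(meta)) meta$gene <- meta$accession
  if (!"marker" %in% names(meta)) meta$marker <- "unknown"
  rownames(meta) <- meta$accession
  meta <- meta[rownames(values), , drop = FALSE]
  structure(list(values = values, scheme = scheme, meta = meta),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat("Profile dataset [", x$scheme$condition, "]: ",
      nrow(x$values), " proteins x ", length(x$scheme$fractions),
      " fractions x ", length(x$scheme$replicates), " replicates\n", sep = "")
  nm <- sum(x$meta$marker != "unknown")
  cat("  markers annotated:", nm, "\n")
  invisible(x)
}

#' @export
dim.profile_dataset <- function(x) dim(x$values)

#' Read a protein-level quantitation table
#'
#' Reads a TSV or CSV file with one row per protein: an `accession` column,
#' an optional `gene` column, then one abundance column per
#' (replicate, fraction) named `<condition>_<replicate>_<fraction>`.
#' Rows containing any missing abundance are dropped and the count reported.
#'
#' @param path Path to a UTF-8 TSV (default) or CSV file with a header row.
#' @param scheme The [fraction_scheme()] the columns must match.
#' @return A [profile_dataset()].
#' @export
read_dataset <- function(path, scheme) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!"accession" %in% names(tab)) {
    stop("schema error: no 'accession' column in ", path)
  }
  want <- .scheme_columns(scheme)
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols)) {
    stop("schema error: abundance columns absent from ", path, ": ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  if (anyDuplicated(tab$accession)) {
    stop("duplicate accessions in ", path, ": ",
         paste(unique(tab$accession[duplicated(tab$accession)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, want, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- tab$accession
  keep <- stats::complete.cases(vals)
  if (any(!keep)) {
    message(sum(!keep), " protein(s) dropped for missing values")
  }
  meta <- tab[keep, setdiff(names(tab), want), drop = FALSE]
  profile_dataset(vals[keep, , drop = FALSE], scheme, meta)
}

#' Write a profile dataset to TSV
#'
#' @param ds A [profile_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  out <- data.frame(accession = rownames(ds$values),
                    gene = ds$meta$gene,
                    ds$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an organelle marker map
#'
#' CSV with columns `accession,organelle`. Every marker maps to exactly one
#' organelle class.
#'
#' @param path CSV file path.
#' @return A named character vector (class `marker_map`): accession ->
#'   organelle class.
#' @export
read_markers <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  marker_map(tab$accession, tab$organelle)
}

#' Construct a marker map
#'
#' @param accessions Character vector of marker protein accessions.
#' @param classes Organelle class label per accession.
#' @return A named character vector of class `marker_map`.
#' @export
marker_map <- function(accessions, classes) {
  if (length(accessions) != length(classes)) {
    stop("accessions and classes differ in length")
  }
  if (anyDuplicated(accessions)) {
    stop("a marker protein must map to exactly one organelle class")
  }
  structure(stats::setNames(as.character(classes), as.character(accessions)),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat("Marker map:", length(x), "markers,",
      length(unique(unclass(x))), "organelle classes\n")
  print(table(unclass(x)))
  invisible(x)
}

#' Read a contaminant-frequency table
#'
#' CSV with columns `accession,freq`; frequencies are the fraction of
#' CRAPome-style control experiments the protein appears in, in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return Named numeric vector accession -> frequency.
#' @export
read_contaminants <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  f <- tab$freq
  if (any(f < 0 | f > 1)) stop("contaminant frequencies must lie in [0, 1]")
  stats::setNames(as.numeric(f), tab$accession)
}

#' Default contaminant blocklist
#'
#' Accessions removed regardless of contaminant frequency: keratins, serum
#' albumin and the digestion trypsin. Shipped as an editable text file
#' (`extdata/blocklist_default.txt`; one accession per line, `#` comments).
#'
#' @param path Blocklist file; defaults to the shipped file.
#' @return Character vector of accessions.
#' @export
default_blocklist <- function(path = system.file("extdata",
                                                 "blocklist_default.txt",
                                                 package = "mitoshift")) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Filter frequent-contaminant proteins
#'
#' Removes proteins whose contaminant frequency meets the threshold, unless
#' they are organelle markers, plus any protein on an explicit blocklist
#' (typically keratins, serum albumin and trypsin). Proteins absent from the
#' table are treated as frequency 0.
#'
#' @param ds A [profile_dataset()].
#' @param contaminants Named numeric vector accession -> frequency in `[0,1]`.
#' @param markers A [marker_map()]; marker proteins are never removed.
#' @param threshold Removal threshold on the frequency (default 0.1).
#' @param blocklist Character vector of accessions always removed (unless
#'   markers).
#' @return The filtered [profile_dataset()].
#' @export
filter_contaminants <- function(ds, contaminants, markers = NULL,
                                threshold = 0.1, blocklist = character()) {
  acc <- rownames(ds$values)
  freq <- contaminants[acc]
  freq[is.na(freq)] <- 0
  drop <- freq >= threshold | acc %in% blocklist
  if (!is.null(markers)) drop <- drop & !(acc %in% names(markers))
  if (any(drop)) {
    message(sum(drop), " contaminant protein(s) removed")
  }
  ds$values <- ds$values[!drop, , drop = FALSE]
  ds$meta <- ds$meta[!drop, , drop = FALSE]
  ds
}

#' Normalise each replicate block to a composition
#'
#' Scales each protein's fraction block within each replicate to sum to 1,
#' turning reporter-ion abundances into per-replicate compositional profiles
#' (the standard LOPIT convention).
#'
#' @param ds A [profile_dataset()] with non-negative abundances.
#' @return The normalised dataset; every (protein, replicate) block sums to 1.
#' @export
normalise_rows <- function(ds) {
  for (r in ds$scheme$replicates) {
    idx <- .block_index(ds$scheme, r)
    s <- rowSums(ds$values[, idx, drop = FALSE])
    if (any(s <= 0)) {
      stop("degenerate all-zero profile block(s) for: ",
           paste(rownames(ds$values)[s <= 0], collapse = ", "))
    }
    ds$values[, idx] <- ds$values[, idx, drop = FALSE] / s
  }
  ds
}

# Replace zeros in a composition by half the smallest non-zero part of the
# same block, then renormalise. Keeps the ALR transform finite.
.zero_adjust <- function(x) {
  if (!any(x == 0)) return(x)
  pseudo <- min(x[x > 0]) / 2
  x[x == 0] <- pseudo
  x / sum(x)
}

#' Additive log-ratio transform
#'
#' Maps a D-part composition to D-1 unconstrained coordinates
#' `log(x_i / x_D)`, i = 1..D-1, with the last part as reference. Zeros are
#' replaced by half the smallest non-zero part of the block (then
#' renormalised) before taking logs.
#'
#' @param x A composition (numeric vector summing to 1) or a matrix with one
#'   composition per row.
#' @return Numeric vector of length D-1, or matrix with D-1 columns.
#' @seealso [inverse_alr()]
#' @export
alr_transform <- function(x) {
  if (is.matrix(x)) {
    return(t(apply(x, 1L, alr_transform)))
  }
  D <- length(x)
  if (D < 2L) stop("ALR needs at least 2 parts")
  x <- .zero_adjust(x)
  log(x[-D] / x[D])
}

#' Inverse additive log-ratio transform
#'
#' @param z ALR coordinates (length D-1 vector, or matrix with one vector
#'   per row).
#' @return The composition of D parts summing to 1.
#' @export
inverse_alr <- function(z) {
  if (is.matrix(z)) {
    return(t(apply(z, 1L, inverse_alr)))
  }
  e <- exp(c(z, 0))
  e / sum(e)
}

#' Concatenate replicate blocks into one feature vector per protein
#'
#' Returns the proteins x (R * D) matrix whose columns are the replicate
#' fraction blocks in scheme replicate order (rep1 f1..fD, rep2 f1..fD, ...).
#' The ordering follows the scheme, not the input file.
#'
#' @param ds A normalised [profile_dataset()].
#' @return Numeric matrix, proteins x (R * D).
#' @export
concatenate_replicates <- function(ds) {
  ds$values
}

#' Principal component projection of protein profiles
#'
#' Mean-centred PCA with a fixed sign convention (for each component, the
#' loading with the largest magnitude is made positive) so projections are
#' reproducible across runs and platforms.
#'
#' @param X Numeric matrix, proteins x features.
#' @param n_components Number of components to return.
#' @return List with `scores` (proteins x n_components), `explained_variance`
#'   (proportion per component) and `loadings`.
#' @export
pca_projection <- function(X, n_components = 2L) {
  if (ncol(X) < n_components) stop("fewer columns than components requested")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- p$rotation[, k, drop = FALSE]
  scores <- p$x[, k, drop = FALSE]
  for (j in k) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[k],
       loadings = rot)
}

#' Supervised organelle classification at a fixed marker FDR
#'
#' Trains a support vector machine on the concatenated profiles of the
#' organelle markers and assigns each unknown protein the class with the
#' highest class probability, but only when that probability exceeds a
#' per-class score threshold. Thresholds are chosen on held-out markers
#' (stratified cross-validation) as the smallest score at which the false
#' discovery proportion among held-out assignments to that class is at most
#' `fdr`; proteins below threshold are reported `"unassigned"`. Marker
#' proteins always keep their curated label.
#'
#' @param ds A normalised [profile_dataset()].
#' @param markers A [marker_map()]; classes with fewer than 6 markers in the
#'   dataset are excluded with a warning.
#' @param fdr Target false discovery proportion per class (default 0.05).
#' @param folds Number of cross-validation folds for threshold estimation.
#' @param seed Seed for fold assignment and the SVM's internal sampling.
#' @return Data frame with `accession`, `class` (organelle or
#'   `"unassigned"`), `score` and `is_marker`.
#' @export
classify_supervised <- function(ds, markers, fdr = 0.05, folds = 5L,
                                seed = 1L) {
  acc <- rownames(ds$values)
  m_acc <- intersect(names(markers), acc)
  if (!length(m_acc)) stop("no marker proteins present in dataset")
  y <- unclass(markers)[m_acc]
  counts <- table(y)
  small <- names(counts)[counts < 6L]
  if (length(small)) {
    warning("marker classes with < 6 markers excluded: ",
            paste(small, collapse = ", "))
    keep <- !(y %in% small)
    m_acc <- m_acc[keep]
    y <- y[keep]
  }
  y <- factor(y)
  Xm <- ds$values[m_acc, , drop = FALSE]

  .with_seed(seed, {
    # stratified CV held-out scores for threshold calibration
    fold <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    held_class <- character(length(y))
    held_score <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      fit <- e1071::svm(x = Xm[tr, , drop = FALSE], y = droplevels(y[tr]),
                        kernel = "radial", probability = TRUE)
      pr <- attr(stats::predict(fit, Xm[!tr, , drop = FALSE],
                                probability = TRUE), "probabilities")
      held_class[!tr] <- colnames(pr)[max.col(pr, ties.method = "first")]
      held_score[!tr] <- pr[cbind(seq_len(nrow(pr)),
                                  max.col(pr, ties.method = "first"))]
    }
    thresholds <- vapply(levels(y), function(cl) {
      sel <- held_class == cl
      if (!any(sel)) return(Inf)
      s <- held_score[sel]
      ok <- (y == cl)[sel]
      cand <- sort(unique(s))
      for (t in cand) {
        at <- s >= t
        if (any(at) && mean(!ok[at]) <= fdr && (fdr > 0 || all(ok[at]))) {
          return(t)
        }
      }
      Inf
    }, numeric(1L))

    fit <- e1071::svm(x = Xm, y = y, kernel = "radial", probability = TRUE)
    out <- data.frame(accession = acc,
                      class = "unassigned",
                      score = NA_real_,
                      is_marker = acc %in% m_acc,
                      stringsAsFactors = FALSE)
    rownames(out) <- acc
    out[m_acc, "class"] <- as.character(y)
    out[m_acc, "score"] <- 1
    unk <- setdiff(acc, m_acc)
    if (length(unk)) {
      pr <- attr(stats::predict(fit, ds$values[unk, , drop = FALSE],
                                probability = TRUE), "probabilities")
      j <- max.col(pr, ties.method = "first")
      cls <- colnames(pr)[j]
      sc <- pr[cbind(seq_len(nrow(pr)), j)]
      pass <- sc >= thresholds[cls]
      out[unk, "class"] <- ifelse(pass, cls, "unassigned")
      out[unk, "score"] <- sc
    }
    out
  })
}
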