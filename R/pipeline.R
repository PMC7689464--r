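#' Run the full differential-localisation comparison
#'
#' End-to-end pipeline for detecting proteins that relocalise towards the
#' mitochondria between a control and a treatment condition: contaminant
#' filtering, per-replicate sum normalisation, TAGM-MAP organelle
#' classification on the control with discarding of resident mitochondrial /
#' nuclear proteins, a per-protein Gaussian-process Bayes factor comparing
#' shared versus independent profile models, a per-protein robust-Mahalanobis
#' MitoRatio, and dual-threshold hit calling. Bait proteins (the relocated
#' construct itself) are flagged and excluded from the hit count.
#'
#' @param control,treatment [profile_dataset()] objects (raw abundances; the
#'   pipeline normalises), sharing fractions and replicates.
#' @param markers A [marker_map()].
#' @param contaminants Optional named frequency vector
#'   (see [read_contaminants()]).
#' @param contaminant_threshold Removal threshold on contaminant frequency.
#' @param blocklist Accessions removed regardless of frequency.
#' @param discard_classes Organelle classes whose predicted residents are
#'   removed before testing; `NULL` selects them by label pattern via
#'   [match_discard_classes()].
#' @param bf_threshold Hit threshold on the natural-log Bayes factor
#'   (default 14.0).
#' @param ratio_threshold Hit threshold on the log2 MitoRatio (default 0.40).
#' @param bait Accessions of the bait construct(s), reported separately.
#' @param mito_class Label of the mitochondrial marker class.
#' @param gp_priors A [gp_hyperpriors()] object.
#' @param tagm_max_iter,tagm_tol TAGM-MAP EM controls.
#' @param seed Seed for the robust covariance subset search.
#' @param verbose Emit per-stage counts via `message()`.
#' @return An object of class `mito_shift`: list with `table` (the per-protein
#'   hit table), `counts` (`analysed`, `retained`, `hits`), `thresholds`,
#'   `discard_classes`, `tagm` (the control TAGM fit) and `call`.
#' @export
run_comparison <- function(control, treatment, markers,
                           contaminants = NULL, contaminant_threshold = 0.1,
                           blocklist = character(),
                           discard_classes = NULL,
                           bf_threshold = 14.0, ratio_threshold = 0.40,
                           bait = character(),
                           mito_class = "mitochondria",
                           gp_priors = gp_hyperpriors(),
                           tagm_max_iter = 200L, tagm_tol = 1e-8,
                           seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (!is.null(contaminants)) {
    control <- filter_contaminants(control, contaminants, markers,
                                   contaminant_threshold, blocklist)
    treatment <- filter_contaminants(treatment, contaminants, markers,
                                     contaminant_threshold, blocklist)
  }
  control <- normalise_rows(control)
  treatment <- normalise_rows(treatment)
  universe <- intersect(rownames(control$values), rownames(treatment$values))
  if (!length(universe)) stop("run_comparison: empty protein universe")
  say("analysed proteins (shared after contaminant filter): ",
      length(universe))

  # TAGM pre-filter on the control condition only
  Xc <- concatenate_replicates(control)[universe, , drop = FALSE]
  fit <- tryCatch(
    fit_tagm_map(Xc, markers, max_iter = tagm_max_iter, tol = tagm_tol),
    error = function(e) stop("stage tagm: ", conditionMessage(e))
  )
  post <- posterior_localisation(fit, Xc)
  if (is.null(discard_classes)) {
    discard_classes <- match_discard_classes(fit$classes)
  }
  retained <- prefilter_discard(post, discard_classes, markers)
  if (!length(retained)) stop("stage prefilter: empty retained set")
  say("retained after pre-filter (discarded ",
      paste(discard_classes, collapse = ", "), "): ", length(retained))

  bf <- tryCatch(
    bf_test(control, treatment, gp_priors, proteins = retained),
    error = function(e) stop("stage bftest: ", conditionMessage(e))
  )
  mr <- tryCatch(
    mito_ratio_table(control, treatment, markers, mito_class,
                     proteins = retained, seed = seed),
    error = function(e) stop("stage mitoratio: ", conditionMessage(e))
  )

  tab <- data.frame(accession = retained,
                    gene = control$meta[retained, "gene"],
                    tagm_class = unname(post$map_class[retained]),
                    logBF = bf$logBF[match(retained, bf$accession)],
                    log2_mitoratio =
                      mr$log2_mitoratio[match(retained, mr$accession)],
                    stringsAsFactors = FALSE)
  tab$is_bait <- tab$accession %in% bait
  tab$is_hit <- tab$logBF >= bf_threshold &
    tab$log2_mitoratio >= ratio_threshold
  n_hits <- sum(tab$is_hit & !tab$is_bait)
  say("hits (excluding bait): ", n_hits)

  structure(list(table = tab,
                 counts = list(analysed = length(universe),
                               retained = length(retained),
                               hits = n_hits),
                 thresholds = c(logBF = bf_threshold,
                                log2_mitoratio = ratio_threshold),
                 discard_classes = discard_classes,
                 tagm = fit,
                 call = match.call()),
            class = "mito_shift")
}

#' @export
print.mito_shift <- function(x, ...) {
  cat("Differential localisation comparison\n")
  cat("  analysed proteins: ", x$counts$analysed, "\n", sep = "")
  cat("  retained after pre-filter (",
      paste(x$discard_classes, collapse = ", "), " discarded): ",
      x$counts$retained, "\n", sep = "")
  cat("  thresholds: log_e(BF) >= ", x$thresholds[["logBF"]],
      ", log2(MitoRatio) >= ", x$thresholds[["log2_mitoratio"]],
      "\n", sep = "")
  cat("  hits (excluding bait): ", x$counts$hits, "\n", sep = "")
  if (any(x$table$is_bait)) {
    cat("  bait: ", paste(x$table$accession[x$table$is_bait],
                          collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mito_shift <- function(object, ...) {
  print(object)
  hits <- object$table[object$table$is_hit & !object$table$is_bait, ]
  hits <- hits[order(-hits$log2_mitoratio), ]
  cat("\nTop hits by MitoRatio:\n")
  print(utils::head(hits[, c("accession", "gene", "tagm_class",
                             "logBF", "log2_mitoratio")], 10L),
        row.names = FALSE)
  invisible(object)
}

#' Scatter plot of MitoRatio versus Bayes factor
#'
#' @param x A `mito_shift` object.
#' @param truncate_axes Start the axes at the thresholds (only the hit
#'   quadrant is shown).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mito_shift <- function(x, truncate_axes = FALSE, ...) {
  tab <- x$table
  bf_t <- x$thresholds[["logBF"]]
  mr_t <- x$thresholds[["log2_mitoratio"]]
  if (truncate_axes) {
    tab <- tab[tab$logBF >= bf_t & tab$log2_mitoratio >= mr_t, , drop = FALSE]
  }
  graphics::plot(tab$logBF, tab$log2_mitoratio,
                 pch = 16, cex = 0.5,
                 col = ifelse(tab$is_bait, "red",
                              ifelse(tab$is_hit, "dodgerblue3", "grey60")),
                 xlab = expression(log[e] ~ "Bayes factor"),
                 ylab = expression(log[2] ~ "MitoRatio"), ...)
  graphics::abline(v = bf_t, h = mr_t, lty = 2, col = "grey40")
  if (any(tab$is_bait)) {
    graphics::text(tab$logBF[tab$is_bait], tab$log2_mitoratio[tab$is_bait],
                   labels = tab$gene[tab$is_bait], pos = 2, col = "red",
                   cex = 0.8)
  }
  invisible(x)
}

#' Write the hit plot to a figure file
#'
#' @param x A `mito_shift` object.
#' @param file Output path; `.pdf` and `.png` are supported.
#' @param truncate_axes See [plot.mito_shift()].
#' @param width,height Device size in inches.
#' @return `file`, invisibly.
#' @export
hit_plot <- function(x, file, truncate_axes = FALSE, width = 6, height = 5) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    grDevices::png(file, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::pdf(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  plot(x, truncate_axes = truncate_axes)
  invisible(file)
}

#' Write the hit table to TSV
#'
#' @param x A `mito_shift` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Calibrate dual thresholds from confirmed positives and negatives
#'
#' Chooses the Bayes-factor and MitoRatio thresholds empirically from
#' experimentally confirmed relocalisers (positives, e.g. known vesicle
#' cargo or the subunits of a complex that must all be hits) and confirmed
#' non-relocalisers (negatives). Returns the largest threshold pair on the
#' observed score grid such that every positive passes both thresholds and
#' no negative passes both; when no such pair exists, returns the pair
#' maximising (positives covered - negatives covered), ties broken towards
#' stricter thresholds, with `feasible = FALSE`.
#'
#' @param scores Data frame with columns `accession`, `logBF`,
#'   `log2_mitoratio` (e.g. the `table` of a `mito_shift` object).
#' @param positives Non-empty accession set that must all be hits.
#' @param negatives Accession set that must not be hits (disjoint from
#'   `positives`).
#' @return List with `bf_threshold`, `ratio_threshold` and `feasible`.
#' @export
calibrate_thresholds <- function(scores, positives, negatives = character()) {
  if (!length(positives)) stop("positives must be non-empty")
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap")
  }
  pos <- scores[scores$accession %in% positives, , drop = FALSE]
  neg <- scores[scores$accession %in% negatives, , drop = FALSE]
  if (nrow(pos) < length(unique(positives))) {
    stop("some positives are absent from the score table")
  }
  bf_star <- min(pos$logBF)
  mr_star <- min(pos$log2_mitoratio)
  neg_pass <- function(bf, mr) {
    nrow(neg) && any(neg$logBF >= bf & neg$log2_mitoratio >= mr)
  }
  if (!neg_pass(bf_star, mr_star)) {
    return(list(bf_threshold = bf_star, ratio_threshold = mr_star,
                feasible = TRUE))
  }
  # infeasible: search the observed score grid for the best compromise
  cand_bf <- sort(unique(c(pos$logBF, neg$logBF)), decreasing = TRUE)
  cand_mr <- sort(unique(c(pos$log2_mitoratio, neg$log2_mitoratio)),
                  decreasing = TRUE)
  best <- NULL
  best_score <- -Inf
  for (bf in cand_bf) {
    for (mr in cand_mr) {
      sc <- sum(pos$logBF >= bf & pos$log2_mitoratio >= mr) -
        sum(neg$logBF >= bf & neg$log2_mitoratio >= mr)
      if (sc > best_score) {
        best_score <- sc
        best <- c(bf, mr)
      }
    }
  }
  list(bf_threshold = best[1L], ratio_threshold = best[2L], feasible = FALSE)
}
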