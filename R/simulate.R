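#' Build organelle profile templates
#'
#' Creates one template composition per organelle class over `D` fractions.
#' Each class peaks in a different region of the fraction gradient (as real
#' organelles do under differential centrifugation), with a seeded jitter in
#' additive log-ratio (ALR) space. Templates are regenerated until every pair
#' is at least `separation` apart in Aitchison distance, or an error is
#' raised after `max_tries` attempts.
#'
#' @param classes Character vector of organelle class labels (at least 2);
#'   one must be `"mitochondria"` for relocation simulations.
#' @param D Number of fractions.
#' @param seed RNG seed; templates are deterministic given the seed.
#' @param separation Minimum pairwise Aitchison distance between template
#'   means (default 2).
#' @param spread Within-class spread multiplier per class (recycled).
#' @param max_tries Bounded number of redraws before failing.
#' @return List of templates, each `list(class, mean, spread)` with `mean` a
#'   composition summing to 1.
#' @export
make_templates <- function(classes, D, seed = 1L, separation = 2,
                           spread = 1, max_tries = 100L) {
  classes <- as.character(classes)
  K <- length(classes)
  if (K < 2L) stop("need at least 2 organelle classes")
  spread <- rep_len(spread, K)
  clr <- function(x) log(x) - mean(log(x))
  aitchison <- function(x, y) sqrt(sum((clr(x) - clr(y))^2))
  .with_seed(seed, {
    for (try in seq_len(max_tries)) {
      centres <- if (K > 1L) 1 + (seq_len(K) - 1L) * (D - 1) / (K - 1) else D / 2
      centres <- centres + stats::runif(K, -0.5, 0.5)
      width <- stats::runif(K, 1, 2)
      # profile contrast is raised gently across retries; pairwise Aitchison
      # distances scale with it, so any floor is eventually met
      contrast <- 1 + 0.15 * (try - 1L)
      means <- lapply(seq_len(K), function(k) {
        base <- exp(-(seq_len(D) - centres[k])^2 / (2 * width[k]^2)) + 0.02
        base <- base / sum(base)
        inverse_alr((alr_transform(base) +
                       stats::rnorm(D - 1L, 0, 0.15)) * contrast)
      })
      dmin <- Inf
      for (i in seq_len(K - 1L)) {
        for (j in (i + 1L):K) {
          dmin <- min(dmin, aitchison(means[[i]], means[[j]]))
        }
      }
      if (dmin >= separation) {
        return(lapply(seq_len(K), function(k) {
          list(class = classes[k], mean = means[[k]], spread = spread[k])
        }))
      }
    }
    stop("could not achieve template separation ", separation,
         " after ", max_tries, " tries")
  })
}

#' Standard organelle template set
#'
#' Templates for a typical differential-centrifugation organelle panel
#' (mitochondria, nucleus, ER, Golgi, endosome, lysosome, plasma membrane,
#' cytosol, ribosome) over `D` fractions, via [make_templates()].
#'
#' @param D Number of fractions (default 10).
#' @param seed RNG seed.
#' @param ... Passed to [make_templates()].
#' @return A template list (see [make_templates()]).
#' @export
default_templates <- function(D = 10L, seed = 1L, ...) {
  make_templates(c("mitochondria", "nucleus", "ER", "golgi", "endosome",
                   "lysosome", "PM", "cytosol", "ribosome"),
                 D = D, seed = seed, ...)
}

#' Simulation configuration
#'
#' Parameters of the synthetic LOPIT-DC generator. Defaults emulate a
#' three-replicate differential-centrifugation design with organelle-clustered
#' compositional profiles, a small heavy-tailed outlier population, and a
#' minority of proteins whose treatment profile is partially displaced toward
#' the mitochondrial template (displacement coefficient `alpha`, partial
#' shifts in `[0.5, 1]`).
#'
#' @param n_proteins Total proteins simulated.
#' @param n_markers_per_class Curated markers per organelle class.
#' @param R Replicates per condition.
#' @param conditions Two condition labels (control first).
#' @param outlier_fraction Fraction of proteins drawn from the heavy-tailed
#'   outlier component (never markers).
#' @param reloc_fraction Fraction of proteins relocated toward mitochondria
#'   in the treatment condition (never markers nor outliers).
#' @param reloc_alpha_range Interval in `[0, 1]` the displacement coefficient
#'   is drawn from; `alpha = 1` means the treatment template equals the
#'   mitochondrial template.
#' @param noise_sd Replicate-level Gaussian noise SD in ALR space.
#' @param protein_sd Protein-level dispersion SD around the class template in
#'   ALR space (shared across conditions and replicates).
#' @param outlier_df Degrees of freedom of the multivariate-T outlier draw.
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000L, n_markers_per_class = 25L,
                       R = 3L, conditions = c("control", "treatment"),
                       outlier_fraction = 0.05, reloc_fraction = 0.025,
                       reloc_alpha_range = c(0.5, 1),
                       noise_sd = 0.15, protein_sd = 0.25,
                       outlier_df = 4, seed = 1L) {
  stopifnot(length(conditions) == 2L,
            outlier_fraction >= 0, reloc_fraction >= 0,
            noise_sd > 0, protein_sd >= 0)
  if (outlier_fraction + reloc_fraction > 1) {
    stop("outlier_fraction + reloc_fraction must not exceed 1")
  }
  if (any(reloc_alpha_range < 0) || any(reloc_alpha_range > 1)) {
    stop("reloc_alpha_range must lie within [0, 1]")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_markers_per_class = as.integer(n_markers_per_class),
                 R = as.integer(R), conditions = conditions,
                 outlier_fraction = outlier_fraction,
                 reloc_fraction = reloc_fraction,
                 reloc_alpha_range = sort(reloc_alpha_range),
                 noise_sd = noise_sd, protein_sd = protein_sd,
                 outlier_df = outlier_df, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-condition LOPIT-DC dataset with known ground truth
#'
#' Each protein belongs to an organelle class; its per-replicate profile is a
#' logistic-normal perturbation of the class template (Gaussian noise in ALR
#' space, mapped back to the simplex). A protein-level offset is drawn once
#' and shared across conditions, so under the null the two conditions follow
#' an identical generative law. Outlier proteins draw their (condition-shared)
#' base profile from a multivariate-T centred on the global template mean.
#' Relocated proteins have their treatment template replaced by
#' `(1 - alpha) * source + alpha * mitochondria` on the simplex before
#' perturbation; their source classes are the trafficking compartments
#' (never the mitochondrial or nuclear classes, whose residents are what a
#' downstream pre-filter removes and for which a shift toward the
#' mitochondrial template would be ill-defined). Markers are never outliers
#' nor relocated.
#'
#' @param cfg A [sim_config()].
#' @param templates Output of [make_templates()]; must contain a class named
#'   `"mitochondria"` when `reloc_fraction > 0`.
#' @return List with elements `control` and `treatment` (each a
#'   [profile_dataset()]), `markers` (a [marker_map()]) and `truth` (data
#'   frame: `accession`, `class`, `is_outlier`, `is_relocated`, `alpha`).
#' @export
simulate_dataset <- function(cfg, templates) {
  classes <- vapply(templates, `[[`, character(1L), "class")
  K <- length(classes)
  D <- length(templates[[1L]]$mean)
  mito_idx <- which(classes == "mitochondria")
  if (cfg$reloc_fraction > 0 && !length(mito_idx)) {
    stop("relocation requires a 'mitochondria' template")
  }
  n <- cfg$n_proteins
  n_mark <- K * cfg$n_markers_per_class
  if (n_mark >= n) stop("n_proteins too small for the requested markers")

  .with_seed(cfg$seed, {
    acc <- sprintf("SIM%05d", seq_len(n))
    cls_idx <- integer(n)
    cls_idx[seq_len(n_mark)] <- rep(seq_len(K), each = cfg$n_markers_per_class)
    cls_idx[(n_mark + 1L):n] <- sample(K, n - n_mark, replace = TRUE)
    is_marker <- seq_len(n) <= n_mark

    free <- which(!is_marker)
    n_out <- round(cfg$outlier_fraction * n)
    n_rel <- round(cfg$reloc_fraction * n)
    if (n_out + n_rel > length(free)) {
      stop("not enough non-marker proteins for outliers + relocated")
    }
    out_pick <- sample(free, n_out)
    is_outlier <- seq_len(n) %in% out_pick
    # relocating cargo originates from the trafficking compartments, not from
    # the resident mitochondrial/nuclear population the pre-filter removes
    reloc_ok <- setdiff(free, out_pick)
    reloc_ok <- reloc_ok[!(classes[cls_idx[reloc_ok]] %in%
                             match_discard_classes(classes))]
    if (n_rel > length(reloc_ok)) {
      stop("not enough eligible non-marker proteins to relocate")
    }
    is_reloc <- seq_len(n) %in% sample(reloc_ok, n_rel)
    alpha <- rep(NA_real_, n)
    alpha[is_reloc] <- stats::runif(n_rel, cfg$reloc_alpha_range[1L],
                                    cfg$reloc_alpha_range[2L])

    tmpl_alr <- t(vapply(templates, function(t) alr_transform(t$mean),
                         numeric(D - 1L)))
    global_mu <- colMeans(tmpl_alr)
    global_S <- .ridge_spd(stats::cov(tmpl_alr), rel = 1e-4)
    Lg <- chol(global_S)

    # condition-shared per-protein base profile in ALR space
    base <- matrix(0, n, D - 1L)
    for (i in seq_len(n)) {
      if (is_outlier[i]) {
        z <- stats::rnorm(D - 1L) %*% Lg
        base[i, ] <- global_mu +
          z / sqrt(stats::rchisq(1L, cfg$outlier_df) / cfg$outlier_df)
      } else {
        sp <- templates[[cls_idx[i]]]$spread
        base[i, ] <- tmpl_alr[cls_idx[i], ] +
          stats::rnorm(D - 1L, 0, cfg$protein_sd * sp)
      }
    }
    # treatment base: relocated templates displaced toward mitochondria on
    # the simplex; the protein-level offset is preserved
    base_tr <- base
    for (i in which(is_reloc)) {
      src <- templates[[cls_idx[i]]]$mean
      tgt <- templates[[mito_idx]]$mean
      moved <- (1 - alpha[i]) * src + alpha[i] * tgt
      base_tr[i, ] <- base[i, ] - tmpl_alr[cls_idx[i], ] +
        alr_transform(moved)
    }

    fr <- sprintf("F%02d", seq_len(D))
    reps <- sprintf("rep%d", seq_len(cfg$R))
    one_condition <- function(mu_mat, condition) {
      vals <- matrix(0, n, cfg$R * D,
                     dimnames = list(acc, NULL))
      for (r in seq_len(cfg$R)) {
        eps <- matrix(stats::rnorm(n * (D - 1L), 0, cfg$noise_sd), n)
        prof <- inverse_alr(mu_mat + eps)
        scale_i <- exp(stats::rnorm(n, log(1e6), 0.2))
        vals[, (r - 1L) * D + seq_len(D)] <- prof * scale_i
      }
      sch <- fraction_scheme(fr, reps, condition)
      meta <- data.frame(accession = acc, gene = acc,
                         marker = ifelse(is_marker, classes[cls_idx],
                                         "unknown"),
                         stringsAsFactors = FALSE)
      profile_dataset(vals, sch, meta)
    }
    control <- one_condition(base, cfg$conditions[1L])
    treatment <- one_condition(base_tr, cfg$conditions[2L])

    list(control = control,
         treatment = treatment,
         markers = marker_map(acc[is_marker], classes[cls_idx[is_marker]]),
         truth = data.frame(accession = acc,
                            class = classes[cls_idx],
                            is_outlier = is_outlier,
                            is_relocated = is_reloc,
                            alpha = alpha,
                            stringsAsFactors = FALSE))
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the control and treatment quantitation TSVs in the format
#' [read_dataset()] reads, the marker CSV, and a `truth.tsv` with the
#' generating ground truth.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dataset(sim$control, file.path(dir, "control.tsv"))
  write_dataset(sim$treatment, file.path(dir, "treatment.tsv"))
  utils::write.csv(data.frame(accession = names(sim$markers),
                              organelle = unclass(sim$markers)),
                   file.path(dir, "markers.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
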