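#' Default TAGM priors derived from the data
#'
#' Conjugate prior hyperparameters for the T-augmented Gaussian mixture:
#' a Normal--Inverse-Wishart prior on each organelle Gaussian, a symmetric
#' Dirichlet on the mixing weights, a Beta prior on the outlier weight, and
#' a fixed multivariate-T outlier component whose location and scale are set
#' from the data. The concrete defaults follow the published TAGM method's
#' documented defaults: `mu0` the overall data mean, `lambda0 = 0.01`,
#' `nu0 = p + 2`, `S0 = diag(variances) / K^(2/p)`, `beta0 = 1` per class,
#' Beta(2, 10) on the outlier weight, T degrees of freedom `kappa = 4`,
#' outlier location the data mean and outlier scale half the data covariance.
#'
#' @param X Numeric matrix, proteins x features (concatenated profiles).
#' @param markers A [marker_map()] covering all classes to be fitted.
#' @return An object of class `tagm_priors`.
#' @export
default_priors <- function(X, markers) {
  p <- ncol(X)
  K <- length(unique(unclass(markers)))
  mu0 <- colMeans(X)
  S <- stats::cov(X)
  if (!all(is.finite(S)) || min(eigen(S, symmetric = TRUE,
                                      only.values = TRUE)$values) < 1e-12) {
    warning("singular data covariance; regularisation applied")
    S <- .ridge_spd(S)
  }
  structure(list(
    beta0 = rep(1, K),
    mu0 = mu0,
    lambda0 = 0.01,
    nu0 = p + 2,
    S0 = diag(apply(X, 2L, stats::var), p) / K^(2 / p),
    u = 2, v = 10,
    kappa = 4,
    M = mu0,
    V = .ridge_spd(S / 2)
  ), class = "tagm_priors")
}

# log NIW + Dirichlet + Beta prior density (up to constants), for the
# log-posterior trace.
.tagm_log_prior <- function(mu, Sigma, pi_k, eps, pr) {
  K <- length(pi_k)
  p <- length(pr$mu0)
  lp <- sum((pr$beta0 - 1) * log(pi_k))
  lp <- lp + (pr$u - 1) * log(eps) + (pr$v - 1) * log(1 - eps)
  for (k in seq_len(K)) {
    L <- chol(Sigma[[k]])
    logdet <- 2 * sum(log(diag(L)))
    Sinv_d <- backsolve(L, backsolve(L, mu[k, ] - pr$mu0, transpose = TRUE))
    lp <- lp - 0.5 * (pr$nu0 + p + 2) * logdet -
      0.5 * sum(diag(backsolve(L, backsolve(L, pr$S0, transpose = TRUE)))) -
      0.5 * pr$lambda0 * sum((mu[k, ] - pr$mu0) * Sinv_d)
  }
  lp
}

#' Fit a T-augmented Gaussian mixture by maximum a posteriori EM
#'
#' Probabilistic organelle assignment: one Gaussian component per organelle
#' class plus a single fixed heavy-tailed multivariate-T outlier component.
#' Marker proteins have fixed class membership (only their outlier indicator
#' is latent); unknown proteins are allocated across all classes. Parameters
#' are obtained by expectation--maximisation on the log posterior under the
#' conjugate priors, initialised deterministically from per-class marker
#' moments. The log posterior is checked for monotonicity at every step.
#'
#' @param X Numeric matrix, proteins x features; row names are accessions.
#' @param markers A [marker_map()]; every class needs at least 2 markers
#'   present in `X`.
#' @param priors A `tagm_priors` object; defaults to [default_priors()].
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-posterior change at which to declare convergence.
#' @param epsilon Optional fixed outlier weight (e.g. 0 disables the outlier
#'   component); `NULL` (default) learns it.
#' @return An object of class `tagm_map` with per-class means `mu`,
#'   covariances `Sigma`, weights `pi`, outlier weight `epsilon`, the
#'   log-posterior trace, and a `converged` flag.
#' @export
fit_tagm_map <- function(X, markers, priors = NULL, max_iter = 200L,
                         tol = 1e-8, epsilon = NULL) {
  acc <- rownames(X)
  if (is.null(acc)) stop("X must have accession row names")
  m_acc <- intersect(names(markers), acc)
  classes <- sort(unique(unclass(markers)[m_acc]))
  K <- length(classes)
  p <- ncol(X)
  n <- nrow(X)
  m_class <- match(unclass(markers)[m_acc], classes)
  if (any(table(factor(m_class, levels = seq_len(K))) < 2L)) {
    stop("every class needs at least 2 markers present in X")
  }
  if (is.null(priors)) priors <- default_priors(X, markers)
  if (length(priors$beta0) != K) priors$beta0 <- rep_len(priors$beta0, K)
  is_marker <- acc %in% m_acc
  z_marker <- integer(n)
  z_marker[match(m_acc, acc)] <- m_class

  # initialise from marker class moments
  mu <- matrix(0, K, p)
  Sigma <- vector("list", K)
  for (k in seq_len(K)) {
    Xk <- X[is_marker & z_marker == k, , drop = FALSE]
    mu[k, ] <- colMeans(Xk)
    Sk <- if (nrow(Xk) > 1L) stats::cov(Xk) else diag(p)
    Sigma[[k]] <- .ridge_spd((Sk * max(nrow(Xk) - 1L, 1L) + priors$S0) /
                               (priors$nu0 + nrow(Xk) + p + 2))
  }
  pi_k <- rep(1 / K, K)
  eps <- if (is.null(epsilon)) 0.05 else epsilon
  eps_fixed <- !is.null(epsilon)

  log_t <- .log_dmvt(X, priors$M, priors$V, priors$kappa)
  trace <- numeric(0L)
  prev <- -Inf
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # E-step: joint responsibilities over (class, inlier/outlier)
    log_norm <- matrix(0, n, K)
    for (k in seq_len(K)) {
      log_norm[, k] <- .log_dmvnorm(X, mu[k, ], Sigma[[k]])
    }
    le <- if (eps > 0) log(eps) else -Inf
    l1e <- if (eps < 1) log1p(-eps) else -Inf
    # a[, k]: P(z=k, inlier); b[, k]: P(z=k, outlier) (unnormalised, logs)
    la <- sweep(log_norm, 2L, log(pi_k) + l1e, `+`)
    lb <- outer(log_t + le, log(pi_k), `+`)
    for (i in which(is_marker)) {
      keep <- z_marker[i]
      la[i, -keep] <- -Inf
      lb[i, -keep] <- -Inf
    }
    M_i <- pmax(apply(la, 1L, max), apply(lb, 1L, max))
    den <- rowSums(exp(la - M_i)) + rowSums(exp(lb - M_i))
    ll <- sum(M_i + log(den))
    r_in <- exp(la - M_i) / den       # n x K inlier responsibilities
    r_out <- exp(lb - M_i) / den      # n x K outlier responsibilities

    lp <- ll + .tagm_log_prior(mu, Sigma, pi_k, max(eps, 1e-12),
                               priors)
    if (!is.finite(lp)) {
      stop("non-finite log-posterior at iteration ", it)
    }
    if (length(trace) && lp < prev - 1e-6 * abs(prev) - 1e-8) {
      stop("EM monotonicity violated at iteration ", it,
           " (", prev, " -> ", lp, ")")
    }
    trace <- c(trace, lp)
    if (length(trace) > 1L &&
        abs(lp - prev) <= tol * (abs(prev) + tol)) {
      converged <- TRUE
      break
    }
    prev <- lp

    # M-step
    gam <- r_in                      # inlier-and-class weights
    n_k <- colSums(gam)
    n_tot_k <- colSums(r_in + r_out)
    pi_k <- (n_tot_k + priors$beta0 - 1) / (n + sum(priors$beta0) - K)
    pi_k <- pmax(pi_k, 1e-12)
    pi_k <- pi_k / sum(pi_k)
    if (!eps_fixed) {
      b_tot <- sum(r_out)
      eps <- (b_tot + priors$u - 1) / (n + priors$u + priors$v - 2)
      eps <- min(max(eps, 1e-12), 1 - 1e-12)
    }
    for (k in seq_len(K)) {
      if (n_k[k] < 1e-10) next
      xbar <- colSums(gam[, k] * X) / n_k[k]
      Xc <- sweep(X, 2L, xbar)
      Ck <- crossprod(Xc * sqrt(gam[, k]))
      d0 <- xbar - priors$mu0
      Sk <- priors$S0 + Ck +
        (priors$lambda0 * n_k[k] / (priors$lambda0 + n_k[k])) * tcrossprod(d0)
      mu[k, ] <- (priors$lambda0 * priors$mu0 + n_k[k] * xbar) /
        (priors$lambda0 + n_k[k])
      Sigma[[k]] <- .ridge_spd(Sk / (priors$nu0 + n_k[k] + p + 2))
    }
  }

  rownames(mu) <- classes
  names(Sigma) <- classes
  structure(list(classes = classes, mu = mu, Sigma = Sigma,
                 pi = stats::setNames(pi_k, classes), epsilon = eps,
                 priors = priors, converged = converged,
                 log_posterior = trace,
                 markers = stats::setNames(unclass(markers)[m_acc], m_acc)),
            class = "tagm_map")
}

#' @export
print.tagm_map <- function(x, ...) {
  cat("TAGM-MAP fit:", length(x$classes), "organelle classes,",
      length(x$priors$mu0), "profile dimensions\n")
  cat("  outlier weight epsilon:", signif(x$epsilon, 4L), "\n")
  cat("  converged:", x$converged, "after", length(x$log_posterior),
      "iterations\n")
  invisible(x)
}

#' Posterior localisation probabilities under a TAGM fit
#'
#' Computes, for each protein, the posterior probability of membership in
#' each organelle class and in the heavy-tailed outlier component; the
#' class probabilities plus the outlier probability sum to 1. The reported
#' `map_class` is the highest-probability category (possibly `"outlier"`).
#'
#' @param fit A `tagm_map` object from [fit_tagm_map()].
#' @param X Numeric matrix of profiles (rows are proteins) to localise.
#' @return An object of class `tagm_posterior`: a list with `prob`
#'   (proteins x classes), `outlier_prob` and `map_class`.
#' @export
posterior_localisation <- function(fit, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  K <- length(fit$classes)
  n <- nrow(X)
  pr <- fit$priors
  log_t <- .log_dmvt(X, pr$M, pr$V, pr$kappa)
  la <- matrix(0, n, K)
  for (k in seq_len(K)) {
    la[, k] <- log(fit$pi[k]) + log1p(-fit$epsilon) +
      .log_dmvnorm(X, fit$mu[k, ], fit$Sigma[[k]])
  }
  lb <- outer(log_t + log(max(fit$epsilon, 1e-300)), log(fit$pi), `+`)
  M_i <- pmax(apply(la, 1L, max), apply(lb, 1L, max))
  den <- rowSums(exp(la - M_i)) + rowSums(exp(lb - M_i))
  prob <- exp(la - M_i) / den
  out_p <- rowSums(exp(lb - M_i)) / den
  colnames(prob) <- fit$classes
  rownames(prob) <- rownames(X)
  full <- cbind(prob, outlier = out_p)
  map <- colnames(full)[max.col(full, ties.method = "first")]
  structure(list(prob = prob,
                 outlier_prob = stats::setNames(out_p, rownames(X)),
                 map_class = stats::setNames(map, rownames(X))),
            class = "tagm_posterior")
}

#' Predict method for TAGM fits
#'
#' @param object A `tagm_map` fit.
#' @param newdata Profile matrix to localise.
#' @param ... Unused.
#' @return A `tagm_posterior` (see [posterior_localisation()]).
#' @export
predict.tagm_map <- function(object, newdata, ...) {
  posterior_localisation(object, newdata)
}

#' @export
print.tagm_posterior <- function(x, ...) {
  cat("TAGM posterior for", nrow(x$prob), "proteins\n")
  print(table(x$map_class))
  invisible(x)
}

#' Discard proteins localised to unwanted compartments
#'
#' Pre-filtering step for differential-localisation analysis: proteins whose
#' maximum a posteriori class is in `discard_classes` (typically the
#' mitochondrial and nuclear compartments, matched on the control condition)
#' are removed, since resident proteins of the capture compartment obscure
#' incoming relocalisers. Marker proteins of non-discarded classes are always
#' retained.
#'
#' @param post A `tagm_posterior` from [posterior_localisation()].
#' @param discard_classes Character vector of class labels to discard; must
#'   be a subset of the model classes. See [match_discard_classes()] for the
#'   default pattern-based selection.
#' @param markers Optional [marker_map()]; markers of retained classes are
#'   kept regardless of their MAP class.
#' @return Character vector of retained accessions.
#' @export
prefilter_discard <- function(post, discard_classes, markers = NULL) {
  model_classes <- colnames(post$prob)
  bad <- setdiff(discard_classes, model_classes)
  if (length(bad)) {
    stop("unknown discard class(es): ", paste(bad, collapse = ", "))
  }
  acc <- rownames(post$prob)
  keep <- !(post$map_class %in% discard_classes)
  if (!is.null(markers)) {
    keep_marker <- acc %in% names(markers) &
      !(unclass(markers)[acc] %in% discard_classes)
    keep_marker[is.na(keep_marker)] <- FALSE
    keep <- keep | keep_marker
  }
  acc[keep]
}

#' Select discard classes by label pattern
#'
#' Matches class labels against case-insensitive patterns for mitochondrial,
#' nuclear and chromatin compartments (`"mito"`, `"nucle"`, `"chromatin"`),
#' the compartments whose resident proteins are removed before relocalisation
#' analysis.
#'
#' @param classes Character vector of model class labels.
#' @param patterns Regular expressions matched case-insensitively.
#' @return The subset of `classes` matching any pattern.
#' @export
match_discard_classes <- function(classes,
                                  patterns = c("mito", "nucle", "chromatin")) {
  classes[Reduce(`|`, lapply(patterns, grepl, x = classes,
                             ignore.case = TRUE))]
}
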