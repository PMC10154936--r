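# Canonical (linear) discriminant analysis of genotype-mean traits by
# ecotype: canonical axes, eigenvalue shares ("percent discrimination"),
# structure-coefficient loadings and resubstitution classification accuracy.

#' Fit a canonical discriminant analysis
#'
#' Solves the generalized eigenproblem of between-group versus pooled
#' within-group scatter. Traits are internally standardized to unit pooled
#' within-group variance for numerical stability and the axes are
#' back-transformed, so results are invariant to affine rescaling of any
#' trait. Axes are ordered by decreasing eigenvalue; scores are centred on
#' the grand mean. Loadings are reported as pooled within-group correlations
#' between each trait and each canonical axis (structure coefficients); the
#' raw discriminant coefficients are also returned.
#'
#' @param means numeric matrix or data frame of genotype-mean traits
#'   (complete cases only), rows = genotypes.
#' @param groups vector of group (ecotype) labels, one per row.
#' @param ridge optional ridge added to the within-group scatter diagonal
#'   (fraction of its mean diagonal) to rescue singular fits.
#' @return An object of class `ecosel_lda` with elements `canonical_axes`,
#'   `eigenvalues`, `pct_discrimination`, `loadings`, `coefficients`,
#'   `group_centroids`, `scores`, `confusion`, `accuracy_overall`,
#'   `accuracy_by_group`, and the fitted `means`/`pooled_cov` needed for
#'   classification.
#' @seealso [lda_classify()]
#' @export
lda_fit <- function(means, groups, ridge = 0) {
  X <- as.matrix(as.data.frame(means))
  storage.mode(X) <- "double"
  groups <- factor(as.character(groups))
  if (nrow(X) != length(groups)) {
    ecosel_error("ecosel_lda_error", "means and groups differ in length")
  }
  if (any(!complete.cases(X))) {
    ecosel_error("ecosel_lda_error", "means must be complete cases")
  }
  k <- nlevels(groups)
  sizes <- table(groups)
  if (k < 2 || any(sizes < 2)) {
    ecosel_error("ecosel_lda_error",
                 "need >= 2 groups with >= 2 members each")
  }
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

  grand <- colMeans(X)
  M <- rowsum(X, groups) / as.vector(sizes)       # group centroids
  W <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (g in levels(groups)) {
    Xc <- sweep(X[groups == g, , drop = FALSE], 2, M[g, ])
    W <- W + crossprod(Xc)
  }
  B <- crossprod(sweep(M, 2, grand) * sqrt(as.vector(sizes)))
  if (ridge > 0) W <- W + diag(ridge * mean(diag(W)), p)

  # standardize to unit pooled within-group variance, then whiten
  s_w <- sqrt(diag(W) / (n - k))
  if (any(s_w <= 0)) {
    ecosel_error("ecosel_lda_error",
                 sprintf("trait(s) with zero within-group variance: %s",
                         paste(colnames(X)[s_w <= 0], collapse = ", ")))
  }
  D <- diag(1 / s_w, p)
  Ws <- D %*% W %*% D
  Bs <- D %*% B %*% D
  ew <- eigen(Ws, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-10) {
    ecosel_error("ecosel_lda_error",
                 paste("within-group scatter is (near-)singular; remove",
                       "collinear traits or set a ridge > 0"))
  }
  Whalf <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  es <- eigen(Whalf %*% Bs %*% Whalf, symmetric = TRUE)
  n_axes <- min(k - 1, p)
  eigenvalues <- pmax(es$values[seq_len(n_axes)], 0)
  A <- D %*% Whalf %*% es$vectors[, seq_len(n_axes), drop = FALSE]
  # scale axes to unit pooled within-group variance of scores
  wvar <- diag(t(A) %*% W %*% A) / (n - k)
  A <- sweep(A, 2, sqrt(wvar), "/")
  dimnames(A) <- list(colnames(X), paste0("CA", seq_len(n_axes)))

  scores <- sweep(X, 2, grand) %*% A
  centroids <- sweep(M, 2, grand) %*% A

  # structure coefficients: pooled within-group trait/score correlations
  loadings <- matrix(0, p, n_axes, dimnames = dimnames(A))
  for (j in seq_len(p)) {
    for (a in seq_len(n_axes)) {
      cw <- 0
      for (g in levels(groups)) {
        idx <- groups == g
        cw <- cw + sum((X[idx, j] - M[g, j]) *
                         (scores[idx, a] - centroids[g, a]))
      }
      loadings[j, a] <- (cw / (n - k)) / s_w[j]  # score within-sd is 1
    }
  }

  fit <- structure(list(
    canonical_axes = A,
    eigenvalues = eigenvalues,
    pct_discrimination = if (sum(eigenvalues) > 0)
      eigenvalues / sum(eigenvalues) else rep(NA_real_, n_axes),
    loadings = loadings,
    coefficients = A,
    group_centroids = centroids,
    scores = scores,
    grand_mean = grand,
    group_means = M,
    pooled_cov = W / (n - k),
    groups = groups,
    trait_names = colnames(X)
  ), class = "ecosel_lda")

  cls <- lda_classify(fit, X, truth = groups)
  fit$confusion <- cls$confusion
  fit$accuracy_overall <- cls$accuracy_overall
  fit$accuracy_by_group <- cls$accuracy_by_group
  fit$predicted <- cls$predicted
  fit
}

#' Classify rows with a fitted discriminant analysis
#'
#' Assigns each row to the group with the maximal linear discriminant score
#' under equal priors and the pooled within-group covariance. With `truth`
#' supplied, a confusion matrix and overall/per-group accuracies are
#' computed. `method = "loo"` refits the group means and pooled covariance
#' without each row before classifying it (leave-one-out), which requires
#' `means`/`truth` to be the training data.
#'
#' @param fit an [lda_fit()] result.
#' @param means trait matrix with the fitted trait set.
#' @param truth optional true group labels.
#' @param method `"resubstitution"` (default) or `"loo"`.
#' @return List with `predicted` and, when `truth` is given, `confusion`,
#'   `accuracy_overall` and `accuracy_by_group`.
#' @export
lda_classify <- function(fit, means, truth = NULL,
                         method = c("resubstitution", "loo")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "ecosel_lda"))
  X <- as.matrix(as.data.frame(means))
  if (!identical(colnames(X), fit$trait_names)) {
    ecosel_error("ecosel_lda_error",
                 "trait set does not match the fitted model")
  }
  lev <- levels(fit$groups)

  assign_rows <- function(X, M, S) {
    Sinv <- solve(S)
    disc <- X %*% Sinv %*% t(M) -
      matrix(rep(diag(M %*% Sinv %*% t(M)) / 2, each = nrow(X)), nrow(X))
    lev[max.col(disc, ties.method = "first")]
  }

  if (method == "resubstitution") {
    pred <- assign_rows(X, fit$group_means, fit$pooled_cov)
  } else {
    if (is.null(truth)) {
      ecosel_error("ecosel_lda_error", "leave-one-out needs 'truth' labels")
    }
    pred <- character(nrow(X))
    for (i in seq_len(nrow(X))) {
      sub <- lda_fit(X[-i, , drop = FALSE], truth[-i])
      pred[i] <- assign_rows(X[i, , drop = FALSE], sub$group_means,
                             sub$pooled_cov)
    }
  }
  out <- list(predicted = factor(pred, levels = lev))
  if (!is.null(truth)) {
    truth <- factor(as.character(truth), levels = lev)
    out$confusion <- table(truth = truth, predicted = out$predicted)
    out$accuracy_overall <- mean(pred == as.character(truth))
    out$accuracy_by_group <- diag(prop.table(out$confusion, 1))
  }
  out
}

#' @export
print.ecosel_lda <- function(x, ...) {
  cat("Canonical discriminant analysis\n")
  cat(sprintf("  groups: %s\n", paste(levels(x$groups), collapse = ", ")))
  cat(sprintf("  axes: %d; discrimination share: %s\n",
              length(x$eigenvalues),
              paste(sprintf("%.1f%%", 100 * x$pct_discrimination),
                    collapse = ", ")))
  cat(sprintf("  resubstitution accuracy: %.1f%%\n",
              100 * x$accuracy_overall))
  invisible(x)
}
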