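# Nested variance partitioning of life-history traits: genotype within
# population cluster within ecotype, fit by REML, with percentile bootstrap
# confidence intervals from resampling genotypes within clusters.

VC_LEVELS <- c("ecotype", "population", "genotype", "residual")

#' Fit the nested random-effects model for one trait
#'
#' Intercept-only Gaussian mixed model with nested random intercepts for
#' ecotype, population cluster within ecotype, and genotype within cluster,
#' fit by REML. Replicate-level rows (blocks) identify the residual
#' variance. The lowland clusters are collapsed to a single group first
#' (see [collapse_lowland_clusters()]) unless `collapse_lowland = FALSE`.
#'
#' @param table replicate-level trait table.
#' @param trait trait column name.
#' @param collapse_lowland collapse the lowland clusters before fitting.
#' @return List of class `ecosel_vc_fit` with `sigma2` (named 4-vector:
#'   ecotype, population, genotype, residual), `n_used`, `n_dropped`,
#'   `converged` and the underlying `lme4` fit.
#' @export
fit_nested_ranef <- function(table, trait, collapse_lowland = TRUE) {
  if (!trait %in% names(table)) {
    ecosel_error("ecosel_schema_error",
                 sprintf("trait column '%s' not found", trait))
  }
  if (collapse_lowland) table <- collapse_lowland_clusters(table, quiet = TRUE)
  d <- data.frame(y = table[[trait]],
                  ecotype = factor(table$ecotype),
                  cluster = factor(paste(table$ecotype,
                                         table$population_cluster, sep = ":")),
                  genotype = factor(table$genotype_id))
  keep <- complete.cases(d)
  d <- d[keep, ]
  if (nlevels(droplevels(d$ecotype)) < 2) {
    ecosel_error("ecosel_varcomp_error",
                 "a single ecotype level: ecotype variance is unidentifiable")
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ 1 + (1 | ecotype) + (1 | cluster) + (1 | genotype),
      data = d, REML = TRUE,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  check.conv.singular = "ignore",
                                  calc.derivs = FALSE,
                                  optCtrl = list(rhobeg = 0.2,
                                                 rhoend = 1e-12,
                                                 maxfun = 1e5)))),
    error = function(e) {
      ecosel_error("ecosel_varcomp_error",
                   sprintf("REML fit failed: %s", conditionMessage(e)))
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_v <- function(g) vc$vcov[match(g, vc$grp)]
  sigma2 <- c(ecotype = get_v("ecotype"), population = get_v("cluster"),
              genotype = get_v("genotype"), residual = get_v("Residual"))
  structure(list(sigma2 = sigma2, trait = trait, n_used = nrow(d),
                 n_dropped = sum(!keep),
                 converged = length(fit@optinfo$conv$lme4$messages %||%
                                      character(0)) == 0,
                 fit = fit),
            class = "ecosel_vc_fit")
}

#' Variance proportions from fitted components
#'
#' Each variance divided by the summed total (including the residual), so
#' the four proportions sum to one.
#'
#' @param fit an `ecosel_vc_fit` or a named/unnamed numeric 4-vector of
#'   variances (ecotype, population, genotype, residual).
#' @return List of class `ecosel_varcomp` with `sigma2` and `proportions`.
#' @export
variance_proportions <- function(fit) {
  sigma2 <- if (inherits(fit, "ecosel_vc_fit")) fit$sigma2 else {
    v <- as.numeric(fit)
    if (length(v) != 4) {
      ecosel_error("ecosel_varcomp_error", "need exactly 4 variances")
    }
    setNames(v, VC_LEVELS)
  }
  if (any(sigma2 < 0)) {
    ecosel_error("ecosel_varcomp_error", "variances must be >= 0")
  }
  total <- sum(sigma2)
  if (total == 0) {
    ecosel_error("ecosel_varcomp_error",
                 "all variances are zero; proportions undefined")
  }
  structure(list(sigma2 = sigma2, proportions = sigma2 / total,
                 trait = if (inherits(fit, "ecosel_vc_fit")) fit$trait else NA),
            class = "ecosel_varcomp")
}

#' Bootstrap confidence intervals for variance proportions
#'
#' Nonparametric case bootstrap: genotypes are resampled with replacement
#' within their population cluster (clusters and ecotypes fixed), all
#' replicate rows of a drawn genotype are carried along under a fresh
#' genotype label, and the nested model is refit on each replicate.
#' Percentile 2.5/97.5 bounds are taken over the converged replicates;
#' failed replicates are dropped and counted.
#'
#' @param table replicate-level trait table.
#' @param trait trait column name.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @param resample `"genotype"` (default) or `"row"`.
#' @param strict error (instead of warn) when more than 20% of replicates
#'   fail.
#' @param collapse_lowland collapse the lowland clusters before fitting.
#' @return List of class `ecosel_varcomp_ci`: `point` (the full-data
#'   [variance_proportions()]), `ci` (2 x 4 matrix), `n_boot`, `n_failed`,
#'   `replicates` (proportion draws).
#' @export
bootstrap_proportions <- function(table, trait, n_boot = 1000, seed = 1L,
                                  level = 0.95,
                                  resample = c("genotype", "row"),
                                  strict = FALSE, collapse_lowland = TRUE) {
  resample <- match.arg(resample)
  if (collapse_lowland) {
    table <- collapse_lowland_clusters(table, quiet = TRUE)
  }
  point <- variance_proportions(
    fit_nested_ranef(table, trait, collapse_lowland = FALSE))
  set.seed(stage_seed(seed, paste0("boot_", trait)))
  by_cluster <- split(seq_len(nrow(table)), table$population_cluster)
  geno_rows <- lapply(by_cluster, function(idx) {
    split(idx, table$genotype_id[idx])
  })

  reps <- matrix(NA_real_, n_boot, 4, dimnames = list(NULL, VC_LEVELS))
  for (b in seq_len(n_boot)) {
    if (resample == "genotype") {
      pieces <- lapply(geno_rows, function(gl) {
        picked <- sample(length(gl), replace = TRUE)
        do.call(rbind, lapply(seq_along(picked), function(j) {
          rows <- table[gl[[picked[j]]], ]
          rows$genotype_id <- paste0(rows$genotype_id[1], "_b", j)
          rows
        }))
      })
      tb <- do.call(rbind, pieces)
    } else {
      tb <- table[sample(nrow(table), replace = TRUE), ]
    }
    prop <- tryCatch(
      variance_proportions(
        fit_nested_ranef(tb, trait, collapse_lowland = FALSE))$proportions,
      error = function(e) NULL)
    if (!is.null(prop)) reps[b, ] <- prop
  }
  ok <- complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot) {
    msg <- sprintf("%d of %d bootstrap replicates failed to converge",
                   n_failed, n_boot)
    if (strict) ecosel_error("ecosel_varcomp_error", msg) else warning(msg)
  }
  alpha <- (1 - level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2, quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(point = point, ci = ci, level = level, n_boot = n_boot,
                 n_failed = n_failed, replicates = reps[ok, , drop = FALSE]),
            class = "ecosel_varcomp_ci")
}

#' Variance partition across all traits of a panel
#'
#' Convenience wrapper running [fit_nested_ranef()] (and optionally
#' [bootstrap_proportions()]) for each trait column.
#'
#' @param table replicate-level trait table.
#' @param traits trait columns (default: all eight panel traits present).
#' @param n_boot bootstrap replicates; 0 skips the intervals.
#' @param seed RNG seed.
#' @return Data frame with one row per trait x level: variance, proportion
#'   and (if bootstrapped) CI bounds.
#' @export
varcomp_table <- function(table, traits = intersect(TRAIT_COLS, names(table)),
                          n_boot = 0, seed = 1L) {
  out <- lapply(traits, function(tr) {
    if (n_boot > 0) {
      bb <- bootstrap_proportions(table, tr, n_boot = n_boot, seed = seed)
      data.frame(trait = tr, level = VC_LEVELS,
                 sigma2 = as.numeric(bb$point$sigma2),
                 proportion = as.numeric(bb$point$proportions),
                 ci_lower = bb$ci["lower", ], ci_upper = bb$ci["upper", ],
                 row.names = NULL)
    } else {
      vp <- variance_proportions(fit_nested_ranef(table, tr))
      data.frame(trait = tr, level = VC_LEVELS,
                 sigma2 = as.numeric(vp$sigma2),
                 proportion = as.numeric(vp$proportions), row.names = NULL)
    }
  })
  do.call(rbind, out)
}

#' @export
print.ecosel_varcomp <- function(x, ...) {
  cat(sprintf("Variance partition%s\n",
              if (!is.na(x$trait)) paste0(" for ", x$trait) else ""))
  print(round(rbind(variance = x$sigma2, proportion = x$proportions), 4))
  invisible(x)
}
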