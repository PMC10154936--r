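# Standardized major axis (SMA) allometry: per-ecotype line fits with
# confidence intervals and correlation tests, and the likelihood-ratio test
# of a common slope among groups.

#' Fit a standardized major axis line
#'
#' The SMA slope is `sign(r) * s_y / s_x` with intercept through the
#' bivariate mean; the test of association is the t-test of `H0: r = 0` on
#' `n - 2` df, and the slope CI uses `B = F(0.95; 1, n-2) (1 - r^2)/(n - 2)`
#' with bounds `b (sqrt(B + 1) +/- sqrt(B))`.
#'
#' @param x,y numeric vectors (`n >= 3`, both varying). Incomplete pairs are
#'   dropped.
#' @param group optional label carried into the result.
#' @param level confidence level for the slope interval.
#' @return List of class `ecosel_sma`: `slope`, `intercept`, `r`, `p_corr`,
#'   `slope_ci`, `n`, `group`.
#' @export
sma_fit <- function(x, y, group = NA_character_, level = 0.95) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) {
    ecosel_error("ecosel_sma_error", "need at least 3 complete pairs")
  }
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) {
    ecosel_error("ecosel_sma_error", "zero variance in x or y")
  }
  r <- cor(x, y)
  sgn <- sign(r)
  if (sgn == 0) {
    warning("correlation is exactly zero; slope sign taken positive")
    sgn <- 1
  }
  b <- sgn * sy / sx
  a <- mean(y) - b * mean(x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p_corr <- 2 * pt(-abs(tstat), n - 2)
  B <- qf(level, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(b * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B)))
  structure(list(slope = b, intercept = a, r = r, p_corr = p_corr,
                 slope_ci = ci, n = n, level = level, group = group,
                 x_mean = mean(x), y_mean = mean(y)),
            class = "ecosel_sma")
}

# squared residual/axis-score correlation at candidate slope beta
r2_uv <- function(beta, sxx, syy, sxy) {
  num <- syy - beta^2 * sxx
  den <- (syy + beta^2 * sxx)^2 - 4 * beta^2 * sxy^2
  if (den <= 0) return(1)
  min(num^2 / den, 1)
}

cs_objective <- function(beta, stats) {
  sum(vapply(stats, function(s) {
    -(s$n - 2) * log(max(1 - r2_uv(beta, s$sxx, s$syy, s$sxy),
                         .Machine$double.eps))
  }, numeric(1)))
}

#' Likelihood-ratio test of a common SMA slope
#'
#' For a candidate slope `beta`, residual and axis scores `u = y - beta x`,
#' `v = y + beta x` are uncorrelated within a group exactly when `beta` is
#' that group's SMA slope. The statistic profiles
#' `-sum_i (n_i - 2) log(1 - r_uv,i(beta)^2)` over `beta`; its minimum is
#' the LR statistic (each group's own-slope term is zero) and the minimizer
#' is the common-slope estimate. Reference distribution: chi-squared with
#' `groups - 1` df.
#'
#' Note that `r_uv^2` depends on `beta` only through `beta^2`, so the profile
#' objective is even in the sign of the slope: groups whose SMA slopes differ
#' only in sign (equal magnitude) are not distinguished by this statistic,
#' and the reported `common_slope` takes the sign of the (df-weighted)
#' majority of the per-group slopes. Sign heterogeneity among groups
#' surfaces in the per-group correlation tests of [sma_fit()] instead.
#'
#' @param groups list of `list(x =, y =)` samples (each `n >= 3`), or a list
#'   of two-column matrices/data frames.
#' @return List of class `ecosel_cs_test`: `lr_stat`, `df`, `p`,
#'   `common_slope`, `group_slopes`.
#' @export
common_slope_test <- function(groups) {
  if (length(groups) < 2) {
    ecosel_error("ecosel_sma_error", "need at least 2 groups (df >= 1)")
  }
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  stats <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (!is.list(g) || is.data.frame(g)) g <- list(x = g[[1]], y = g[[2]])
    ok <- complete.cases(g$x, g$y)
    x <- as.numeric(g$x[ok]); y <- as.numeric(g$y[ok])
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      ecosel_error("ecosel_sma_error",
                   sprintf("degenerate group '%s'", nm[i]))
    }
    list(n = length(x), sxx = var(x), syy = var(y), sxy = cov(x, y),
         b = sign(cor(x, y) + (cor(x, y) == 0)) * sd(y) / sd(x))
  })
  slopes <- vapply(stats, `[[`, numeric(1), "b")
  # profile minimization: coarse sign-aware scan, then local refinement
  mags <- abs(slopes)
  lo <- min(mags) / 10; hi <- max(mags) * 10
  grid <- c(-exp(seq(log(lo), log(hi), length.out = 200)),
            exp(seq(log(lo), log(hi), length.out = 200)))
  vals <- vapply(grid, cs_objective, numeric(1), stats = stats)
  best <- grid[which.min(vals)]
  span <- sort(best * c(0.5, 2))
  opt <- optimise(cs_objective, interval = span, stats = stats,
                  tol = .Machine$double.eps^0.5)
  lr <- max(opt$objective, 0)
  df <- length(stats) - 1
  # the objective is even in beta; report the consensus sign of the groups
  wsign <- sign(sum(vapply(stats, function(s) (s$n - 2) * sign(s$b),
                           numeric(1))))
  cslope <- if (wsign == 0) opt$minimum else wsign * abs(opt$minimum)
  structure(list(lr_stat = lr, df = df, p = pchisq(lr, df, lower.tail = FALSE),
                 common_slope = cslope,
                 group_slopes = setNames(slopes, nm)),
            class = "ecosel_cs_test")
}

#' Ecotype-specific SMA of one trait against seed mass
#'
#' Computes genotype means, fits one SMA line per ecotype (groups with fewer
#' than 3 genotypes are skipped with a warning, reducing the test df) and
#' runs the among-ecotype common-slope test. Pairwise slope comparisons use
#' the same LR statistic on group pairs with Bonferroni correction.
#'
#' @param traits trait table (replicate- or genotype-level).
#' @param y trait column regressed against seed mass.
#' @param x x-variable column (default `"seed_mass"`).
#' @param log_scale analyze both variables on the natural-log scale.
#' @param pairwise also run pairwise common-slope comparisons.
#' @return List of class `ecosel_sma_set`: `fits` (per-ecotype
#'   `ecosel_sma`), `test` (`ecosel_cs_test` or `NULL` if fewer than two
#'   usable groups), `pairwise`, `summary` (one row per ecotype).
#' @export
sma_by_ecotype <- function(traits, y, x = "seed_mass", log_scale = FALSE,
                           pairwise = FALSE) {
  gm <- if ("block" %in% names(traits)) genotype_means(traits) else traits
  if (!y %in% names(gm) || !x %in% names(gm)) {
    ecosel_error("ecosel_schema_error",
                 sprintf("column '%s' or '%s' not found", x, y))
  }
  tf <- if (log_scale) log else identity
  groups <- split(gm, gm$ecotype)
  fits <- list(); samples <- list()
  for (eco in names(groups)) {
    g <- groups[[eco]]
    ok <- complete.cases(g[[x]], g[[y]])
    if (sum(ok) < 3) {
      warning(sprintf("ecotype '%s' has fewer than 3 genotypes; skipped", eco))
      next
    }
    xi <- tf(g[[x]][ok]); yi <- tf(g[[y]][ok])
    fits[[eco]] <- sma_fit(xi, yi, group = eco)
    samples[[eco]] <- list(x = xi, y = yi)
  }
  test <- if (length(samples) >= 2) common_slope_test(samples) else NULL
  pw <- NULL
  if (pairwise && length(samples) >= 2) {
    prs <- combn(names(samples), 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(prs, function(pr) {
      tt <- common_slope_test(samples[pr])
      data.frame(group1 = pr[1], group2 = pr[2], lr_stat = tt$lr_stat,
                 p = min(1, tt$p * length(prs)), stringsAsFactors = FALSE)
    }))
  }
  summary <- do.call(rbind, lapply(fits, function(f) {
    data.frame(ecotype = f$group, n = f$n, slope = f$slope,
               intercept = f$intercept, r = f$r, p_corr = f$p_corr,
               ci_lower = f$slope_ci[1], ci_upper = f$slope_ci[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(fits = fits, test = test, pairwise = pw, summary = summary,
                 trait_pair = c(x = x, y = y), log_scale = log_scale),
            class = "ecosel_sma_set")
}

#' @export
print.ecosel_sma <- function(x, ...) {
  cat(sprintf("SMA fit%s: slope %.4g [%.4g, %.4g], r = %.3f (p = %.3g), n = %d\n",
              if (!is.na(x$group)) paste0(" (", x$group, ")") else "",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$r, x$p_corr, x$n))
  invisible(x)
}

#' @export
print.ecosel_cs_test <- function(x, ...) {
  cat(sprintf("Common-slope LR test: stat %.4g on %d df (p = %.3g); common slope %.4g\n",
              x$lr_stat, x$df, x$p, x$common_slope))
  invisible(x)
}
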