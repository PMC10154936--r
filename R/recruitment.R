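# Poisson GLMs of seedling and adult recruitment with ecotype x site
# interaction: likelihood-ratio term tests, Pearson goodness of fit and
# within-ecotype site contrasts with percent differences.

#' Fit the recruitment Poisson GLM
#'
#' Log-link Poisson GLM of a recruitment count on ecotype, site and their
#' interaction, on the non-control plots. Treatment coding uses the
#' configured reference levels (xeric site, lowland ecotype by default).
#' Zero-count ecotype x site cells (an infinite MLE direction) are flagged
#' with a warning.
#'
#' @param plots a validated plot table.
#' @param response `"seedling"` or `"adult"`.
#' @param site_ref,ecotype_ref reference levels.
#' @param formula model formula on `count`; default
#'   `count ~ ecotype * site`.
#' @param offset_seeds add `log(seeds_added)` as an offset (for designs with
#'   unequal sowing; the default design adds 100 seeds everywhere).
#' @return List of class `ecosel_glm` wrapping the `stats::glm` fit, with
#'   `coefficients`, `cov`, `deviance`, `pearson_x2`, `df_resid`, `fitted`
#'   and the modelling `data`.
#' @export
fit_poisson_glm <- function(plots, response = c("seedling", "adult"),
                            site_ref = "xeric", ecotype_ref = "lowland",
                            formula = count ~ ecotype * site,
                            offset_seeds = FALSE) {
  response <- match.arg(response)
  d <- plots[!plots$is_control, , drop = FALSE]
  d$count <- d[[paste0(response, "_count")]]
  d <- d[complete.cases(d[, c("count", "ecotype", "site")]), ]
  if (length(unique(d$site)) < 2 || length(unique(d$ecotype)) < 2) {
    ecosel_error("ecosel_glm_error",
                 "need both sites and at least two ecotypes")
  }
  d$site <- stats::relevel(factor(d$site), ref = site_ref)
  d$ecotype <- stats::relevel(factor(d$ecotype), ref = ecotype_ref)
  cell_tot <- tapply(d$count, list(d$ecotype, d$site), sum)
  if (any(cell_tot == 0, na.rm = TRUE)) {
    warning(paste("ecotype x site cell(s) with zero total count: the MLE",
                  "diverges there; estimates are finite-precision artefacts"))
  }
  fit <- if (offset_seeds) {
    glm(stats::update(formula, . ~ . + offset(log(seeds_added))),
        family = poisson(), data = d,
        control = list(epsilon = 1e-10, maxit = 100))
  } else {
    glm(formula, family = poisson(), data = d,
        control = list(epsilon = 1e-10, maxit = 100))
  }
  structure(list(fit = fit, response = response,
                 coefficients = coef(fit), cov = as.matrix(vcov(fit)),
                 deviance = deviance(fit),
                 pearson_x2 = sum((d$count - fit$fitted.values)^2 /
                                    fit$fitted.values),
                 df_resid = fit$df.residual,
                 fitted = fit$fitted.values, data = d,
                 site_ref = site_ref, ecotype_ref = ecotype_ref),
            class = "ecosel_glm")
}

#' Likelihood-ratio term tests
#'
#' Chi-squared tests per model term: the interaction is tested by dropping
#' it from the full model; each main effect is tested by dropping it from
#' the main-effects (no-interaction) model. Degrees of freedom equal the
#' coefficients lost.
#'
#' @param fit an [fit_poisson_glm()] result.
#' @return Data frame with `term`, `df`, `chisq`, `p`.
#' @export
term_tests <- function(fit) {
  stopifnot(inherits(fit, "ecosel_glm"))
  d <- fit$data
  ctl <- list(epsilon = 1e-10, maxit = 100)
  dev <- function(f) {
    m <- glm(f, family = poisson(), data = d, control = ctl)
    c(deviance(m), m$df.residual)
  }
  full <- dev(count ~ ecotype * site)
  main <- dev(count ~ ecotype + site)
  no_eco <- dev(count ~ site)
  no_site <- dev(count ~ ecotype)
  row <- function(term, reduced, base) {
    data.frame(term = term, df = reduced[2] - base[2],
               chisq = reduced[1] - base[1],
               p = pchisq(reduced[1] - base[1], reduced[2] - base[2],
                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  rbind(row("ecotype", no_eco, main),
        row("site", no_site, main),
        row("site x ecotype", main, full))
}

#' Pearson goodness of fit
#'
#' `X^2 = sum (obs - fitted)^2 / fitted` with `df = n - p`; the dispersion
#' ratio `X^2/df` near 1 indicates the Poisson variance assumption is
#' adequate.
#'
#' @param fit an [fit_poisson_glm()] result.
#' @return List with `x2`, `df`, `dispersion`.
#' @export
pearson_gof <- function(fit) {
  stopifnot(inherits(fit, "ecosel_glm"))
  list(x2 = fit$pearson_x2, df = fit$df_resid,
       dispersion = fit$pearson_x2 / fit$df_resid)
}

#' Within-ecotype site contrasts on the count scale
#'
#' Per ecotype: fitted mean counts per site (`exp` of the linear
#' predictor), delta-method standard errors, the percent difference
#' `(favoured - other)/other * 100` with its direction, and the Wald test
#' of the within-ecotype site difference on the log scale.
#'
#' @param fit an [fit_poisson_glm()] result from the interaction model.
#' @return Data frame with one row per ecotype: `mean_xeric`, `mean_mesic`,
#'   `se_xeric`, `se_mesic`, `pct_difference`, `favoured_site`, `p`.
#' @export
site_contrasts <- function(fit) {
  stopifnot(inherits(fit, "ecosel_glm"))
  d <- fit$data
  beta <- fit$coefficients
  V <- fit$cov
  out <- lapply(levels(d$ecotype), function(eco) {
    cell <- function(site) {
      nd <- data.frame(ecotype = factor(eco, levels(d$ecotype)),
                       site = factor(site, levels(d$site)))
      x <- model.matrix(stats::delete.response(stats::terms(fit$fit)), nd)
      eta <- as.numeric(x %*% beta)
      se_eta <- sqrt(as.numeric(x %*% V %*% t(x)))
      list(x = x, mean = exp(eta), se = exp(eta) * se_eta, eta = eta,
           se_eta = se_eta)
    }
    cx <- cell("xeric"); cm <- cell("mesic")
    dvec <- cm$x - cx$x
    diff_eta <- as.numeric(dvec %*% beta)
    se_diff <- sqrt(as.numeric(dvec %*% V %*% t(dvec)))
    pval <- 2 * pnorm(-abs(diff_eta / se_diff))
    favoured <- if (cm$mean >= cx$mean) "mesic" else "xeric"
    hi <- max(cm$mean, cx$mean); lo <- min(cm$mean, cx$mean)
    pct <- if (lo > 0) (hi - lo) / lo * 100 else Inf
    if (!is.finite(pct)) {
      warning(sprintf("zero cell mean for ecotype '%s'; contrast unbounded",
                      eco))
    }
    data.frame(ecotype = eco, mean_xeric = cx$mean, mean_mesic = cm$mean,
               se_xeric = cx$se, se_mesic = cm$se,
               pct_difference = pct, favoured_site = favoured, p = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize the seed-bank background from control plots
#'
#' @param plots a validated plot table.
#' @return Data frame per site with the number of control plots and mean
#'   seedling/adult counts (natural recruitment with no seed added).
#' @export
control_summary <- function(plots) {
  d <- plots[plots$is_control, , drop = FALSE]
  out <- aggregate(cbind(seedling_count, adult_count) ~ site, data = d,
                   FUN = mean)
  out$n_plots <- as.numeric(table(d$site)[out$site])
  out
}

#' @export
print.ecosel_glm <- function(x, ...) {
  gof <- pearson_gof(x)
  cat(sprintf("Poisson GLM of %s recruitment (n = %d plots)\n",
              x$response, nrow(x$data)))
  cat(sprintf("  deviance %.2f; Pearson X2 %.2f on %d df (dispersion %.2f)\n",
              x$deviance, gof$x2, gof$df, gof$dispersion))
  invisible(x)
}
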