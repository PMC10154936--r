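# Climate-of-origin effects on seed mass: all-subsets selection over seven
# standardized predictors with AICc, full (zero-substituted) model averaging
# over the small-delta candidate set, and the marginal R^2 of the global
# mixed model.

#' Assemble the genotype-level seed-mass modelling frame
#'
#' Joins genotype-mean seed mass to the climate table and z-standardizes the
#' seven predictors so coefficients read as mg per predictor SD.
#'
#' @param traits replicate- or genotype-level trait table.
#' @param climate climate table (one row per genotype).
#' @param response response column (default `"seed_mass"`).
#' @return Data frame with the standardized predictors, the response, labels
#'   and an attribute `"scaling"` holding each predictor's center/scale.
#' @export
climate_frame <- function(traits, climate, response = "seed_mass") {
  gm <- if (!"block" %in% names(traits)) traits else genotype_means(traits)
  d <- merge(gm[, c("genotype_id", "ecotype", "population_cluster", response)],
             climate, by = "genotype_id")
  d <- d[complete.cases(d[, c(response, CLIMATE_PREDICTORS)]), ]
  scaling <- list()
  for (p in CLIMATE_PREDICTORS) {
    z <- zscore(d[[p]])
    d[[p]] <- z$values
    scaling[[p]] <- c(center = z$center, scale = z$scale)
  }
  attr(d, "scaling") <- scaling
  attr(d, "response") <- response
  d
}

lmm_formula <- function(response, predictors) {
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  as.formula(paste(response, "~", rhs,
                   "+ (1 | ecotype) + (1 | ecotype:population_cluster)"))
}

fit_candidate <- function(frame, predictors, response) {
  if (qr(cbind(1, as.matrix(frame[, predictors, drop = FALSE])))$rank <
      length(predictors) + 1) {
    ecosel_error("ecosel_climate_error",
                 sprintf("rank-deficient predictor matrix (aliased among: %s)",
                         paste(predictors, collapse = ", ")))
  }
  suppressMessages(lme4::lmer(
    lmm_formula(response, predictors), data = frame, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
}

#' Fit the global climate model
#'
#' Gaussian mixed model of genotype seed mass on all seven standardized
#' climate/geography predictors with random intercepts for ecotype and
#' population cluster within ecotype, fit by maximum likelihood (ML rather
#' than REML so that AICc is comparable across fixed-effect subsets).
#'
#' @param traits,climate,response as in [climate_frame()]; `traits` may also
#'   be a ready-made [climate_frame()].
#' @return List of class `ecosel_global_lmm` with the `lme4` `fit`, the
#'   modelling `frame`, `coefficients` (fixed effects), `n` (genotypes).
#' @export
fit_global_lmm <- function(traits, climate = NULL, response = "seed_mass") {
  frame <- if (is.null(climate)) traits
           else climate_frame(traits, climate, response)
  fit <- fit_candidate(frame, CLIMATE_PREDICTORS,
                       attr(frame, "response") %||% response)
  structure(list(fit = fit, frame = frame,
                 coefficients = lme4::fixef(fit), n = nrow(frame)),
            class = "ecosel_global_lmm")
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    ecosel_error("ecosel_climate_error",
                 sprintf("AICc undefined: n (%d) must exceed k + 1 (%d)",
                         n, k + 1))
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike deltas and weights
#'
#' @param aicc_values numeric vector of AICc values.
#' @return List with `delta` (AICc minus the minimum) and `weight`
#'   (normalized relative likelihoods `exp(-delta/2)`).
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values)) {
    ecosel_error("ecosel_climate_error", "need at least one model")
  }
  delta <- aicc_values - min(aicc_values)
  rel <- exp(-delta / 2)
  list(delta = delta, weight = rel / sum(rel))
}

#' All additive predictor subsets ranked by AICc
#'
#' Fits every additive combination of the seven predictors (2^7 = 128
#' models, intercept-only included) with the identical ML routine and row
#' set, and ranks them by AICc. The AICc sample size is the number of
#' genotypes; the parameter count is intercept + predictors + the two
#' random-intercept variances + the residual variance.
#'
#' @param global an [fit_global_lmm()] result (fixes the complete-case rows).
#' @param predictors predictor pool (default the seven climate predictors).
#' @return Data frame of class `ecosel_candidates`, one row per model with
#'   `predictor_set`, coefficient and SE columns, `loglik`, `k`, `aicc`,
#'   `delta`, `weight`; fitted models in `attr(, "fits")`.
#' @export
all_subsets <- function(global, predictors = CLIMATE_PREDICTORS) {
  stopifnot(inherits(global, "ecosel_global_lmm"))
  frame <- global$frame
  response <- attr(frame, "response") %||% "seed_mass"
  n <- nrow(frame)
  p <- length(predictors)
  subsets <- lapply(0:p, function(m) {
    if (m == 0) list(character(0)) else
      asplit(combn(predictors, m), 2)
  })
  subsets <- unlist(subsets, recursive = FALSE)

  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    ps <- as.character(subsets[[i]])
    fit <- fit_candidate(frame, ps, response)
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    k <- 1 + length(ps) + 2 + 1
    ll <- as.numeric(logLik(fit))
    coefs <- setNames(rep(NA_real_, p), predictors)
    ses <- setNames(rep(NA_real_, p), predictors)
    coefs[ps] <- fe[ps]
    ses[ps] <- se[ps]
    rows[[i]] <- data.frame(
      model_id = i,
      predictor_set = paste(ps, collapse = "+"),
      t(coefs), t(setNames(ses, paste0("se_", predictors))),
      loglik = ll, k = k, aicc = aicc(ll, k, n),
      stringsAsFactors = FALSE)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  aw <- akaike_weights(out$aicc)
  out$delta <- aw$delta
  out$weight <- aw$weight
  ord <- order(out$aicc)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  attr(out, "n") <- n
  attr(out, "predictors") <- predictors
  class(out) <- c("ecosel_candidates", "data.frame")
  out
}

#' Full (zero-substituted) model averaging
#'
#' Retains candidates with `delta < delta_max`, renormalizes their weights,
#' and averages each predictor's coefficient with zeros substituted in
#' models where it is absent. Unconditional standard errors follow the
#' classic formula `sum_i w_i * sqrt(se_i^2 + (b_i - b_bar)^2)`; z-ratios
#' and two-sided normal p-values are reported, along with each predictor's
#' relative importance (summed weight of retaining models).
#'
#' @param candidates an [all_subsets()] table.
#' @param delta_max retention threshold on the AICc delta (default 7).
#' @param conditional also report conditional (presence-only) averages.
#' @return Data frame of class `ecosel_averaged`, one row per predictor:
#'   `averaged_coef`, `unconditional_se`, `z`, `p`, `importance`; the number
#'   of retained models in `attr(, "n_models")`.
#' @export
model_average <- function(candidates, delta_max = 7, conditional = FALSE) {
  stopifnot(inherits(candidates, "ecosel_candidates"))
  keep <- candidates$delta < delta_max
  if (!any(keep)) {
    ecosel_error("ecosel_climate_error", "no candidate models retained")
  }
  cand <- candidates[keep, ]
  w <- cand$weight / sum(cand$weight)
  predictors <- attr(candidates, "predictors")

  out <- lapply(predictors, function(p) {
    b <- cand[[p]]
    se <- cand[[paste0("se_", p)]]
    present <- !is.na(b)
    b0 <- ifelse(present, b, 0)
    se0 <- ifelse(present, se, 0)
    bbar <- sum(w * b0)
    use <- sum(w * sqrt(se0^2 + (b0 - bbar)^2))
    z <- if (use > 0) bbar / use else NA_real_
    row <- data.frame(predictor = p, averaged_coef = bbar,
                      unconditional_se = use, z = z,
                      p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
                      importance = sum(w[present]),
                      stringsAsFactors = FALSE)
    if (conditional) {
      wc <- w[present] / sum(w[present])
      bc <- sum(wc * b[present])
      row$conditional_coef <- bc
      row$conditional_se <- sum(wc * sqrt(se[present]^2 + (b[present] - bc)^2))
    }
    row
  })
  out <- do.call(rbind, out)
  attr(out, "n_models") <- sum(keep)
  attr(out, "delta_max") <- delta_max
  attr(out, "averaging") <- if (conditional) "full+conditional" else "full"
  class(out) <- c("ecosel_averaged", "data.frame")
  out
}

#' Marginal R-squared of a mixed model
#'
#' Fixed-effect variance share: the variance of the fixed-effect linear
#' predictor divided by itself plus the summed random-intercept variances
#' and the residual variance.
#'
#' @param global an [fit_global_lmm()] result or an `lme4` fit.
#' @return Value in `[0, 1]`.
#' @export
marginal_r2 <- function(global) {
  fit <- if (inherits(global, "ecosel_global_lmm")) global$fit else global
  X <- model.matrix(fit)
  var_f <- var(as.numeric(X %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f / (var_f + var_r + var_e)
}
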