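# Joint hierarchical Bayesian model of seedling and adult recruitment.
# Both counts are Poisson with a log link. Seedlings: seed mass (SD scale),
# site and their interaction; adults: seedling count, seed mass, site and
# their two-way interactions. Each response has a genotype intercept, and
# the two plot effects are correlated bivariate-normal to absorb the
# dependence of adults on seedlings within a plot. Priors are weakly
# informative: N(0, sd 25) slopes, N(0, sd 10) intercepts, half-Student-t(3,
# 0, 10) random-effect sds, uniform(-1, 1) plot-effect correlation.

SEL_FIXED <- c("alpha_s", "beta_mass", "beta_site", "beta_int",
               "alpha_a", "gamma_seedling", "gamma_mass", "gamma_site",
               "gamma_mass_site", "gamma_seedling_site")
SEL_HYPER <- c("sd_u_seedling", "sd_u_adult", "rho",
               "sd_v_seedling", "sd_v_adult")

#' Specify the selection model
#'
#' @param prior_sd_slope prior SD of slope coefficients (default 25).
#' @param prior_sd_intercept prior SD of intercepts (default 10).
#' @param prior_t_df,prior_t_scale half-Student-t prior on random-effect sds.
#' @param three_way add the seedling x seed mass x site three-way term to
#'   the adult submodel (default `FALSE`: two-way interactions only).
#' @param scale_seedling divide the seedling covariate of the adult submodel
#'   by its sample SD (default `TRUE`).
#' @param chains,iter MCMC defaults: 3 chains of 4000 iterations each, the
#'   first half of each chain discarded as warm-up.
#' @return List of class `ecosel_selection_spec`.
#' @export
selection_model_spec <- function(prior_sd_slope = 25, prior_sd_intercept = 10,
                                 prior_t_df = 3, prior_t_scale = 10,
                                 three_way = FALSE, scale_seedling = TRUE,
                                 chains = 3L, iter = 4000L) {
  if (any(c(prior_sd_slope, prior_sd_intercept, prior_t_scale) <= 0)) {
    ecosel_error("ecosel_config_error", "prior sds must be > 0")
  }
  structure(list(prior_sd_slope = prior_sd_slope,
                 prior_sd_intercept = prior_sd_intercept,
                 prior_t_df = prior_t_df, prior_t_scale = prior_t_scale,
                 three_way = three_way, scale_seedling = scale_seedling,
                 chains = as.integer(chains), iter = as.integer(iter)),
            class = "ecosel_selection_spec")
}

#' Assemble model data from a plot table and genotype seed masses
#'
#' Drops control plots, z-standardizes seed mass across the experimental
#' genotypes, codes site as a mesic indicator (xeric is the reference) and
#' scales the seedling covariate of the adult submodel by its sample SD.
#'
#' @param plots a validated plot table.
#' @param seed_mass named numeric vector (names = genotype ids) or data
#'   frame with `genotype_id` and `seed_mass` (mg, genotype level).
#' @param spec an [selection_model_spec()].
#' @return List of class `ecosel_selection_data`.
#' @export
selection_data <- function(plots, seed_mass, spec = selection_model_spec()) {
  if (is.data.frame(seed_mass)) {
    seed_mass <- setNames(seed_mass$seed_mass, seed_mass$genotype_id)
  }
  d <- plots[!plots$is_control, , drop = FALSE]
  miss <- setdiff(unique(d$genotype_id), names(seed_mass))
  if (length(miss)) {
    ecosel_error("ecosel_config_error",
                 sprintf("seed_mass missing for genotype(s): %s",
                         paste(miss, collapse = ", ")))
  }
  geno <- factor(d$genotype_id)
  zs <- zscore(seed_mass[levels(geno)])
  s_sd <- if (spec$scale_seedling) sd(d$seedling_count) else 1
  if (!is.finite(s_sd) || s_sd == 0) s_sd <- 1
  structure(list(
    y_s = d$seedling_count,
    y_a = d$adult_count,
    z = as.numeric(zs$values[as.integer(geno)]),
    mesic = as.numeric(d$site == "mesic"),
    g = as.integer(geno),
    geno_levels = levels(geno),
    s_cov = d$seedling_count / s_sd,
    s_sd = s_sd,
    n = nrow(d),
    n_geno = nlevels(geno),
    z_center = zs$center, z_scale = zs$scale
  ), class = "ecosel_selection_data")
}

sel_linpreds <- function(spec, params, data) {
  with(params, {
    eta_s <- alpha_s + beta_mass * data$z + beta_site * data$mesic +
      beta_int * data$z * data$mesic + u[, 1] + v_s[data$g]
    eta_a <- alpha_a + gamma_seedling * data$s_cov + gamma_mass * data$z +
      gamma_site * data$mesic + gamma_mass_site * data$z * data$mesic +
      gamma_seedling_site * data$s_cov * data$mesic + u[, 2] + v_a[data$g]
    if (isTRUE(spec$three_way)) {
      eta_a <- eta_a + params$gamma_three * data$s_cov * data$z * data$mesic
    }
    list(eta_s = eta_s, eta_a = eta_a)
  })
}

half_t_logpdf <- function(x, df, scale) {
  if (x < 0) return(-Inf)
  log(2) + dt(x / scale, df, log = TRUE) - log(scale)
}

#' Joint log posterior density of the selection model
#'
#' Sum of the Poisson log-likelihoods of both responses, the bivariate
#' normal log density of the plot-effect pairs, the normal log densities of
#' the genotype effects, and the prior log densities. Exposed so the model
#' can be checked against independent implementations and optimized
#' directly.
#'
#' @param spec an [selection_model_spec()].
#' @param params named list: fixed effects (`alpha_s`, `beta_mass`,
#'   `beta_site`, `beta_int`, `alpha_a`, `gamma_seedling`, `gamma_mass`,
#'   `gamma_site`, `gamma_mass_site`, `gamma_seedling_site`, plus
#'   `gamma_three` when the spec includes it), `u` (n x 2 plot effects),
#'   `v_s`, `v_a` (genotype effects), `sd_u` (length 2), `rho`, `sd_v`
#'   (length 2).
#' @param data an [selection_data()] object.
#' @return Scalar log density (can be `-Inf` on the support boundary).
#' @export
log_posterior <- function(spec, params, data) {
  stopifnot(inherits(data, "ecosel_selection_data"))
  need <- c(SEL_FIXED, if (isTRUE(spec$three_way)) "gamma_three",
            "u", "v_s", "v_a", "sd_u", "rho", "sd_v")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    ecosel_error("ecosel_config_error",
                 sprintf("params missing: %s", paste(miss, collapse = ", ")))
  }
  params$u <- as.matrix(params$u)
  if (nrow(params$u) != data$n || ncol(params$u) != 2 ||
      length(params$v_s) != data$n_geno ||
      length(params$v_a) != data$n_geno) {
    ecosel_error("ecosel_config_error", "parameter dimensions do not match")
  }
  fixed <- unlist(params[c(SEL_FIXED,
                           if (isTRUE(spec$three_way)) "gamma_three")])
  if (!all(is.finite(fixed))) {
    ecosel_error("ecosel_config_error", "non-finite fixed effects")
  }
  if (abs(params$rho) > 1 || any(params$sd_u < 0) || any(params$sd_v < 0)) {
    return(-Inf)
  }

  eta <- sel_linpreds(spec, params, data)
  ll <- sum(dpois(data$y_s, exp(eta$eta_s), log = TRUE)) +
    sum(dpois(data$y_a, exp(eta$eta_a), log = TRUE))

  # bivariate normal of plot-effect pairs
  s1 <- params$sd_u[1]; s2 <- params$sd_u[2]; rho <- params$rho
  if (s1 == 0 || s2 == 0 || abs(rho) == 1) return(-Inf)
  q <- (params$u[, 1] / s1)^2 - 2 * rho * (params$u[, 1] / s1) *
    (params$u[, 2] / s2) + (params$u[, 2] / s2)^2
  lp_u <- sum(-log(2 * pi) - log(s1 * s2) - 0.5 * log(1 - rho^2) -
                q / (2 * (1 - rho^2)))
  lp_v <- sum(dnorm(params$v_s, 0, params$sd_v[1], log = TRUE)) +
    sum(dnorm(params$v_a, 0, params$sd_v[2], log = TRUE))

  slopes <- setdiff(names(fixed), c("alpha_s", "alpha_a"))
  lp_prior <- sum(dnorm(fixed[slopes], 0, spec$prior_sd_slope, log = TRUE)) +
    sum(dnorm(fixed[c("alpha_s", "alpha_a")], 0, spec$prior_sd_intercept,
              log = TRUE)) +
    sum(vapply(c(params$sd_u, params$sd_v), half_t_logpdf, numeric(1),
               df = spec$prior_t_df, scale = spec$prior_t_scale)) -
    log(2)  # uniform(-1, 1) on rho
  ll + lp_u + lp_v + lp_prior
}

# Poisson-GLM starting values for the fixed effects (clamped to keep the
# initial state well inside the prior bulk)
sel_glm_start <- function(data, spec) {
  d <- data.frame(y_s = data$y_s, y_a = data$y_a, z = data$z,
                  mesic = data$mesic, s_cov = data$s_cov)
  cf_s <- tryCatch(
    coef(glm(y_s ~ z * mesic, family = poisson(), data = d)),
    error = function(e) c(0, 0, 0, 0))
  cf_a <- tryCatch(
    coef(glm(y_a ~ s_cov + z + mesic + s_cov:mesic + z:mesic,
             family = poisson(), data = d)),
    error = function(e) rep(0, 6))
  cl <- function(x) ifelse(is.finite(x), pmin(pmax(x, -8), 8), 0)
  out <- c(alpha_s = cl(cf_s[["(Intercept)"]]),
           beta_mass = cl(cf_s[["z"]]), beta_site = cl(cf_s[["mesic"]]),
           beta_int = cl(cf_s[["z:mesic"]]),
           alpha_a = cl(cf_a[["(Intercept)"]]),
           gamma_seedling = cl(cf_a[["s_cov"]]),
           gamma_mass = cl(cf_a[["z"]]), gamma_site = cl(cf_a[["mesic"]]),
           gamma_mass_site = cl(cf_a[["z:mesic"]]),
           gamma_seedling_site = cl(cf_a[["s_cov:mesic"]]))
  if (isTRUE(spec$three_way)) out <- c(out, gamma_three = 0)
  out
}

# design matrices of the two submodels (intercept first)
sel_design <- function(spec, data) {
  Xs <- cbind(1, data$z, data$mesic, data$z * data$mesic)
  colnames(Xs) <- c("alpha_s", "beta_mass", "beta_site", "beta_int")
  Xa <- cbind(1, data$s_cov, data$z, data$mesic, data$z * data$mesic,
              data$s_cov * data$mesic)
  colnames(Xa) <- c("alpha_a", "gamma_seedling", "gamma_mass", "gamma_site",
                    "gamma_mass_site", "gamma_seedling_site")
  if (isTRUE(spec$three_way)) {
    Xa <- cbind(Xa, gamma_three = data$s_cov * data$z * data$mesic)
  }
  list(Xs = Xs, Xa = Xa)
}

# The sampler works on a column-centered design (the convention of the
# stated-prior software): slope samplers decorrelate from the intercept and
# the intercept prior applies on the centered scale; the reported intercept
# is back-transformed deterministically.
sel_jags_model <- function(spec, likelihood = TRUE) {
  pr_slope <- 1 / spec$prior_sd_slope^2
  pr_int <- 1 / spec$prior_sd_intercept^2
  pr_t <- 1 / spec$prior_t_scale^2
  ps <- 4L
  pa <- if (isTRUE(spec$three_way)) 7L else 6L
  paste0("model {\n",
    "  for (i in 1:n) {\n",
    "    e1[i] ~ dnorm(0, 1)\n",
    "    e2[i] ~ dnorm(0, 1)\n",
    "    u1[i] <- sd_u_seedling * e1[i]\n",
    "    u2[i] <- sd_u_adult * (rho * e1[i] + sqrt(1 - pow(rho, 2)) * e2[i])\n",
    "    eta_s[i] <- inprod(Xs[i, ], bs[]) + u1[i] + v_s[g[i]]\n",
    "    eta_a[i] <- inprod(Xa[i, ], ba[]) + u2[i] + v_a[g[i]]\n",
    if (likelihood) paste0(
      "    y_s[i] ~ dpois(exp(eta_s[i]))\n",
      "    y_a[i] ~ dpois(exp(eta_a[i]))\n"), "  }\n",
    "  for (j in 1:n_geno) {\n",
    "    f_s[j] ~ dnorm(0, 1)\n",
    "    f_a[j] ~ dnorm(0, 1)\n",
    "    v_s[j] <- sd_v_seedling * f_s[j]\n",
    "    v_a[j] <- sd_v_adult * f_a[j]\n  }\n",
    "  bs[1] ~ dnorm(0, ", pr_int, ")\n",
    "  for (k in 2:", ps, ") { bs[k] ~ dnorm(0, ", pr_slope, ") }\n",
    "  ba[1] ~ dnorm(0, ", pr_int, ")\n",
    "  for (k in 2:", pa, ") { ba[k] ~ dnorm(0, ", pr_slope, ") }\n",
    "  alpha_s <- bs[1] - inprod(bs[2:", ps, "], xbar_s[])\n",
    "  alpha_a <- ba[1] - inprod(ba[2:", pa, "], xbar_a[])\n",
    "  beta_mass <- bs[2]\n  beta_site <- bs[3]\n  beta_int <- bs[4]\n",
    "  gamma_seedling <- ba[2]\n  gamma_mass <- ba[3]\n",
    "  gamma_site <- ba[4]\n  gamma_mass_site <- ba[5]\n",
    "  gamma_seedling_site <- ba[6]\n",
    if (pa == 7L) "  gamma_three <- ba[7]\n",
    "  sd_u_seedling ~ dt(0, ", pr_t, ", ", spec$prior_t_df, ") T(0,)\n",
    "  sd_u_adult ~ dt(0, ", pr_t, ", ", spec$prior_t_df, ") T(0,)\n",
    "  sd_v_seedling ~ dt(0, ", pr_t, ", ", spec$prior_t_df, ") T(0,)\n",
    "  sd_v_adult ~ dt(0, ", pr_t, ", ", spec$prior_t_df, ") T(0,)\n",
    "  rho ~ dunif(-1, 1)\n",
    "}\n")
}

#' Sample the selection-model posterior
#'
#' Runs the MCMC (Gibbs/slice sampling via JAGS on the model rendered from
#' the spec), discarding the first half of each chain as warm-up, and
#' computes split-chain Rhat and effective sample sizes for the fixed
#' effects and hyperparameters. A run with any Rhat above 1.05 is returned
#' with `converged = FALSE` and a warning.
#'
#' @param data an [selection_data()] object.
#' @param spec an [selection_model_spec()].
#' @param chains,iter override the spec's sampler settings.
#' @param warmup iterations discarded per chain (adaptation included);
#'   default half of `iter`.
#' @param seed integer seed; the run is reproducible given the seed.
#' @param likelihood set `FALSE` to sample from the priors only.
#' @param quiet suppress JAGS progress output.
#' @return Object of class `ecosel_selection_posterior`: `draws` (pooled
#'   matrix, retained iterations x parameters), `chains` (`coda::mcmc.list`),
#'   `rhat`, `ess`, `converged`, plus the `spec` and `data`.
#' @export
sample_posterior <- function(data, spec = selection_model_spec(),
                             chains = spec$chains, iter = spec$iter,
                             warmup = floor(iter / 2),
                             seed = 1L, likelihood = TRUE, quiet = TRUE) {
  stopifnot(inherits(data, "ecosel_selection_data"))
  if (chains < 2 && likelihood) {
    warning("fewer than 2 chains: Rhat is split-chain only")
  }
  if (warmup < 1 || warmup >= iter) {
    ecosel_error("ecosel_config_error", "need 1 <= warmup < iter")
  }
  n_adapt <- min(warmup, 1000L)
  des <- sel_design(spec, data)
  xbar_s <- colMeans(des$Xs)[-1]
  xbar_a <- colMeans(des$Xa)[-1]
  Xs_c <- sweep(des$Xs[, -1, drop = FALSE], 2, xbar_s)
  Xa_c <- sweep(des$Xa[, -1, drop = FALSE], 2, xbar_a)
  jd <- list(n = data$n, n_geno = data$n_geno, g = data$g,
             Xs = cbind(1, Xs_c), Xa = cbind(1, Xa_c),
             xbar_s = xbar_s, xbar_a = xbar_a)
  if (likelihood) {
    jd$y_s <- data$y_s
    jd$y_a <- data$y_a
  }
  # start the fixed effects at Poisson-GLM estimates (cheap, deterministic)
  start <- if (likelihood) sel_glm_start(data, spec) else
    setNames(rep(0, length(SEL_FIXED)), SEL_FIXED)
  bs0 <- unname(start[colnames(des$Xs)])
  ba0 <- unname(start[colnames(des$Xa)])
  bs0[1] <- bs0[1] + sum(bs0[-1] * xbar_s)   # centered-scale intercepts
  ba0[1] <- ba0[1] + sum(ba0[-1] * xbar_a)
  inits <- lapply(seq_len(chains), function(ch) {
    list(bs = bs0, ba = ba0,
         .RNG.name = "base::Wichmann-Hill",
         .RNG.seed = stage_seed(seed, paste0("chain", ch)),
         sd_u_seedling = 0.3, sd_u_adult = 0.3,
         sd_v_seedling = 0.2, sd_v_adult = 0.2, rho = 0)
  })
  monitors <- c(SEL_FIXED, if (isTRUE(spec$three_way)) "gamma_three",
                SEL_HYPER)
  run <- function() {
    try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
    jm <- rjags::jags.model(textConnection(sel_jags_model(spec, likelihood)),
                            data = jd, inits = inits, n.chains = chains,
                            n.adapt = n_adapt, quiet = TRUE)
    if (warmup > n_adapt) stats::update(jm, warmup - n_adapt,
                                        progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = iter - warmup,
                        progress.bar = "none")
  }
  sm <- if (quiet) suppressWarnings(run()) else run()

  draws_by_chain <- lapply(sm, as.matrix)
  pooled <- do.call(rbind, draws_by_chain)
  rhat <- vapply(colnames(pooled), function(p) {
    split_rhat(sapply(draws_by_chain, function(m) m[, p]))
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(sm), error = function(e) {
    setNames(rep(NA_real_, ncol(pooled)), colnames(pooled))
  })
  converged <- all(is.finite(rhat)) && max(rhat) <= 1.05
  if (!converged && likelihood) {
    warning(sprintf("convergence failure: max Rhat = %.3f", max(rhat)))
  }
  structure(list(draws = pooled, chains = sm, rhat = rhat, ess = ess,
                 converged = converged, spec = spec, data = data,
                 n_chains = chains, iter = iter, warmup = warmup,
                 seed = seed, likelihood = likelihood),
            class = "ecosel_selection_posterior")
}

#' Site-specific selection gradients on seed mass
#'
#' The xeric-site gradient is the base seed-mass slope; the mesic-site
#' gradient adds the seed-mass x site interaction, draw-wise. Summaries are
#' the posterior mean, central 95% and 80% credible intervals, and the
#' posterior probability that the gradient is negative; the mesic-minus-
#' xeric difference is summarized the same way.
#'
#' @param posterior an [sample_posterior()] result.
#' @param response `"seedling"` or `"adult"`.
#' @return List of class `ecosel_gradients` with per-site summaries
#'   (`xeric`, `mesic`), `difference`, and the `draws` used.
#' @export
selection_gradients <- function(posterior,
                                response = c("seedling", "adult")) {
  response <- match.arg(response)
  stopifnot(inherits(posterior, "ecosel_selection_posterior"))
  dr <- posterior$draws
  base <- if (response == "seedling") "beta_mass" else "gamma_mass"
  int <- if (response == "seedling") "beta_int" else "gamma_mass_site"
  xeric <- dr[, base]
  mesic <- dr[, base] + dr[, int]
  summarize <- function(v) {
    list(mean = mean(v),
         ci95 = quantile(v, c(0.025, 0.975), names = FALSE),
         ci80 = quantile(v, c(0.10, 0.90), names = FALSE),
         prob_negative = mean(v < 0))
  }
  structure(list(response = response,
                 xeric = summarize(xeric), mesic = summarize(mesic),
                 difference = summarize(mesic - xeric),
                 draws = data.frame(xeric = xeric, mesic = mesic)),
            class = "ecosel_gradients")
}

#' Posterior predictive check of the count distributions
#'
#' Replicates datasets from the fitted model (new plot and genotype effects
#' drawn from their posterior hyperparameters, counts from the Poisson
#' likelihood; the adult submodel keeps the observed seedling covariate) and
#' compares the observed mean, variance and zero fraction of each response
#' with their replicated distributions via mid-p posterior predictive
#' p-values `Pr(T_rep > T_obs) + Pr(T_rep = T_obs)/2` (the mid correction
#' keeps discrete statistics such as the zero fraction calibrated at the
#' support boundary).
#'
#' @param posterior an [sample_posterior()] result.
#' @param data an [selection_data()] object (defaults to the fitted data).
#' @param n_rep replicated datasets (default 200).
#' @param seed RNG seed for the replication draws.
#' @return Data frame: response x statistic with observed value, replicated
#'   mean and `ppp`.
#' @export
posterior_predictive_check <- function(posterior, data = posterior$data,
                                       n_rep = 200, seed = 1L) {
  stopifnot(inherits(posterior, "ecosel_selection_posterior"))
  set.seed(stage_seed(seed, "ppc"))
  dr <- posterior$draws
  idx <- sample(nrow(dr), n_rep, replace = n_rep > nrow(dr))
  stats_fun <- function(y) c(mean = mean(y), variance = var(y),
                             zero_fraction = mean(y == 0))
  obs <- rbind(seedling = stats_fun(data$y_s), adult = stats_fun(data$y_a))
  reps <- array(NA_real_, c(n_rep, 2, 3),
                dimnames = list(NULL, c("seedling", "adult"),
                                colnames(obs)))
  for (r in seq_len(n_rep)) {
    p <- dr[idx[r], ]
    u <- rbvnorm(data$n, p["sd_u_seedling"], p["sd_u_adult"], p["rho"])
    v_s <- rnorm(data$n_geno, 0, p["sd_v_seedling"])
    v_a <- rnorm(data$n_geno, 0, p["sd_v_adult"])
    params <- c(as.list(p[c(SEL_FIXED,
                            if (isTRUE(posterior$spec$three_way))
                              "gamma_three")]),
                list(u = u, v_s = v_s, v_a = v_a))
    eta <- sel_linpreds(posterior$spec, params, data)
    reps[r, "seedling", ] <- stats_fun(rpois(data$n, exp(eta$eta_s)))
    reps[r, "adult", ] <- stats_fun(rpois(data$n, exp(eta$eta_a)))
  }
  out <- expand.grid(response = c("seedling", "adult"),
                     statistic = colnames(obs), stringsAsFactors = FALSE)
  out$observed <- mapply(function(rsp, st) obs[rsp, st],
                         out$response, out$statistic)
  out$rep_mean <- mapply(function(rsp, st) mean(reps[, rsp, st]),
                         out$response, out$statistic)
  out$ppp <- mapply(function(rsp, st) {
    mean(reps[, rsp, st] > obs[rsp, st]) +
      0.5 * mean(reps[, rsp, st] == obs[rsp, st])
  }, out$response, out$statistic)
  out
}

#' @export
print.ecosel_selection_posterior <- function(x, ...) {
  cat(sprintf("Selection-model posterior: %d chains x %d iterations (%d warm-up)\n",
              x$n_chains, x$iter, x$warmup))
  cat(sprintf("  max Rhat %.3f; min bulk ESS %.0f; converged: %s\n",
              max(x$rhat), min(x$ess, na.rm = TRUE), x$converged))
  invisible(x)
}

#' @export
print.ecosel_gradients <- function(x, ...) {
  cat(sprintf("Seed-mass selection gradients (%s recruitment, per SD):\n",
              x$response))
  for (s in c("xeric", "mesic")) {
    g <- x[[s]]
    cat(sprintf("  %-6s %+.3f [95%% CI %+.3f, %+.3f]  Pr(<0) = %.2f\n",
                s, g$mean, g$ci95[1], g$ci95[2], g$prob_negative))
  }
  cat(sprintf("  mesic - xeric: %+.3f [%+.3f, %+.3f]\n",
              x$difference$mean, x$difference$ci95[1], x$difference$ci95[2]))
  invisible(x)
}
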