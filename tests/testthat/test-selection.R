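# naive-loop oracle for the joint log posterior (kept deliberately
# elementary: scalar loops, explicit factorials, textbook densities)
brute_log_posterior <- function(spec, p, d) {
  lp <- 0
  for (i in seq_len(d$n)) {
    eta_s <- p$alpha_s + p$beta_mass * d$z[i] + p$beta_site * d$mesic[i] +
      p$beta_int * d$z[i] * d$mesic[i] + p$u[i, 1] + p$v_s[d$g[i]]
    eta_a <- p$alpha_a + p$gamma_seedling * d$s_cov[i] +
      p$gamma_mass * d$z[i] + p$gamma_site * d$mesic[i] +
      p$gamma_mass_site * d$z[i] * d$mesic[i] +
      p$gamma_seedling_site * d$s_cov[i] * d$mesic[i] +
      p$u[i, 2] + p$v_a[d$g[i]]
    lp <- lp + d$y_s[i] * eta_s - exp(eta_s) - lfactorial(d$y_s[i])
    lp <- lp + d$y_a[i] * eta_a - exp(eta_a) - lfactorial(d$y_a[i])
    # bivariate normal density of the plot-effect pair
    s1 <- p$sd_u[1]; s2 <- p$sd_u[2]; r <- p$rho
    qf <- (p$u[i, 1] / s1)^2 - 2 * r * p$u[i, 1] * p$u[i, 2] / (s1 * s2) +
      (p$u[i, 2] / s2)^2
    lp <- lp - log(2 * pi * s1 * s2 * sqrt(1 - r^2)) - qf / (2 * (1 - r^2))
  }
  for (j in seq_len(d$n_geno)) {
    lp <- lp + dnorm(p$v_s[j], 0, p$sd_v[1], log = TRUE) +
      dnorm(p$v_a[j], 0, p$sd_v[2], log = TRUE)
  }
  slopes <- c(p$beta_mass, p$beta_site, p$beta_int, p$gamma_seedling,
              p$gamma_mass, p$gamma_site, p$gamma_mass_site,
              p$gamma_seedling_site)
  lp <- lp + sum(dnorm(slopes, 0, spec$prior_sd_slope, log = TRUE))
  lp <- lp + dnorm(p$alpha_s, 0, spec$prior_sd_intercept, log = TRUE) +
    dnorm(p$alpha_a, 0, spec$prior_sd_intercept, log = TRUE)
  for (s in c(p$sd_u, p$sd_v)) {
    lp <- lp + log(2) + dt(s / spec$prior_t_scale, spec$prior_t_df,
                           log = TRUE) - log(spec$prior_t_scale)
  }
  lp - log(2)
}

toy_selection_data <- function() {
  plots <- data.frame(
    plot_id = paste0("P", 1:5),
    site = c("xeric", "xeric", "mesic", "mesic", "xeric"),
    genotype_id = c("G1", "G2", "G1", "G2", "G1"),
    ecotype = "upland", population_cluster = "u1",
    seeds_added = 100,
    seedling_count = c(0, 2, 5, 1, 3),
    adult_count = c(0, 1, 2, 0, 3),
    is_control = FALSE, stringsAsFactors = FALSE)
  selection_data(plots, c(G1 = 0.8, G2 = 1.3))
}

test_that("log_posterior matches the brute-force oracle on 5-plot toys", {
  d <- toy_selection_data()
  spec <- selection_model_spec()
  set.seed(5)
  for (i in 1:5) {
    p <- zero_params(d)
    for (nm in c("alpha_s", "beta_mass", "beta_site", "beta_int", "alpha_a",
                 "gamma_seedling", "gamma_mass", "gamma_site",
                 "gamma_mass_site", "gamma_seedling_site")) {
      p[[nm]] <- rnorm(1, 0, 0.8)
    }
    p$u <- matrix(rnorm(2 * d$n, 0, 0.5), d$n, 2)
    p$v_s <- rnorm(d$n_geno, 0, 0.3)
    p$v_a <- rnorm(d$n_geno, 0, 0.3)
    p$sd_u <- runif(2, 0.2, 1.5)
    p$sd_v <- runif(2, 0.2, 1.5)
    p$rho <- runif(1, -0.8, 0.8)
    expect_equal(log_posterior(spec, p, d), brute_log_posterior(spec, p, d),
                 tolerance = 1e-8)
  }
})

test_that("the plot-effect term factorizes at zero correlation", {
  d <- toy_selection_data()
  spec <- selection_model_spec()
  p <- zero_params(d)
  set.seed(7)
  p$u <- matrix(rnorm(2 * d$n, 0, 0.4), d$n, 2)
  p$sd_u <- c(0.7, 1.1)
  p$rho <- 0
  joint <- log_posterior(spec, p, d)
  # the bivariate term must equal two independent normal densities; isolate
  # it by differencing against the same state with u = 0
  indep <- sum(dnorm(p$u[, 1], 0, 0.7, log = TRUE)) +
    sum(dnorm(p$u[, 2], 0, 1.1, log = TRUE))
  p0 <- p
  p0$u <- matrix(0, d$n, 2)
  base <- log_posterior(spec, p0, d)
  base_u0 <- sum(dnorm(rep(0, d$n), 0, 0.7, log = TRUE)) +
    sum(dnorm(rep(0, d$n), 0, 1.1, log = TRUE))
  lik_term <- function(pp) {
    sum(dpois(d$y_s, exp(pp$alpha_s + pp$u[, 1]), log = TRUE)) +
      sum(dpois(d$y_a, exp(pp$alpha_a + pp$u[, 2]), log = TRUE))
  }
  expect_equal(joint - lik_term(p) - (base - lik_term(p0)),
               indep - base_u0, tolerance = 1e-12)
})

test_that("log_posterior validates its inputs", {
  d <- toy_selection_data()
  spec <- selection_model_spec()
  p <- zero_params(d)
  p$u <- matrix(0, 2, 2)
  expect_error(log_posterior(spec, p, d), class = "ecosel_config_error")
  p <- zero_params(d)
  p$beta_mass <- NULL
  expect_error(log_posterior(spec, p, d), class = "ecosel_config_error")
  p <- zero_params(d)
  p$alpha_s <- Inf
  expect_error(log_posterior(spec, p, d), class = "ecosel_config_error")
  p <- zero_params(d)
  p$rho <- 1.2
  expect_identical(log_posterior(spec, p, d), -Inf)
})

test_that("with random effects pinned at zero the posterior mode matches the
           Poisson GLM", {
  s <- small_field(seed = 21, n_reps = 6)
  d <- s$data
  spec <- selection_model_spec(prior_sd_slope = 1000,
                               prior_sd_intercept = 1000)
  obj <- function(th) {
    p <- zero_params(d)
    p$alpha_s <- th[1]; p$beta_mass <- th[2]; p$beta_site <- th[3]
    p$beta_int <- th[4]
    -log_posterior(spec, p, d)
  }
  opt <- optim(c(2, 0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  glm_fit <- glm(d$y_s ~ d$z * d$mesic, family = poisson())
  expect_equal(unname(opt$par), unname(coef(glm_fit)), tolerance = 0.02)
})

test_that("posterior sampling is reproducible and summarizes gradients", {
  s <- small_field(seed = 31)
  p1 <- suppressWarnings(sample_posterior(s$data, chains = 2, iter = 600,
                                          seed = 9))
  p2 <- suppressWarnings(sample_posterior(s$data, chains = 2, iter = 600,
                                          seed = 9))
  expect_identical(p1$draws, p2$draws)
  p3 <- suppressWarnings(sample_posterior(s$data, chains = 2, iter = 600,
                                          seed = 10))
  expect_false(identical(p1$draws, p3$draws))

  gr <- selection_gradients(p1, "seedling")
  expect_equal(gr$xeric$mean + gr$difference$mean, gr$mesic$mean,
               tolerance = 1e-10)
  expect_true(gr$xeric$ci95[1] <= gr$xeric$mean &&
                gr$xeric$mean <= gr$xeric$ci95[2])
  expect_true(all(gr$mesic$ci80 >= gr$mesic$ci95[1] - 1e-12) &&
                all(gr$mesic$ci80 <= gr$mesic$ci95[2] + 1e-12))
})

test_that("gradient identities hold on degenerate posteriors", {
  draws <- cbind(beta_mass = c(-0.2, -0.4, -0.3), beta_int = 0,
                 gamma_mass = c(-1, -2, -3), gamma_mass_site = c(1, 1, 1))
  fake <- structure(list(draws = draws), class = "ecosel_selection_posterior")
  gs <- selection_gradients(fake, "seedling")
  expect_equal(gs$xeric$mean, gs$mesic$mean)
  expect_equal(gs$difference$mean, 0)
  expect_equal(gs$xeric$prob_negative, 1.0)
  ga <- selection_gradients(fake, "adult")
  expect_equal(ga$difference$mean, 1.0)
})

test_that("prior-only sampling recovers the stated prior scales", {
  s <- small_field(seed = 41, n_reps = 2)
  pr <- sample_posterior(s$data, chains = 2, iter = 4000, seed = 3,
                         likelihood = FALSE)
  expect_equal(sd(pr$draws[, "beta_mass"]), 25, tolerance = 2)
  expect_equal(sd(pr$draws[, "gamma_mass"]), 25, tolerance = 2)
  expect_equal(sd(pr$draws[, "alpha_s"]), 10, tolerance = 1)
  expect_equal(mean(pr$draws[, "beta_mass"]), 0, tolerance = 1.5)
  expect_true(all(abs(pr$draws[, "rho"]) <= 1))
})

test_that("simulated-truth gradients are recovered by the sampler", {
  geno <- data.frame(genotype_id = sprintf("G%02d", 1:21),
                     ecotype = rep(c("lowland", "sympatric", "upland"),
                                   each = 7),
                     population_cluster = rep(c("l1", "s1", "u1"), each = 7),
                     seed_mass = seq(0.5, 1.5, length.out = 21))
  cfg <- field_config(gamma_mass = c(xeric = -0.49, mesic = -1.0), seed = 55)
  fld <- simulate_field(cfg, geno)
  d <- selection_data(fld$plots, setNames(geno$seed_mass, geno$genotype_id))
  post <- suppressWarnings(sample_posterior(d, chains = 2, iter = 3000,
                                            seed = 2))
  gr <- selection_gradients(post, "seedling")
  expect_true(gr$xeric$ci95[1] <= 0.20 && 0.20 <= gr$xeric$ci95[2])
  expect_true(gr$mesic$ci95[1] <= -0.56 && -0.56 <= gr$mesic$ci95[2])
  expect_equal(gr$difference$mean, -0.76, tolerance = 0.25)
})

test_that("posterior predictive checks calibrate and detect gross misfit", {
  s <- small_field(seed = 61)
  post <- suppressWarnings(sample_posterior(s$data, chains = 2, iter = 1500,
                                            seed = 4))
  ppc <- posterior_predictive_check(post, n_rep = 150, seed = 5)
  expect_true(all(ppc$ppp > 0.01 & ppc$ppp < 0.99))

  # gross misfit: multiply the observed counts tenfold
  d10 <- s$data
  d10$y_s <- d10$y_s * 10L
  d10$y_a <- d10$y_a * 10L
  ppc10 <- posterior_predictive_check(post, data = d10, n_rep = 100, seed = 6)
  expect_lt(ppc10$ppp[ppc10$response == "seedling" &
                        ppc10$statistic == "mean"], 0.01)

  # replicated statistics respect the count support
  expect_true(all(ppc$rep_mean[ppc$statistic == "zero_fraction"] >= 0))
  expect_true(all(ppc$rep_mean[ppc$statistic == "zero_fraction"] <= 1))
  expect_true(all(ppc$rep_mean[ppc$statistic == "mean"] >= 0))
  expect_true(all(post$draws[, "sd_u_seedling"] >= 0))
})

test_that("the sampler attains clean diagnostics on the default field design", {
  pan <- simulate_panel(panel_config(seed = 1))
  gm <- genotype_means(pan$traits)
  fg <- select_field_genotypes(gm, 3, seed = 1)
  fld <- simulate_field(field_config(seed = 1), fg)
  d <- selection_data(fld$plots, fg)
  # the Gibbs/slice sampler needs several-fold the nominal chain length to
  # match gradient-based effective sample sizes; run long, discard little
  post <- suppressWarnings(sample_posterior(d, chains = 3, iter = 30000,
                                            warmup = 3000, seed = 1))
  expect_lte(max(post$rhat), 1.01)
  expect_gte(min(post$ess), 400)
  expect_true(post$converged)
})
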