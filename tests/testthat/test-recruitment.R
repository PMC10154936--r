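# Newton-Raphson oracle for the Poisson log-link MLE (no IRLS machinery)
newton_poisson <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  for (i in seq_len(maxit)) {
    mu <- as.numeric(exp(X %*% beta))
    score <- crossprod(X, y - mu)
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

three_eco_plots <- function(seed = 1, n_rep = 20,
                            means = NULL) {
  set.seed(seed)
  grid <- expand.grid(site = c("xeric", "mesic"),
                      ecotype = c("lowland", "sympatric", "upland"),
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  lam <- if (is.null(means)) {
    exp(2 + 0.3 * (grid$site == "mesic") - 0.2 * (grid$ecotype == "upland") +
          0.5 * (grid$site == "mesic") * (grid$ecotype == "lowland"))
  } else means[cbind(grid$ecotype, grid$site)]
  data.frame(plot_id = paste0("P", seq_len(nrow(grid))),
             site = grid$site, genotype_id = "G1",
             ecotype = grid$ecotype, population_cluster = "c1",
             seeds_added = 100,
             seedling_count = rpois(nrow(grid), lam),
             adult_count = 0, is_control = FALSE, stringsAsFactors = FALSE)
}

test_that("the Poisson GLM matches an independent Newton solver", {
  d <- three_eco_plots(seed = 2)
  fit <- fit_poisson_glm(d, "seedling")
  X <- stats::model.matrix(~ ecotype * site, fit$data)
  oracle <- newton_poisson(X, fit$data$count)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-8)
})

test_that("intercept-only and saturated fits hit their closed forms", {
  d <- three_eco_plots(seed = 3)[1:3, ]
  d$seedling_count <- c(2, 4, 6)
  fit <- fit_poisson_glm(d, "seedling", formula = count ~ 1)
  expect_equal(unname(fit$coefficients), log(4), tolerance = 1e-10)
  expect_equal(unname(fit$fitted), rep(4, 3), tolerance = 1e-10)
  gof <- pearson_gof(fit)
  expect_equal(gof$x2, 2.0, tolerance = 1e-10)
  expect_equal(gof$df, 2)

  # saturated factorial: fitted values equal cell means
  d2 <- three_eco_plots(seed = 4)
  fit2 <- fit_poisson_glm(d2, "seedling")
  cm <- tapply(fit2$data$count, list(fit2$data$ecotype, fit2$data$site), mean)
  fitted_cells <- tapply(fit2$fitted, list(fit2$data$ecotype,
                                           fit2$data$site), mean)
  expect_equal(fitted_cells, cm, tolerance = 1e-8)
  expect_equal(pearson_gof(fit2)$x2,
               sum((fit2$data$count - fit2$fitted)^2 / fit2$fitted))

  # homogeneous counts: all non-intercept effects vanish
  d3 <- three_eco_plots(seed = 5)
  d3$seedling_count <- 7
  fit3 <- fit_poisson_glm(d3, "seedling")
  expect_equal(max(abs(fit3$coefficients[-1])), 0, tolerance = 1e-8)
})

test_that("canonical-link identity: fitted cell totals equal observed", {
  d <- three_eco_plots(seed = 6)
  fit <- fit_poisson_glm(d, "seedling")
  obs <- tapply(fit$data$count, list(fit$data$ecotype, fit$data$site), sum)
  hat <- tapply(fit$fitted, list(fit$data$ecotype, fit$data$site), sum)
  expect_equal(hat, obs, tolerance = 1e-8)
})

test_that("term tests are LR chi-squares with correct bookkeeping", {
  d <- three_eco_plots(seed = 7)
  fit <- fit_poisson_glm(d, "seedling")
  tt <- term_tests(fit)
  expect_equal(tt$df, c(2, 1, 2))
  expect_true(all(tt$chisq >= 0))

  # oracle: explicit deviance differences
  full <- glm(count ~ ecotype * site, poisson(), fit$data)
  main <- glm(count ~ ecotype + site, poisson(), fit$data)
  expect_equal(tt$chisq[tt$term == "site x ecotype"],
               deviance(main) - deviance(full), tolerance = 1e-8)

  # invariance to reference levels
  fit2 <- fit_poisson_glm(d, "seedling", site_ref = "mesic",
                          ecotype_ref = "upland")
  tt2 <- term_tests(fit2)
  expect_equal(tt2$chisq, tt$chisq, tolerance = 1e-8)

  # duplicating the data doubles each statistic
  d2 <- rbind(d, transform(d, plot_id = paste0(plot_id, "b")))
  tt3 <- term_tests(fit_poisson_glm(d2, "seedling"))
  expect_equal(tt3$chisq, 2 * tt$chisq, tolerance = 0.01 * max(tt$chisq))
})

test_that("dispersion is near one for true Poisson data", {
  d <- three_eco_plots(seed = 8, n_rep = 50)
  fit <- fit_poisson_glm(d, "seedling")
  expect_equal(pearson_gof(fit)$dispersion, 1.0, tolerance = 0.15)
})

test_that("site contrasts report direction, percent and Wald p", {
  means <- matrix(c(13.8, 10, 8, 8, 5, 10), 3, 2, byrow = TRUE,
                  dimnames = list(c("lowland", "sympatric", "upland"),
                                  c("mesic", "xeric")))
  d <- three_eco_plots(seed = 9, n_rep = 400, means = means)
  fit <- fit_poisson_glm(d, "seedling")
  sc <- site_contrasts(fit)
  low <- sc[sc$ecotype == "lowland", ]
  expect_equal(low$favoured_site, "mesic")
  expect_equal(low$pct_difference, 38, tolerance = 5)
  expect_lt(low$p, 1e-6)
  sym <- sc[sc$ecotype == "sympatric", ]
  expect_equal(sym$pct_difference, 0, tolerance = 6)
  expect_gt(sym$p, 0.05)
  # cell means and delta-method SEs match the observed scale
  expect_equal(low$mean_mesic,
               mean(fit$data$count[fit$data$ecotype == "lowland" &
                                     fit$data$site == "mesic"]),
               tolerance = 1e-8)
})

test_that("a generated within-ecotype site advantage is recovered", {
  z_up <- zscore(c(0.6, 1.4))$values[2]   # upland standardized seed mass
  a <- log(1.37) / (2 * z_up)             # -> upland xeric/mesic ratio 1.37
  geno <- data.frame(genotype_id = c("G1", "G2"),
                     ecotype = c("lowland", "upland"),
                     population_cluster = c("l1", "u1"),
                     seed_mass = c(0.6, 1.4))
  cfg <- field_config(n_reps = 300, alpha = c(seedling = log(12), adult = 0),
                      beta_mass = c(xeric = a, mesic = -a),
                      gamma_mass = c(xeric = 0, mesic = 0),
                      gamma_seedling = 0,
                      sd_plot = c(seedling = 0, adult = 0), cor_plot = 0,
                      sd_genotype = c(seedling = 0, adult = 0), seed = 10)
  fld <- simulate_field(cfg, geno)
  fit <- fit_poisson_glm(fld$plots, "seedling")
  up <- site_contrasts(fit)
  up <- up[up$ecotype == "upland", ]
  expect_equal(up$favoured_site, "xeric")
  expect_equal(up$pct_difference, 37, tolerance = 8)
})

test_that("control plots are excluded from models and summarized apart", {
  s <- small_field(seed = 12)
  fit <- fit_poisson_glm(s$fld$plots, "adult")
  expect_equal(nrow(fit$data), sum(!s$fld$plots$is_control))
  ctrl <- control_summary(s$fld$plots)
  expect_equal(sum(ctrl$n_plots), 14)
  expect_true(all(ctrl$seedling_count == 0))
})
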