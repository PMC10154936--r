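test_that("AICc follows its closed form and guards its domain", {
  expect_equal(aicc(-10, 2, 100), 24.12371134, tolerance = 1e-8)
  # large n: correction vanishes
  expect_lt(abs(aicc(-10, 3, 1e6) - (-2 * -10 + 2 * 3)), 1e-4)
  expect_error(aicc(-10, 2, 3), class = "ecosel_climate_error")
})

test_that("Akaike weights normalize relative likelihoods", {
  w1 <- akaike_weights(42.0)
  expect_equal(w1$weight, 1.0)
  w2 <- akaike_weights(c(10, 10))
  expect_equal(w2$weight, c(0.5, 0.5))
  w3 <- akaike_weights(c(100, 102))
  expect_equal(w3$delta, c(0, 2))
  expect_equal(w3$weight, c(0.7310586, 0.2689414), tolerance = 1e-6)
  set.seed(1)
  w4 <- akaike_weights(runif(20, 50, 80))
  expect_equal(sum(w4$weight), 1, tolerance = 1e-12)
  expect_true(all(w4$delta >= 0))
})

make_panel_mat_only <- function(seed = 1, effect = -0.28) {
  specs <- list(seed_mass = trait_spec(
    "log", ecotype_means = c(upland = 0, lowland = 0, sympatric = 0),
    sigma2_population = 0, sigma2_genotype = 0.16,
    sigma2_residual = 1e-5))
  simulate_panel(panel_config(traits = specs, climate_effect = effect,
                              seed = seed))
}

test_that("the global model recovers a pure MAT effect on seed mass", {
  pan <- make_panel_mat_only(seed = 3)
  gl <- fit_global_lmm(pan$traits, pan$climate)
  expect_equal(unname(gl$coefficients["mat"]), -0.28, tolerance = 0.1)

  # shift invariance: adding a constant to MAT leaves the coefficient alone
  cl2 <- pan$climate
  cl2$mat <- cl2$mat + 5
  gl2 <- fit_global_lmm(pan$traits, cl2)
  expect_equal(unname(gl2$coefficients["mat"]),
               unname(gl$coefficients["mat"]), tolerance = 1e-8)
})

test_that("when the random variances vanish the fit matches least squares", {
  pan <- make_panel_mat_only(seed = 7)
  frame <- climate_frame(pan$traits, pan$climate)
  gl <- fit_global_lmm(frame)
  vc <- as.data.frame(lme4::VarCorr(gl$fit))
  expect_equal(sum(vc$vcov[vc$grp != "Residual"]), 0)  # boundary fit
  ols <- lm(as.formula(paste("seed_mass ~",
                             paste(c("elevation", "latitude", "longitude",
                                     "mat", "temp_seasonality",
                                     "annual_precip", "precip_seasonality"),
                                   collapse = "+"))), data = frame)
  expect_equal(unname(gl$coefficients), unname(coef(ols)), tolerance = 1e-6)
})

test_that("all_subsets enumerates every additive model, ranked", {
  pan <- make_panel_mat_only(seed = 7)
  gl <- fit_global_lmm(pan$traits, pan$climate)
  cand2 <- all_subsets(gl, predictors = c("mat", "elevation"))
  expect_equal(nrow(cand2), 4)
  expect_setequal(cand2$predictor_set,
                  c("", "mat", "elevation", "mat+elevation"))
  expect_equal(cand2$delta[1], 0)
  expect_equal(sum(cand2$weight), 1, tolerance = 1e-12)

  cand <- all_subsets(gl)
  expect_equal(nrow(cand), 128)
  expect_equal(cand$delta[1], 0)
  expect_true(!is.unsorted(cand$aicc))

  # ranking invariant to a constant shift in log-likelihoods
  aw1 <- akaike_weights(cand$aicc)
  aw2 <- akaike_weights(cand$aicc + 1000)
  expect_equal(aw1$weight, aw2$weight, tolerance = 1e-12)
})

# hand-built candidate table exercising the averaging definition
fake_candidates <- function(coefs, ses, aiccs, predictors = c("A", "B")) {
  df <- data.frame(model_id = seq_along(aiccs),
                   predictor_set = vapply(seq_along(aiccs), function(i) {
                     paste(predictors[!is.na(coefs[[i]])], collapse = "+")
                   }, character(1)))
  for (j in seq_along(predictors)) {
    df[[predictors[j]]] <- vapply(coefs, `[`, numeric(1), j)
    df[[paste0("se_", predictors[j])]] <- vapply(ses, `[`, numeric(1), j)
  }
  df$loglik <- NA_real_; df$k <- 3
  df$aicc <- aiccs
  aw <- akaike_weights(aiccs)
  df$delta <- aw$delta; df$weight <- aw$weight
  attr(df, "predictors") <- predictors
  class(df) <- c("ecosel_candidates", "data.frame")
  df
}

test_that("full model averaging zero-substitutes absent predictors", {
  # two models with equal weight; A present only in the first with beta = 1
  cand <- fake_candidates(coefs = list(c(1, 0.5), c(NA, 0.5)),
                          ses = list(c(0.1, 0.1), c(NA, 0.1)),
                          aiccs = c(10, 10))
  avg <- model_average(cand, delta_max = 7)
  expect_equal(avg$averaged_coef[avg$predictor == "A"], 0.5)
  expect_equal(avg$importance[avg$predictor == "A"], 0.5)
  expect_equal(avg$importance[avg$predictor == "B"], 1.0)
  # B's unconditional SE reduces to the common within-model SE
  expect_equal(avg$unconditional_se[avg$predictor == "B"], 0.1)

  # retained set of one model returns that model's coefficients
  one <- model_average(fake_candidates(list(c(2, -1)), list(c(0.2, 0.3)),
                                       aiccs = 5), delta_max = 7)
  expect_equal(one$averaged_coef, c(2, -1))
  expect_equal(attr(one, "n_models"), 1L)

  # delta_max excludes distant models
  far <- fake_candidates(list(c(1, 0), c(3, 0)), list(c(0.1, 0.1), c(0.1, 0.1)),
                         aiccs = c(0, 50))
  expect_equal(model_average(far)$averaged_coef[1], 1)
  expect_error(model_average(far, delta_max = -1),
               class = "ecosel_climate_error")
})

test_that("averaged coefficients shrink as importance decreases", {
  # weight moves to models lacking predictor A via the AICc spacing
  shift <- seq(0, 4, by = 2)
  means <- vapply(shift, function(s) {
    cand <- fake_candidates(coefs = list(c(1, 0.5), c(NA, 0.5)),
                            ses = list(c(0.1, 0.1), c(NA, 0.1)),
                            aiccs = c(10 + s, 10))
    model_average(cand)$averaged_coef[1]
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_true(all(means > 0))
})

test_that("marginal R2 is the fixed-effect variance share", {
  pan <- make_panel_mat_only(seed = 9)
  gl <- fit_global_lmm(pan$traits, pan$climate)
  r2 <- marginal_r2(gl)
  expect_true(r2 >= 0 && r2 <= 1)
  # independent computation from the fit components
  X <- stats::model.matrix(gl$fit)
  vf <- var(as.numeric(X %*% lme4::fixef(gl$fit)))
  vc <- as.data.frame(lme4::VarCorr(gl$fit))
  expect_equal(r2, vf / (vf + sum(vc$vcov)), tolerance = 1e-10)

  # null fixed effects: shuffle climate so predictors carry no signal
  pan0 <- make_panel_mat_only(seed = 10, effect = 0)
  cl0 <- pan0$climate
  set.seed(1)
  for (p in setdiff(names(cl0), "genotype_id")) cl0[[p]] <- sample(cl0[[p]])
  gl0 <- fit_global_lmm(pan0$traits, cl0)
  expect_lt(marginal_r2(gl0), 0.15)
})

test_that("only MAT is flagged when it is the only true predictor", {
  pan <- make_panel_mat_only(seed = 11)
  gl <- fit_global_lmm(pan$traits, pan$climate)
  avg <- model_average(all_subsets(gl))
  expect_lt(avg$p[avg$predictor == "mat"], 0.05)
  expect_equal(avg$importance[avg$predictor == "mat"], 1, tolerance = 0.01)
  others <- avg$p[avg$predictor != "mat"]
  expect_gte(sum(others > 0.05, na.rm = TRUE), 5)
})

test_that("rank-deficient predictors are rejected with their names", {
  pan <- make_panel_mat_only(seed = 13)
  cl <- pan$climate
  cl$elevation <- cl$mat * 2 + 3  # aliased after standardization
  expect_error(fit_global_lmm(pan$traits, cl),
               class = "ecosel_climate_error")
})
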