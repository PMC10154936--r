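# Synthetic stand-ins for the diversity-panel and field-experiment data.
# The generators mirror the study design (3 ecotypes, 7 population clusters,
# 123 genotypes x 3 replicate blocks; 21 genotypes x 7 replicates x 2 sites,
# 100 seeds per plot) and return the generative truth so every downstream
# stage can be checked by parameter recovery.

#' Specification of one simulated trait
#'
#' Traits are generated hierarchically on a model scale: `ecotype mean +
#' cluster effect + genotype effect + block residual`, each Gaussian with the
#' configured variances, then transformed to the data scale. Sizes and masses
#' use a log scale (positivity), times a raw scale, and germination
#' percentage a logit scale.
#'
#' When `sma` is supplied the trait's genetic deviation is generated from the
#' genetic deviation of log seed mass so that, within each ecotype, the
#' standardized-major-axis slope of the trait on log seed mass equals
#' `sma[[ecotype]]$slope` with correlation `sma[[ecotype]]$r`; the trait's
#' own `sigma2_population`/`sigma2_genotype` are then implied by the link
#' rather than taken from the configuration.
#'
#' @param scale `"log"`, `"raw"` or `"logit"` (model scale).
#' @param ecotype_means named numeric, mean per ecotype on the model scale;
#'   `NULL` to draw ecotype effects from `N(0, sigma2_ecotype)` around
#'   `grand_mean`.
#' @param grand_mean grand mean used when `ecotype_means` is `NULL`.
#' @param sigma2_ecotype,sigma2_population,sigma2_genotype,sigma2_residual
#'   variance components on the model scale (all `>= 0`).
#' @param sma optional per-ecotype list of `list(slope =, r =)` linking the
#'   trait to log seed mass at the genetic level; `slope` and `r` must share
#'   their sign (an SMA slope carries the sign of the correlation).
#' @param empirical scale each drawn effect vector so its realized sample
#'   variance equals the configured component exactly (useful for parameter
#'   recovery studies; default `FALSE`).
#' @return A list of class `ecosel_trait_spec`.
#' @export
trait_spec <- function(scale = c("raw", "log", "logit"),
                       ecotype_means = NULL, grand_mean = 0,
                       sigma2_ecotype = 0, sigma2_population = 0,
                       sigma2_genotype = 1, sigma2_residual = 1,
                       sma = NULL, empirical = FALSE) {
  scale <- match.arg(scale)
  v <- c(sigma2_ecotype, sigma2_population, sigma2_genotype, sigma2_residual)
  if (any(v < 0)) {
    ecosel_error("ecosel_config_error", "variance components must be >= 0")
  }
  if (!is.null(sma)) {
    for (s in sma) {
      if (abs(s$r) > 1) {
        ecosel_error("ecosel_config_error", "|correlation| must be <= 1")
      }
      if (s$r * s$slope < 0) {
        ecosel_error("ecosel_config_error",
                     "SMA slope and correlation must share their sign")
      }
    }
  }
  structure(list(scale = scale, ecotype_means = ecotype_means,
                 grand_mean = grand_mean, sigma2_ecotype = sigma2_ecotype,
                 sigma2_population = sigma2_population,
                 sigma2_genotype = sigma2_genotype,
                 sigma2_residual = sigma2_residual, sma = sma,
                 empirical = isTRUE(empirical)),
            class = "ecosel_trait_spec")
}

# center and rescale a draw to an exact sample variance (empirical mode)
scale_to_var <- function(e, s2) {
  if (length(e) < 2 || s2 <= 0) return(e * sqrt(s2 > 0))
  v <- var(e)
  if (v == 0) return(e)
  (e - mean(e)) * sqrt(s2 / v)
}

# Empirical mode: center a draw within its parent stratum and scale it so
# the stratum's mean square equals the target (the expected mean square of
# a balanced nested ANOVA). The classical estimators -- and hence REML on a
# balanced design -- then recover the configured components exactly.
scale_to_ms <- function(e, target, parent = NULL) {
  if (target <= 0) return(e * 0)
  e <- if (is.null(parent)) e - mean(e) else e - ave(e, parent)
  df <- length(e) - if (is.null(parent)) 1L else length(unique(parent))
  ss <- sum(e^2)
  if (df < 1 || ss == 0) return(e)
  e * sqrt(target * df / ss)
}

default_trait_specs <- function() {
  sma3 <- function(up, sy, lo) {
    list(upland = list(slope = up[1], r = up[2]),
         sympatric = list(slope = sy[1], r = sy[2]),
         lowland = list(slope = lo[1], r = lo[2]))
  }
  list(
    # anchor trait; mg on log scale, tiny weighing residual (seed mass is a
    # genotype-level quantity: mass of 100 seeds / 100). Ecotype means and
    # genetic variances are set so ecotypes overlap (the sympatric group is
    # admixed) and ecotype remains the largest variance source for this trait.
    seed_mass = trait_spec("log",
      ecotype_means = c(upland = log(1.30), sympatric = log(0.95),
                        lowland = log(0.73)),
      sigma2_population = 0.018, sigma2_genotype = 0.050,
      sigma2_residual = 1e-4),
    # hours; large seeds germinate later in upland/sympatric groups
    germination_time = trait_spec("raw",
      ecotype_means = c(upland = 112, sympatric = 100, lowland = 88),
      sigma2_residual = 40,
      sma = sma3(c(60, 0.65), c(55, 0.6), c(-30, -0.25))),
    # proportion on logit scale; declines with seed mass except lowland
    germination_pct = trait_spec("logit",
      ecotype_means = c(upland = 0.55, sympatric = 0.85, lowland = 1.15),
      sigma2_residual = 0.08,
      sma = sma3(c(-2.0, -0.55), c(-1.8, -0.45), c(-1.2, -0.15))),
    # mm at day 18, log scale
    shoot_length = trait_spec("log",
      ecotype_means = c(upland = log(40), sympatric = log(43),
                        lowland = log(47)),
      sigma2_residual = 0.012,
      sma = sma3(c(0.55, 0.5), c(0.6, 0.55), c(0.35, 0.2))),
    root_length = trait_spec("log",
      ecotype_means = c(upland = log(60), sympatric = log(55),
                        lowland = log(50)),
      sigma2_residual = 0.012,
      sma = sma3(c(0.7, 0.65), c(0.65, 0.6), c(0.6, 0.6))),
    # days, raw scale; earlier flowering with larger seeds in lowland/sympatric
    flowering_time = trait_spec("raw",
      ecotype_means = c(upland = 70, sympatric = 74, lowland = 79),
      sigma2_residual = 12,
      sma = sma3(c(10, 0.08), c(-25, -0.35), c(-35, -0.6))),
    # count per panicle, log scale; the size-number trade-off flips by ecotype
    seed_number = trait_spec("log",
      ecotype_means = c(upland = log(105), sympatric = log(125),
                        lowland = log(155)),
      sigma2_residual = 0.05,
      sma = sma3(c(-1.1, -0.6), c(0.9, 0.45), c(0.6, 0.2))),
    # mg dry mass, log scale; lowland plants are larger
    aboveground_biomass = trait_spec("log",
      ecotype_means = c(upland = log(2800), sympatric = log(3300),
                        lowland = log(4000)),
      sigma2_residual = 0.03,
      sma = sma3(c(1.0, 0.55), c(0.9, 0.5), c(-0.8, -0.35)))
  )
}

#' Configuration of the synthetic diversity panel
#'
#' Defaults mirror the study design: three ecotypes (upland, lowland,
#' sympatric), seven population clusters (3 + 3 + 1), 123 genotypes and three
#' replicate blocks, with most genotypes in the widespread upland ecotype and
#' few in the lowland ecotype. Mean annual temperature of origin is generated
#' so that genotype seed mass regresses on standardized MAT with coefficient
#' `climate_effect` (mg per SD; default -0.28, i.e. lighter seeds from warmer
#' origins).
#'
#' @param clusters_per_ecotype named integer vector, clusters per ecotype.
#' @param genotypes_per_cluster named list (per ecotype) or vector of genotype
#'   counts per cluster; the default allocates 24/7/30 genotypes per
#'   upland/lowland/sympatric cluster (123 total).
#' @param n_blocks replicate blocks (default 3).
#' @param traits named list of [trait_spec()]s; must contain `seed_mass`.
#' @param climate_effect regression slope of genotype seed mass (mg) on
#'   standardized MAT.
#' @param mat_mean,mat_sd mean and SD (degrees C) used to place MAT on its
#'   natural scale (default SD 2.34).
#' @param seed RNG seed.
#' @return A list of class `ecosel_panel_config`.
#' @export
panel_config <- function(clusters_per_ecotype = c(upland = 3, lowland = 3,
                                                  sympatric = 1),
                         genotypes_per_cluster = list(upland = 24, lowland = 7,
                                                      sympatric = 30),
                         n_blocks = 3,
                         traits = default_trait_specs(),
                         climate_effect = -0.28,
                         mat_mean = 17.2, mat_sd = 2.34,
                         seed = 1L) {
  if (is.null(names(clusters_per_ecotype))) {
    ecosel_error("ecosel_config_error", "clusters_per_ecotype must be named")
  }
  if (!"seed_mass" %in% names(traits)) {
    ecosel_error("ecosel_config_error", "traits must include 'seed_mass'")
  }
  gpc <- lapply(names(clusters_per_ecotype), function(eco) {
    g <- if (is.list(genotypes_per_cluster)) {
      genotypes_per_cluster[[eco]] %||% genotypes_per_cluster[[1]]
    } else genotypes_per_cluster
    rep_len(g, clusters_per_ecotype[[eco]])
  })
  names(gpc) <- names(clusters_per_ecotype)
  if (any(unlist(gpc) < 1)) {
    ecosel_error("ecosel_config_error",
                 "every cluster needs at least one genotype")
  }
  structure(list(clusters_per_ecotype = clusters_per_ecotype,
                 genotypes_per_cluster = gpc, n_blocks = n_blocks,
                 traits = traits, climate_effect = climate_effect,
                 mat_mean = mat_mean, mat_sd = mat_sd, seed = seed),
            class = "ecosel_panel_config")
}

to_data_scale <- function(x, scale) {
  switch(scale, raw = x, log = exp(x), logit = plogis(x))
}

#' Simulate the diversity-panel trait and climate tables
#'
#' Draws trait values hierarchically per [trait_spec()], builds the
#' climate-of-origin table so that seed mass regresses on standardized MAT
#' with the configured coefficient, and returns the generative truth
#' (ecotype/cluster/genotype effects on the model scale and genotype-level
#' seed mass) for recovery tests.
#'
#' @param config an [panel_config()] object.
#' @return List with `traits` (validated trait table), `climate` (validated
#'   climate table) and `truth`.
#' @export
simulate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "ecosel_panel_config"))
  set.seed(stage_seed(config$seed, "panel"))

  ecos <- names(config$clusters_per_ecotype)
  # genotype frame
  rows <- list()
  gid <- 0L
  for (eco in ecos) {
    for (cl in seq_len(config$clusters_per_ecotype[[eco]])) {
      cl_name <- sprintf("%s_c%d", eco, cl)
      ng <- config$genotypes_per_cluster[[eco]][cl]
      for (g in seq_len(ng)) {
        gid <- gid + 1L
        rows[[gid]] <- data.frame(genotype_id = sprintf("G%03d", gid),
                                  ecotype = eco, population_cluster = cl_name,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  geno <- do.call(rbind, rows)
  n_g <- nrow(geno)
  clusters <- unique(geno[, c("ecotype", "population_cluster")])

  # balanced-design cell counts used by the empirical scaling targets
  n_cl <- nrow(clusters)
  C_bar <- n_cl / length(ecos)
  G_bar <- n_g / n_cl
  B <- config$n_blocks

  draw_effects <- function(spec) {
    ems <- function(lvls) {   # expected mean square per observation unit
      s <- spec$sigma2_residual / B
      if ("g" %in% lvls) s <- s + spec$sigma2_genotype
      if ("c" %in% lvls) s <- (s / G_bar) + spec$sigma2_population
      if ("e" %in% lvls && "c" %in% lvls) s <- (s / C_bar) + spec$sigma2_ecotype
      s
    }
    mu_eco <- if (!is.null(spec$ecotype_means)) {
      miss <- setdiff(ecos, names(spec$ecotype_means))
      if (length(miss)) {
        ecosel_error("ecosel_config_error",
                     sprintf("ecotype_means missing level(s): %s",
                             paste(miss, collapse = ", ")))
      }
      spec$ecotype_means[ecos]
    } else {
      e <- rnorm(length(ecos), 0, sqrt(spec$sigma2_ecotype))
      if (spec$empirical) e <- scale_to_ms(e, ems(c("e", "c", "g")))
      setNames(spec$grand_mean + e, ecos)
    }
    cl_eff <- rnorm(nrow(clusters), 0, sqrt(spec$sigma2_population))
    g_eff <- rnorm(n_g, 0, sqrt(spec$sigma2_genotype))
    if (spec$empirical) {
      cl_eff <- scale_to_ms(cl_eff, ems(c("c", "g")),
                            parent = clusters$ecotype)
      g_eff <- scale_to_ms(g_eff, ems("g"),
                           parent = geno$population_cluster)
    }
    list(mu_eco = mu_eco,
         cl_eff = setNames(cl_eff, clusters$population_cluster),
         g_eff = g_eff)
  }

  # seed mass anchors the allometric links
  sm_spec <- config$traits$seed_mass
  sm <- draw_effects(sm_spec)
  sm_gen <- sm$cl_eff[geno$population_cluster] + sm$g_eff  # genetic deviation
  sm_var_gen <- sm_spec$sigma2_population + sm_spec$sigma2_genotype
  geno_model <- list(seed_mass = sm$mu_eco[geno$ecotype] + sm_gen)
  truth_effects <- list(seed_mass = sm)

  for (tr in setdiff(names(config$traits), "seed_mass")) {
    spec <- config$traits[[tr]]
    if (is.null(spec$sma)) {
      ef <- draw_effects(spec)
      gen <- ef$cl_eff[geno$population_cluster] + ef$g_eff
      mu <- ef$mu_eco[geno$ecotype]
      truth_effects[[tr]] <- ef
    } else {
      mu_eco <- if (!is.null(spec$ecotype_means)) spec$ecotype_means[ecos]
                else setNames(rep(spec$grand_mean, length(ecos)), ecos)
      gen <- numeric(n_g)
      for (eco in ecos) {
        link <- spec$sma[[eco]]
        if (is.null(link)) {
          ecosel_error("ecosel_config_error",
                       sprintf("sma link for trait '%s' missing ecotype '%s'",
                               tr, eco))
        }
        idx <- geno$ecotype == eco
        b <- link$slope; r <- link$r
        noise <- rnorm(sum(idx), 0, sqrt(b^2 * sm_var_gen * (1 - r^2)))
        if (spec$empirical) {
          noise <- scale_to_var(noise, b^2 * sm_var_gen * (1 - r^2))
        }
        # regression of the trait's genetic deviation on log seed mass is
        # r * |b|; the SMA slope then equals b with sign(b) = sign(r)
        gen[idx] <- r * abs(b) * sm_gen[idx] + noise
      }
      mu <- mu_eco[geno$ecotype]
      truth_effects[[tr]] <- list(mu_eco = mu_eco, sma = spec$sma)
    }
    geno_model[[tr]] <- mu + gen
  }

  # replicate blocks with residual noise on the model scale
  blocks <- paste0("B", seq_len(config$n_blocks))
  tab <- geno[rep(seq_len(n_g), each = config$n_blocks), ]
  tab$block <- rep(blocks, times = n_g)
  for (tr in names(config$traits)) {
    spec <- config$traits[[tr]]
    eps <- rnorm(nrow(tab), 0, sqrt(spec$sigma2_residual))
    if (spec$empirical) {
      eps <- scale_to_ms(eps, spec$sigma2_residual,
                         parent = tab$genotype_id)
    }
    vals <- rep(geno_model[[tr]], each = config$n_blocks) + eps
    tab[[tr]] <- to_data_scale(vals, spec$scale)
  }
  for (tr in setdiff(TRAIT_COLS, names(config$traits))) {
    tab[[tr]] <- NA_real_   # traits not configured stay missing
  }
  tab <- tab[, schema_columns("trait")]
  rownames(tab) <- NULL

  # Climate of origin: standardized MAT is built from the genotype seed
  # masses (mg) so that seed mass regresses on z(MAT) with the configured
  # coefficient. The residual MAT variation is drawn hierarchically with
  # ecotype/cluster/genotype shares proportional to seed mass's own variance
  # decomposition, so the slope holds within clusters as well as marginally
  # and a nested mixed model recovers it regardless of pooling.
  sm_mg <- to_data_scale(geno_model$seed_mass, sm_spec$scale)
  v_sm <- var(sm_mg)
  if (config$climate_effect^2 > v_sm) {
    ecosel_error("ecosel_config_error",
                 paste("climate_effect^2 exceeds the genotype seed-mass",
                       "variance; no unit-variance MAT can satisfy it"))
  }
  cc <- config$climate_effect / v_sm
  v_e <- max(0, 1 - cc^2 * v_sm)
  eco_mean_sm <- tapply(sm_mg, geno$ecotype, mean)
  cl_mean_sm <- tapply(sm_mg, geno$population_cluster, mean)
  d_eco <- eco_mean_sm[geno$ecotype] - mean(sm_mg)
  d_cl <- cl_mean_sm[geno$population_cluster] - eco_mean_sm[geno$ecotype]
  d_g <- sm_mg - cl_mean_sm[geno$population_cluster]
  shares <- c(var(d_eco), var(d_cl), var(d_g))
  shares <- shares / sum(shares)
  unitize <- function(x) {
    s <- sd(x)
    if (is.finite(s) && s > 0) (x - mean(x)) / s else x * 0
  }
  e_eco <- setNames(rnorm(length(ecos)), ecos)
  e_cl <- setNames(rnorm(nrow(clusters)), clusters$population_cluster)
  zmat <- cc * (sm_mg - mean(sm_mg)) +
    sqrt(v_e) * (sqrt(shares[1]) * unitize(e_eco[geno$ecotype]) +
                 sqrt(shares[2]) * unitize(e_cl[geno$population_cluster]) +
                 sqrt(shares[3]) * rnorm(n_g))
  climate <- data.frame(
    genotype_id = geno$genotype_id,
    elevation = pmax(0, 800 - 320 * zmat + rnorm(n_g, 0, 220)),
    latitude = pmin(36, pmax(26, 30.5 - 1.1 * zmat + rnorm(n_g, 0, 1.4))),
    longitude = -98 + 0.8 * zmat + rnorm(n_g, 0, 1.8),
    mat = config$mat_mean + config$mat_sd * zmat,
    temp_seasonality = 7.2 + 0.9 * zmat + rnorm(n_g, 0, 0.7),
    annual_precip = pmax(120, 680 + 140 * zmat + rnorm(n_g, 0, 140)),
    precip_seasonality = 52 - 4.5 * zmat + rnorm(n_g, 0, 7),
    stringsAsFactors = FALSE
  )

  list(traits = validate_table(tab, "trait"),
       climate = validate_table(climate, "climate"),
       truth = list(config = config, genotypes = geno,
                    genotype_values_model_scale = as.data.frame(geno_model),
                    seed_mass_mg = setNames(sm_mg, geno$genotype_id),
                    zmat = zmat, effects = truth_effects))
}

#' Configuration of the synthetic field experiment
#'
#' Defaults mirror the reciprocal seed-addition design: 21 genotypes (three
#' per population cluster), seven replicate plots per genotype per site, two
#' sites (xeric, mesic), 100 seeds added per plot. Seed-mass gradients are
#' per standard deviation of genotype seed mass on the log-count scale; the
#' seedling defaults (xeric +0.20, mesic -0.56) and adult defaults (xeric
#' -0.49, mesic -1.5) reproduce selection favouring large seeds in xeric and
#' small seeds in mesic habitat. A mesic adult gradient much beyond -1.5 on a
#' log-linear generator makes the truncation at the seedling count bind for
#' most small-seeded plots (adult counts saturate), which no field census
#' shows; stronger regimes remain available through this argument.
#'
#' @param n_reps plots per genotype per site.
#' @param seeds_added seeds sown per treatment plot.
#' @param n_controls no-seed control plots per site.
#' @param alpha named log-scale intercepts `c(seedling =, adult =)`.
#' @param beta_mass named seedling gradients `c(xeric =, mesic =)` per SD of
#'   seed mass.
#' @param gamma_mass named adult gradients `c(xeric =, mesic =)` per SD.
#' @param gamma_seedling adult log-count effect per observed seedling.
#' @param sd_plot plot-effect SDs `c(seedling =, adult =)`.
#' @param cor_plot correlation of the two plot effects.
#' @param sd_genotype genotype-effect SDs `c(seedling =, adult =)`.
#' @param seed RNG seed.
#' @return List of class `ecosel_field_config`.
#' @export
field_config <- function(n_reps = 7, seeds_added = 100, n_controls = 7,
                         alpha = c(seedling = log(12), adult = log(0.6)),
                         beta_mass = c(xeric = 0.20, mesic = -0.56),
                         gamma_mass = c(xeric = -0.49, mesic = -1.5),
                         gamma_seedling = 0.05,
                         sd_plot = c(seedling = 0.30, adult = 0.30),
                         cor_plot = 0.5,
                         sd_genotype = c(seedling = 0.20, adult = 0.20),
                         seed = 1L) {
  if (abs(cor_plot) > 1) {
    ecosel_error("ecosel_config_error", "|cor_plot| must be <= 1")
  }
  if (any(c(sd_plot, sd_genotype) < 0)) {
    ecosel_error("ecosel_config_error", "random-effect sds must be >= 0")
  }
  if (n_reps < 1 || seeds_added < 1) {
    ecosel_error("ecosel_config_error", "counts must be positive")
  }
  structure(list(n_reps = n_reps, seeds_added = seeds_added,
                 n_controls = n_controls, alpha = alpha,
                 beta_mass = beta_mass, gamma_mass = gamma_mass,
                 gamma_seedling = gamma_seedling, sd_plot = sd_plot,
                 cor_plot = cor_plot, sd_genotype = sd_genotype, seed = seed),
            class = "ecosel_field_config")
}

#' Pick field genotypes from a panel (n per population cluster)
#'
#' @param panel_means genotype-level trait means (see [genotype_means()]).
#' @param per_cluster genotypes sampled per population cluster (default 3).
#' @param seed RNG seed.
#' @return Subset of `panel_means` rows.
#' @export
select_field_genotypes <- function(panel_means, per_cluster = 3, seed = 1L) {
  set.seed(stage_seed(seed, "field_genotypes"))
  idx <- unlist(lapply(split(seq_len(nrow(panel_means)),
                             panel_means$population_cluster),
                       function(i) sample(i, min(per_cluster, length(i)))))
  out <- panel_means[sort(idx), ]
  rownames(out) <- NULL
  out
}

#' Simulate the reciprocal seed-addition field experiment
#'
#' Per plot, correlated plot effects `(u_S, u_A)` are drawn from a bivariate
#' normal; seedling counts are Poisson with log mean `alpha_S +
#' beta_mass[site] * z(seed mass) + genotype effect + u_S`, truncated at the
#' number of seeds added; adult counts are Poisson with log mean `alpha_A +
#' gamma_seedling * seedlings + gamma_mass[site] * z(seed mass) + genotype
#' effect + u_A`, truncated at the seedling count. Control plots receive no
#' seed and emit zero counts.
#'
#' @param config an [field_config()] object.
#' @param genotypes data frame with `genotype_id`, `ecotype`,
#'   `population_cluster` and `seed_mass` (mg per seed, genotype level).
#' @return List with `plots` (validated plot table) and `truth` (generative
#'   parameters, standardized seed mass and random effects).
#' @export
simulate_field <- function(config = field_config(), genotypes) {
  stopifnot(inherits(config, "ecosel_field_config"))
  if (any(is.na(genotypes$seed_mass))) {
    ecosel_error("ecosel_config_error",
                 "seed_mass must be available for all field genotypes")
  }
  set.seed(stage_seed(config$seed, "field"))
  zs <- zscore(genotypes$seed_mass)
  z <- zs$values
  n_g <- nrow(genotypes)
  vS <- rnorm(n_g, 0, config$sd_genotype[["seedling"]])
  vA <- rnorm(n_g, 0, config$sd_genotype[["adult"]])

  grid <- expand.grid(site = SITE_LEVELS, rep = seq_len(config$n_reps),
                      g = seq_len(n_g), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  u <- rbvnorm(n, config$sd_plot[["seedling"]], config$sd_plot[["adult"]],
               config$cor_plot)
  eta_s <- config$alpha[["seedling"]] +
    config$beta_mass[grid$site] * z[grid$g] + vS[grid$g] + u[, 1]
  y_s <- pmin(rpois(n, exp(eta_s)), config$seeds_added)
  eta_a <- config$alpha[["adult"]] + config$gamma_seedling * y_s +
    config$gamma_mass[grid$site] * z[grid$g] + vA[grid$g] + u[, 2]
  y_a <- pmin(rpois(n, exp(eta_a)), y_s)

  plots <- data.frame(
    plot_id = sprintf("P%03d", seq_len(n)),
    site = grid$site,
    genotype_id = genotypes$genotype_id[grid$g],
    ecotype = genotypes$ecotype[grid$g],
    population_cluster = genotypes$population_cluster[grid$g],
    seeds_added = config$seeds_added,
    seedling_count = y_s,
    adult_count = y_a,
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
  ctrl <- data.frame(
    plot_id = sprintf("C%03d", seq_len(2 * config$n_controls)),
    site = rep(SITE_LEVELS, each = config$n_controls),
    genotype_id = NA_character_, ecotype = NA_character_,
    population_cluster = NA_character_, seeds_added = 0,
    seedling_count = 0, adult_count = 0, is_control = TRUE,
    stringsAsFactors = FALSE
  )
  plots <- rbind(plots, ctrl)

  list(plots = validate_table(plots, "plot"),
       truth = list(config = config,
                    z_seed_mass = setNames(z, genotypes$genotype_id),
                    z_center = zs$center, z_scale = zs$scale,
                    genotype_effects = data.frame(
                      genotype_id = genotypes$genotype_id,
                      v_seedling = vS, v_adult = vA),
                    plot_effects = u))
}
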