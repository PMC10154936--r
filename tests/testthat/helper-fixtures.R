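# Shared fixtures, built in code.

# minimal valid trait table (2 genotypes x 2 blocks)
tiny_trait_table <- function() {
  data.frame(
    genotype_id = rep(c("G1", "G2"), each = 2),
    ecotype = rep(c("upland", "lowland"), each = 2),
    population_cluster = rep(c("u1", "l1"), each = 2),
    block = rep(c("B1", "B2"), 2),
    seed_mass = rep(c(1.2, 0.7), each = 2),
    germination_time = c(100, 104, 80, 84),
    germination_pct = c(0.6, 0.7, 0.8, 0.75),
    shoot_length = c(40, 42, 48, 47),
    root_length = c(60, 61, 50, 52),
    flowering_time = c(70, 72, 80, 79),
    seed_number = c(100, 110, 150, 140),
    aboveground_biomass = c(2800, 2900, 4000, 4100),
    stringsAsFactors = FALSE
  )
}

tiny_plot_table <- function() {
  data.frame(
    plot_id = paste0("P", 1:4),
    site = c("xeric", "mesic", "xeric", "mesic"),
    genotype_id = c("G1", "G1", "G2", "G2"),
    ecotype = c("upland", "upland", "lowland", "lowland"),
    population_cluster = c("u1", "u1", "l1", "l1"),
    seeds_added = 100,
    seedling_count = c(12, 8, 9, 15),
    adult_count = c(3, 1, 2, 5),
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
}

# balanced nested Gaussian panel with known variance components, via the
# generator's generic trait specification
nested_panel <- function(n_eco, n_cl, n_geno, n_blocks, sigma2,
                         seed = 1L, sma = NULL) {
  cfg <- panel_config(
    clusters_per_ecotype = setNames(rep(n_cl, n_eco), paste0("E", seq_len(n_eco))),
    genotypes_per_cluster = n_geno,
    n_blocks = n_blocks,
    traits = list(
      seed_mass = trait_spec("log", grand_mean = 0, sigma2_ecotype = 0.02,
                             sigma2_population = 0, sigma2_genotype = 0.04,
                             sigma2_residual = 1e-5, empirical = TRUE),
      germination_time = trait_spec("raw", grand_mean = 100,
                                    sigma2_ecotype = sigma2[1],
                                    sigma2_population = sigma2[2],
                                    sigma2_genotype = sigma2[3],
                                    sigma2_residual = sigma2[4],
                                    sma = sma, empirical = TRUE)),
    climate_effect = 0,
    seed = seed)
  simulate_panel(cfg)
}

# small field design + selection data for Bayesian tests
small_field <- function(seed = 3, n_reps = 4,
                        beta_mass = c(xeric = 0.20, mesic = -0.56),
                        gamma_mass = c(xeric = -0.49, mesic = -1.0), ...) {
  geno <- data.frame(
    genotype_id = sprintf("G%02d", 1:12),
    ecotype = rep(c("lowland", "sympatric", "upland"), each = 4),
    population_cluster = rep(c("l1", "s1", "u1"), each = 4),
    seed_mass = seq(0.5, 1.5, length.out = 12),
    stringsAsFactors = FALSE)
  cfg <- field_config(n_reps = n_reps, beta_mass = beta_mass,
                      gamma_mass = gamma_mass, seed = seed, ...)
  fld <- simulate_field(cfg, geno)
  list(geno = geno, cfg = cfg, fld = fld,
       data = selection_data(fld$plots,
                             setNames(geno$seed_mass, geno$genotype_id)))
}

# default-size parameter list for log_posterior tests
zero_params <- function(data, spec = selection_model_spec()) {
  list(alpha_s = 0, beta_mass = 0, beta_site = 0, beta_int = 0,
       alpha_a = 0, gamma_seedling = 0, gamma_mass = 0, gamma_site = 0,
       gamma_mass_site = 0, gamma_seedling_site = 0,
       u = matrix(0, data$n, 2), v_s = rep(0, data$n_geno),
       v_a = rep(0, data$n_geno), sd_u = c(1, 1), rho = 0, sd_v = c(1, 1))
}
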