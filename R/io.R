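# Table schemas, validation and CSV round-trip for the three pipeline inputs:
# the diversity-panel trait table, the climate-of-origin table and the field
# plot table.

TRAIT_COLS <- c("seed_mass", "germination_time", "germination_pct",
                "shoot_length", "root_length", "flowering_time",
                "seed_number", "aboveground_biomass")

CLIMATE_PREDICTORS <- c("elevation", "latitude", "longitude", "mat",
                        "temp_seasonality", "annual_precip",
                        "precip_seasonality")

ECOTYPE_LEVELS <- c("lowland", "sympatric", "upland")
SITE_LEVELS <- c("xeric", "mesic")

schema_columns <- function(schema) {
  switch(schema,
    trait = c("genotype_id", "ecotype", "population_cluster", "block",
              TRAIT_COLS),
    climate = c("genotype_id", CLIMATE_PREDICTORS),
    plot = c("plot_id", "site", "genotype_id", "ecotype",
             "population_cluster", "seeds_added", "seedling_count",
             "adult_count", "is_control"),
    ecosel_error("ecosel_schema_error",
                 sprintf("unknown schema '%s'", schema))
  )
}

#' Read and validate a pipeline table
#'
#' Reads a CSV file with a header row, coerces columns to the types of the
#' requested schema and checks the schema invariants. The three schemas are
#' `"trait"` (genotype x replicate-block life-history traits with ecotype and
#' population-cluster labels), `"climate"` (one row of climate-of-origin
#' covariates per genotype) and `"plot"` (the field seed-addition design with
#' seedling and adult counts per plot).
#'
#' Germination percentage is stored as a proportion in `[0, 1]`; input on the
#' percent scale (values greater than 1) is auto-detected, divided by 100 and
#' reported via a message.
#'
#' @param path path to a CSV file with a header row.
#' @param schema one of `"trait"`, `"climate"`, `"plot"`.
#' @return A validated `data.frame` with class `ecosel_<schema>_table`.
#' @seealso [validate_table()], [write_table()]
#' @export
read_table <- function(path, schema = c("trait", "climate", "plot")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    ecosel_error("ecosel_io_error", sprintf("file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema)
}

#' Validate a data frame against a pipeline schema
#'
#' @param df a data frame.
#' @param schema one of `"trait"`, `"climate"`, `"plot"`.
#' @return The validated (and possibly rescaled/typed) data frame, classed
#'   `ecosel_<schema>_table`.
#' @export
validate_table <- function(df, schema = c("trait", "climate", "plot")) {
  schema <- match.arg(schema)
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    ecosel_error("ecosel_schema_error",
                 sprintf("schema '%s' is missing required column(s): %s",
                         schema, paste(missing_cols, collapse = ", ")),
                 columns = missing_cols)
  }
  df <- df[, cols, drop = FALSE]
  check <- switch(schema,
                  trait = validate_trait(df),
                  climate = validate_climate(df),
                  plot = validate_plot(df))
  class(check) <- c(paste0("ecosel_", schema, "_table"), "data.frame")
  check
}

fail_rows <- function(bad, what) {
  ecosel_error("ecosel_validation_error",
               sprintf("%s (offending row(s): %s)", what,
                       paste(utils::head(which(bad), 10L), collapse = ", ")),
               rows = which(bad))
}

validate_trait <- function(df) {
  df$genotype_id <- as.character(df$genotype_id)
  df$ecotype <- as.character(df$ecotype)
  df$population_cluster <- as.character(df$population_cluster)
  df$block <- as.character(df$block)
  for (tr in TRAIT_COLS) df[[tr]] <- as.numeric(df[[tr]])

  # percent-scale germination auto-detection
  gp <- df$germination_pct
  if (any(gp > 1, na.rm = TRUE)) {
    if (any(gp > 100, na.rm = TRUE)) {
      fail_rows(!is.na(gp) & gp > 100, "germination_pct above 100")
    }
    message("germination_pct supplied on the percent scale; divided by 100")
    df$germination_pct <- gp / 100
  }
  gp <- df$germination_pct
  if (any(gp < 0 | gp > 1, na.rm = TRUE)) {
    fail_rows(!is.na(gp) & (gp < 0 | gp > 1),
              "germination_pct outside [0, 1]")
  }
  for (tr in setdiff(TRAIT_COLS, "flowering_time")) {
    if (any(df[[tr]] < 0, na.rm = TRUE)) {
      fail_rows(!is.na(df[[tr]]) & df[[tr]] < 0,
                sprintf("negative values in %s", tr))
    }
  }
  # one ecotype and one population cluster per genotype
  eco_n <- tapply(df$ecotype, df$genotype_id, function(x) length(unique(x)))
  if (any(eco_n > 1)) {
    ecosel_error("ecosel_validation_error",
                 sprintf("genotype(s) with conflicting ecotype labels: %s",
                         paste(names(eco_n)[eco_n > 1], collapse = ", ")))
  }
  pc_n <- tapply(df$population_cluster, df$genotype_id,
                 function(x) length(unique(x)))
  if (any(pc_n > 1)) {
    ecosel_error("ecosel_validation_error",
                 sprintf("genotype(s) with conflicting population_cluster labels: %s",
                         paste(names(pc_n)[pc_n > 1], collapse = ", ")))
  }
  # seed mass is a genotype-level quantity (mass of 100 seeds / 100);
  # replicate weighings may differ slightly, so near-constancy is enforced
  rel_sd <- tapply(df$seed_mass, df$genotype_id, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(0)
    sd(x) / mean(x)
  })
  if (any(rel_sd > 0.05, na.rm = TRUE)) {
    ecosel_error("ecosel_validation_error",
                 sprintf("seed_mass varies by more than 5%% within genotype(s): %s",
                         paste(names(rel_sd)[rel_sd > 0.05], collapse = ", ")))
  }
  df
}

validate_climate <- function(df) {
  df$genotype_id <- as.character(df$genotype_id)
  for (cl in CLIMATE_PREDICTORS) df[[cl]] <- as.numeric(df[[cl]])
  if (anyDuplicated(df$genotype_id)) {
    ecosel_error("ecosel_validation_error",
                 "climate table must have one row per genotype")
  }
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE)) {
    fail_rows(!is.na(df$latitude) & (df$latitude < -90 | df$latitude > 90),
              "latitude outside [-90, 90]")
  }
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE)) {
    fail_rows(!is.na(df$longitude) & abs(df$longitude) > 180,
              "longitude outside [-180, 180]")
  }
  df
}

validate_plot <- function(df) {
  df$plot_id <- as.character(df$plot_id)
  df$site <- as.character(df$site)
  df$genotype_id <- as.character(df$genotype_id)
  df$ecotype <- as.character(df$ecotype)
  df$population_cluster <- as.character(df$population_cluster)
  df$is_control <- as.logical(df$is_control)
  for (cc in c("seeds_added", "seedling_count", "adult_count")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (!is_count(df[[cc]])) {
      fail_rows(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] != round(df[[cc]])),
                sprintf("%s must be a non-negative integer", cc))
    }
  }
  bad_site <- !df$site %in% SITE_LEVELS
  if (any(bad_site)) fail_rows(bad_site, "site must be 'xeric' or 'mesic'")
  bad <- !is.na(df$adult_count) & !is.na(df$seedling_count) &
    df$adult_count > df$seedling_count
  if (any(bad)) fail_rows(bad, "adult_count exceeds seedling_count")
  df
}

#' Write a pipeline table to CSV
#'
#' @param df a validated pipeline table (or plain data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' Standardize a numeric vector (z-score)
#'
#' Centers and scales with the sample standard deviation (n - 1 denominator)
#' and keeps the transform parameters so values can be mapped back to the
#' original scale. Coefficients estimated on z-scored predictors are read as
#' "per standard deviation" effects.
#'
#' @param x numeric vector, `n >= 2`, non-constant. `NA`s are ignored for the
#'   parameters and propagated in the output.
#' @return A list with `values`, `center`, `scale`, classed `ecosel_zscore`.
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (sum(!is.na(x)) < 2) {
    ecosel_error("ecosel_scale_error", "need at least 2 non-missing values")
  }
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    ecosel_error("ecosel_scale_error",
                 "constant column cannot be standardized (sd = 0)")
  }
  structure(list(values = (x - m) / s, center = m, scale = s),
            class = "ecosel_zscore")
}

#' Invert a z-score transform
#'
#' @param z an `ecosel_zscore` object, or a numeric vector together with
#'   `center` and `scale`.
#' @param center,scale transform parameters when `z` is a plain vector.
#' @return Numeric vector on the original scale.
#' @export
unzscore <- function(z, center = NULL, scale = NULL) {
  if (inherits(z, "ecosel_zscore")) {
    return(z$values * z$scale + z$center)
  }
  z * scale + center
}

#' Collapse genotype-by-block replicates to genotype means
#'
#' Averages every numeric trait across replicate blocks within genotype,
#' preserving the ecotype and population-cluster labels. Downstream stages
#' (discriminant analysis, allometry, climate models) operate on these
#' genotype-level means.
#'
#' @param table a validated trait table.
#' @param na.rm drop missing cells when averaging (default `TRUE`).
#' @return A data frame with one row per genotype.
#' @export
genotype_means <- function(table, na.rm = TRUE) {
  stopifnot(is.data.frame(table))
  eco_n <- tapply(table$ecotype, table$genotype_id,
                  function(x) length(unique(x)))
  if (any(eco_n > 1)) {
    ecosel_error("ecosel_validation_error",
                 "conflicting ecotype labels within a genotype")
  }
  labs <- unique(table[, c("genotype_id", "ecotype", "population_cluster")])
  num_cols <- intersect(TRAIT_COLS, names(table))
  agg <- aggregate(table[num_cols], by = list(genotype_id = table$genotype_id),
                   FUN = function(x) mean(x, na.rm = na.rm))
  agg[num_cols] <- lapply(agg[num_cols], function(x) {
    x[is.nan(x)] <- NA_real_
    x
  })
  out <- merge(labs, agg, by = "genotype_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Collapse the lowland population clusters into a single group
#'
#' The lowland ecotype contributes few genotypes per cluster, so the variance
#' partition stage condenses its three clusters into one group before fitting
#' the nested random-effects model. The relabelling is explicit and reported.
#'
#' @param table a trait table (replicate- or genotype-level).
#' @param label replacement cluster label (default `"lowland_all"`).
#' @param quiet suppress the message.
#' @return The table with lowland rows relabelled.
#' @export
collapse_lowland_clusters <- function(table, label = "lowland_all",
                                      quiet = FALSE) {
  idx <- table$ecotype == "lowland"
  n_cl <- length(unique(table$population_cluster[idx]))
  table$population_cluster[idx] <- label
  if (!quiet && n_cl > 1) {
    message(sprintf("collapsed %d lowland population clusters into '%s'",
                    n_cl, label))
  }
  table
}

#' Default pipeline configuration
#'
#' Reference levels, seeds and iteration counts shared across stages. A YAML
#' file with any subset of these keys can be merged over the defaults with
#' [read_config()].
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(
    site_reference = "xeric",
    ecotype_reference = "lowland",
    seed = 1L,
    n_boot = 1000L,
    delta_max = 7,
    chains = 3L,
    iter = 4000L
  )
}

#' Read a YAML configuration file
#'
#' @param path YAML file; keys override [default_config()].
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (!requireNamespace("yaml", quietly = TRUE)) {
    ecosel_error("ecosel_io_error", "the 'yaml' package is required")
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
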