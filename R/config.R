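#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. Defaults encode the experimental world the downstream analyses
#' assume: three independent biological repeats, a ten-point sampling grid
#' from 20 min to 48 h, five housekeeping genes for count normalization,
#' a 30\% wild-type rosette reduction under mild osmotic stress, ten plants
#' per genotype and condition (eight for crosses), and four transactivation
#' assay replicates in each of three experiments.
#'
#' @param n_repeats integer, number of independent biological repeats (>= 2).
#' @param time_grid_h strictly increasing sampling times in hours.
#' @param nb_dispersion negative-binomial overdispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param housekeeping_ids identifiers of the condition-independent
#'   housekeeping genes appended to every simulated count table.
#' @param hk_mean expected housekeeping count before size/batch factors.
#' @param gain counts per unit of simulated transcript concentration.
#' @param sf_sdlog log-normal sd of the per-sample size factor.
#' @param batch_sdlog log-normal sd of the per-repeat batch factor.
#' @param stress_area_multiplier wild-type rosette area multiplier under
#'   stress relative to control, in (0, 2]; 0.70 plants a 30\% reduction.
#' @param n_plants plants per genotype x condition in phenotype simulations.
#' @param n_plants_cross plants per cross genotype in epistasis simulations.
#' @param tea_cv log-normal sd of replicate luminescence noise.
#' @param tea_reps replicates per construct per experiment.
#' @param tea_experiments number of independent TEA experiments (batches).
#' @param interaction_coefficients optional named numeric, per-cross log2-scale
#'   deviation from additivity.
#' @param base_area_mm2 wild-type control rosette area (mm^2) at harvest.
#' @param plant_sdlog log-normal sd of plant-to-plant area variation.
#' @param repeat_sdlog log-normal sd of the per-repeat area batch effect.
#' @param n_leaves number of leaves in the simulated leaf series.
#' @param cell_area_um2 mean pavement cell area (micrometre^2) of leaf 3.
#' @param cell_sdlog log-normal sd of cell-to-cell area variation.
#' @param cells_per_leaf pavement cells sampled per leaf (default 100,
#'   matching the "approximately 100 cells traced" convention).
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_repeats = 3)
#' cfg$time_grid_h
sim_config <- function(n_repeats = 3L,
                       time_grid_h = c(0.33, 0.67, 1, 2, 4, 8, 12, 16, 24, 48),
                       nb_dispersion = 0.02,
                       housekeeping_ids = c("AT1G13320", "AT2G32170",
                                            "AT2G28390", "AT5G15710",
                                            "AT4G24550"),
                       hk_mean = 600,
                       gain = 30,
                       sf_sdlog = 0.08,
                       batch_sdlog = 0.08,
                       stress_area_multiplier = 0.70,
                       n_plants = 10L,
                       n_plants_cross = 8L,
                       tea_cv = 0.25,
                       tea_reps = 4L,
                       tea_experiments = 3L,
                       interaction_coefficients = NULL,
                       base_area_mm2 = 250,
                       plant_sdlog = 0.18,
                       repeat_sdlog = 0.06,
                       n_leaves = 12L,
                       cell_area_um2 = 1500,
                       cell_sdlog = 0.4,
                       cells_per_leaf = 100L) {
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 2L)
    stop("n_repeats must be an integer >= 2", call. = FALSE)
  if (length(time_grid_h) < 2L || any(diff(time_grid_h) <= 0))
    stop("time_grid_h must be strictly increasing", call. = FALSE)
  if (any(nb_dispersion < 0))
    stop("nb_dispersion must be >= 0", call. = FALSE)
  mults <- c(stress_area_multiplier)
  if (any(mults <= 0) || any(mults > 2))
    stop("stress_area_multiplier must lie in (0, 2]", call. = FALSE)
  if (tea_reps < 1L || tea_experiments < 1L)
    stop("tea_reps and tea_experiments must be >= 1", call. = FALSE)

  structure(list(
    n_repeats = n_repeats,
    time_grid_h = as.numeric(time_grid_h),
    nb_dispersion = nb_dispersion,
    housekeeping_ids = as.character(housekeeping_ids),
    hk_mean = hk_mean,
    gain = gain,
    sf_sdlog = sf_sdlog,
    batch_sdlog = batch_sdlog,
    stress_area_multiplier = stress_area_multiplier,
    n_plants = as.integer(n_plants),
    n_plants_cross = as.integer(n_plants_cross),
    tea_cv = tea_cv,
    tea_reps = as.integer(tea_reps),
    tea_experiments = as.integer(tea_experiments),
    interaction_coefficients = interaction_coefficients,
    base_area_mm2 = base_area_mm2,
    plant_sdlog = plant_sdlog,
    repeat_sdlog = repeat_sdlog,
    n_leaves = as.integer(n_leaves),
    cell_area_um2 = cell_area_um2,
    cell_sdlog = cell_sdlog,
    cells_per_leaf = as.integer(cells_per_leaf)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  repeats:          ", x$n_repeats, "\n")
  cat("  time grid (h):    ", paste(x$time_grid_h, collapse = ", "), "\n")
  cat("  NB dispersion:    ", x$nb_dispersion, "\n")
  cat("  housekeeping:     ", paste(x$housekeeping_ids, collapse = ", "), "\n")
  cat("  stress multiplier:", x$stress_area_multiplier, "\n")
  invisible(x)
}

# Derive a reproducible 32-bit sub-seed from a root seed and a dataset label.
# One root seed governs a whole simulated study; each dataset draws from its
# own sub-stream so that adding a dataset never shifts the others.
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483629  # prime below 2^31
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}
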