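# End-to-end convenience wrappers tying the generator to the analysis
# modules; used by the worked examples and the acceptance script.

#' Simulate a wild-type stress time-course experiment and analyse it
#'
#' Integrates control and stress dynamics, draws the count table for a
#' two-arm design over the configured time grid, normalizes against the
#' housekeeping genes and computes the per-gene-per-time differential
#' statistics.
#'
#' @param network a \code{\link{make_ground_truth}} network.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer root seed.
#' @return list: \code{counts} (\code{count_table}), \code{expr}
#'   (\code{expression_table}), \code{stats}
#'   (\code{\link{timecourse_differential}} result).
#' @export
simulate_stress_experiment <- function(network, config = sim_config(),
                                       seed = 1L) {
  grid <- config$time_grid_h
  trajs <- list(
    control = simulate_dynamics(network, stimulus = NULL, grid = grid),
    stress = simulate_dynamics(network, stimulus = list(t_on = 0),
                               grid = grid))
  design <- stress_design(config)
  counts <- simulate_nanostring(trajs, design, config, seed = seed)
  expr <- normalize_housekeeping(counts,
                                 hk_ids = config$housekeeping_ids)
  stats <- timecourse_differential(expr, genes = network$nodes)
  list(counts = counts, expr = expr, stats = stats)
}

#' Simulate one gain-of-function line experiment and estimate contrasts
#'
#' Clamps the regulator at the overexpression level (DEX induction, no
#' stress stimulus), simulates the line against the control line over the
#' GOF sampling times, normalizes, and fits the line-versus-control
#' contrasts for all other network genes.
#'
#' @param network a \code{ground_truth_network}.
#' @param regulator the clamped TF (a network node).
#' @param config a \code{\link{sim_config}}.
#' @param seed integer root seed.
#' @param times GOF sampling times (default 1, 2, 4, 8, 24 h).
#' @param clamp_level overexpression level (default: network's
#'   \code{clamp_level}).
#' @return a \code{\link{fit_line_time_model}} result for the regulator's
#'   line (targets exclude the regulator itself).
#' @export
simulate_gof_experiment <- function(network, regulator,
                                    config = sim_config(), seed = 1L,
                                    times = c(1, 2, 4, 8, 24),
                                    clamp_level = NULL) {
  if (!regulator %in% network$nodes)
    stop("unknown regulator: ", regulator, call. = FALSE)
  line <- paste0(regulator, "-GR")
  trajs <- list(
    control = simulate_dynamics(network, stimulus = NULL, grid = times),
    gof = simulate_dynamics(
      network, stimulus = NULL,
      perturbation = list(node = regulator,
                          level = if (is.null(clamp_level))
                            network$clamp_level else clamp_level),
      grid = times))
  design <- gof_design(line, times = times, n_repeats = config$n_repeats)
  counts <- simulate_nanostring(trajs, design, config,
                                seed = substream_seed(seed, line))
  expr <- normalize_housekeeping(counts, hk_ids = config$housekeeping_ids)
  fit_line_time_model(expr, line = line, regulator = regulator,
                      genes = setdiff(network$nodes, regulator))
}
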