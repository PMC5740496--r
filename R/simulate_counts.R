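# Probe-count emission: negative-binomial counts around the deterministic
# trajectories, with per-sample size factors, a per-repeat batch factor
# shared by all of that repeat's samples, and condition-independent
# housekeeping genes.

#' Simulate a NanoString-style count table from trajectories
#'
#' Counts for gene g in sample s are drawn negative binomial with mean
#' \code{gain * x_g(t_s) * sf_s * batch_r} where \code{sf_s} is a per-sample
#' log-normal size factor, \code{batch_r} a log-normal batch factor shared
#' by every sample of biological repeat r, and dispersion
#' \code{config$nb_dispersion} (0 gives Poisson). The five housekeeping
#' genes are appended with a constant expected level \code{config$hk_mean},
#' independent of line, treatment and time by construction.
#'
#' @param trajectories named list of \code{\link{simulate_dynamics}} results;
#'   names are trajectory ids referenced by \code{design$traj_id}.
#' @param design data.frame with columns \code{line}, \code{treatment},
#'   \code{time_h}, \code{repeat} and \code{traj_id}; one row per sample.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer root seed (sub-stream "nanostring").
#' @return a \code{\link{count_table}}.
#' @export
simulate_nanostring <- function(trajectories, design, config = sim_config(),
                                seed = 1L) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(design))
  need <- c("line", "treatment", "time_h", "repeat", "traj_id")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols))
    stop("design lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(design$traj_id %in% names(trajectories)))
    stop("unknown traj_id in design", call. = FALSE)

  genes <- colnames(trajectories[[1]]$states)
  all_genes <- c(genes, config$housekeeping_ids)
  n_s <- nrow(design)
  sample_ids <- sprintf("S%03d", seq_len(n_s))

  with_substream(seed, "nanostring", {
    sf <- stats::rlnorm(n_s, 0, config$sf_sdlog)
    reps <- sort(unique(design[["repeat"]]))
    batch <- stats::setNames(stats::rlnorm(length(reps), 0,
                                           config$batch_sdlog),
                             as.character(reps))
    counts <- matrix(0L, length(all_genes), n_s,
                     dimnames = list(all_genes, sample_ids))
    disp <- rep_len(config$nb_dispersion, length(all_genes))
    for (s in seq_len(n_s)) {
      tr <- trajectories[[design$traj_id[s]]]
      x <- traj_state(tr, genes, design$time_h[s])
      mu <- c(config$gain * x, rep(config$hk_mean, length(config$housekeeping_ids)))
      mu <- mu * sf[s] * batch[as.character(design[["repeat"]][s])]
      draw <- ifelse(disp > 0,
                     stats::rnbinom(length(mu), size = 1 / pmax(disp, 1e-12),
                                    mu = mu),
                     stats::rpois(length(mu), mu))
      counts[, s] <- as.integer(draw)
    }
    meta <- data.frame(sample = sample_ids, line = design$line,
                       treatment = design$treatment,
                       time_h = design$time_h, stringsAsFactors = FALSE)
    meta[["repeat"]] <- design[["repeat"]]
    count_table(counts, meta)
  })
}

#' Build a two-arm stress time-course design
#'
#' Convenience constructor for the wild-type experiment: one control and one
#' stress arm, all grid times, \code{n_repeats} repeats.
#'
#' @param config a \code{\link{sim_config}}.
#' @param line line label (default "WT").
#' @return design data.frame for \code{\link{simulate_nanostring}} with
#'   traj_id "control" / "stress".
#' @export
stress_design <- function(config = sim_config(), line = "WT") {
  grid <- expand.grid(time_h = config$time_grid_h,
                      rep = seq_len(config$n_repeats),
                      treatment = c("control", "mannitol"),
                      stringsAsFactors = FALSE)
  out <- data.frame(line = line, treatment = grid$treatment,
                    time_h = grid$time_h, stringsAsFactors = FALSE)
  out[["repeat"]] <- grid$rep
  out$traj_id <- ifelse(grid$treatment == "mannitol", "stress", "control")
  out
}

#' Build a gain-of-function (DEX clamp) design
#'
#' One overexpression line versus the control line, measured at the GOF
#' sampling times; both arms on DEX, no stress stimulus.
#'
#' @param line overexpression line label (e.g. "ERF6-GR").
#' @param control_line control line label.
#' @param times sampling times in hours.
#' @param n_repeats biological repeats.
#' @return design data.frame with traj_id "gof" / "control".
#' @export
gof_design <- function(line, control_line = "GFP-GR",
                       times = c(1, 2, 4, 8, 24), n_repeats = 3L) {
  grid <- expand.grid(time_h = times, rep = seq_len(n_repeats),
                      ln = c(line, control_line), stringsAsFactors = FALSE)
  out <- data.frame(line = grid$ln, treatment = "dex", time_h = grid$time_h,
                    stringsAsFactors = FALSE)
  out[["repeat"]] <- grid$rep
  out$traj_id <- ifelse(grid$ln == line, "gof", "control")
  out
}
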