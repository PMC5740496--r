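# Transient expression assay generator.
#
# Replicate relative activities are (1 + sum of effective weights on the
# promoter, floored at a small positive value) times log-normal noise; the
# raw table is emitted on the luminometer scale with a per-experiment batch
# level and includes the neutral control construct, so that the analysis
# side has to undo the batch effect itself.

#' Simulate transient expression assay measurements
#'
#' Single effectors act on a promoter with an effective TEA weight derived
#' from the ground-truth adjacency (\code{weight / tea_scale}); pairs act
#' with the sum of their single weights unless an explicit pair rule
#' overrides it (modelling emergent, enhanced or attenuated joint
#' regulation). The expected relative activity is
#' \code{max(floor, 1 + sum(weights))}; each replicate multiplies a
#' log-normal noise term and the experiment's batch level.
#'
#' @param network a \code{\link{make_ground_truth}} network.
#' @param effectors character vector of 1 or 2 effector TF ids, or a list of
#'   such vectors to simulate several constructs in one batch layout.
#' @param promoter reporter promoter (a network node).
#' @param config a \code{\link{sim_config}} (uses \code{tea_reps},
#'   \code{tea_experiments}, \code{tea_cv}).
#' @param seed integer root seed (sub-stream "tea").
#' @param pair_rules optional data.frame with columns \code{effector_a},
#'   \code{effector_b}, \code{promoter}, \code{pair_weight}: the joint
#'   effective weight for that pair on that promoter (order-free match).
#' @param tea_scale divisor mapping adjacency weights to TEA effect units
#'   (default 10: a weight of 20 gives a 3-fold activation).
#' @param floor lower bound of the expected relative activity (default
#'   0.05).
#' @param control_construct label of the neutral control (default "GUS").
#' @param batch_mean,batch_sdlog luminometer-scale batch level parameters.
#' @return data.frame with columns \code{effector1}, \code{effector2},
#'   \code{promoter}, \code{experiment}, \code{replicate}, \code{activity}.
#' @export
#' @examples
#' net <- make_ground_truth(seed = 1)
#' raw <- simulate_tea(net, "ERF6", "STZ", seed = 2)
#' head(raw)
simulate_tea <- function(network, effectors, promoter,
                         config = sim_config(), seed = 1L,
                         pair_rules = NULL, tea_scale = 10, floor = 0.05,
                         control_construct = "GUS",
                         batch_mean = 1000, batch_sdlog = 0.3) {
  stopifnot(inherits(network, "ground_truth_network"),
            inherits(config, "sim_config"))
  if (!is.list(effectors)) effectors <- list(effectors)
  if (!promoter %in% network$nodes)
    stop("unknown promoter: ", promoter, call. = FALSE)
  for (ef in effectors) {
    if (length(ef) < 1L || length(ef) > 2L)
      stop("each construct takes 1 or 2 effectors", call. = FALSE)
    unknown <- setdiff(ef, network$nodes)
    if (length(unknown))
      stop("unknown effector: ", unknown[1], call. = FALSE)
  }

  eff_weight <- function(ef) {
    if (length(ef) == 2L && !is.null(pair_rules)) {
      hit <- (pair_rules$promoter == promoter) &
        ((pair_rules$effector_a == ef[1] & pair_rules$effector_b == ef[2]) |
         (pair_rules$effector_a == ef[2] & pair_rules$effector_b == ef[1]))
      if (any(hit)) return(pair_rules$pair_weight[which(hit)[1]])
    }
    sum(network$adjacency[ef, promoter]) / tea_scale
  }

  with_substream(seed, paste0("tea:", promoter), {
    rows <- list()
    for (e in seq_len(config$tea_experiments)) {
      batch <- batch_mean * stats::rlnorm(1, 0, batch_sdlog)
      # neutral control replicates
      rows[[length(rows) + 1L]] <- data.frame(
        effector1 = control_construct, effector2 = NA_character_,
        promoter = promoter, experiment = e,
        replicate = seq_len(config$tea_reps),
        activity = batch * stats::rlnorm(config$tea_reps, 0, config$tea_cv),
        stringsAsFactors = FALSE)
      for (ef in effectors) {
        mu <- max(floor, 1 + eff_weight(ef))
        rows[[length(rows) + 1L]] <- data.frame(
          effector1 = ef[1],
          effector2 = if (length(ef) == 2L) ef[2] else NA_character_,
          promoter = promoter, experiment = e,
          replicate = seq_len(config$tea_reps),
          activity = batch * mu *
            stats::rlnorm(config$tea_reps, 0, config$tea_cv),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Run the single-effector TEA pipeline on simulated or imported raw data
#'
#' Convenience wrapper: batch-normalises raw activities and produces one
#' \code{\link{call_single_regulation}} per (effector, promoter) construct
#' present (single effectors only).
#'
#' @param raw TEA table (see \code{\link{relative_luminescence}}).
#' @param alpha significance level.
#' @param control_construct neutral control label.
#' @return list of \code{regulation_call}s.
#' @export
tea_single_calls <- function(raw, alpha = 0.05, control_construct = "GUS") {
  ratios <- relative_luminescence(raw, control_construct)
  e2 <- ratios$effector2
  single <- ratios[(is.na(e2) | e2 == "") &
                     ratios$effector1 != control_construct, , drop = FALSE]
  keys <- unique(single[c("effector1", "promoter")])
  lapply(seq_len(nrow(keys)), function(i) {
    means <- .experiment_means(single, keys$effector1[i], NA,
                               keys$promoter[i])
    call_single_regulation(means, alpha = alpha,
                           effector = keys$effector1[i],
                           promoter = keys$promoter[i])
  })
}
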