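# Phenotype generator: log-normal rosette areas with multiplicative
# genotype, treatment and repeat effects; leaf series decomposing each
# rosette over a fixed leaf-position profile; pavement-cell samples for
# leaf 3; and double-cross tables with a configurable log2-scale
# interaction coefficient.

# leaf-position weight profile (old -> young): mid positions carry most
# area at harvest, the youngest leaves are still small.
.leaf_profile <- function(n_leaves) {
  pos <- seq_len(n_leaves)
  w <- stats::dgamma(pos, shape = 3.2, rate = 0.55)
  w / sum(w)
}

#' Simulate plant phenotype tables
#'
#' Per-plant rosette areas are log-normal around a genotype x treatment x
#' repeat mean; the mean-of-areas equals the configured target
#' (\code{base_area_mm2 * control_mult [* stress_mult]}), so the wild type
#' loses \code{1 - stress_area_multiplier} (default 30\%) of its rosette
#' area under stress on average. Each rosette is decomposed into a leaf
#' series over a fixed leaf-position profile (rosette area = sum of leaf
#' areas, as in leaf-series measurements), and leaf 3 receives a sample of
#' \code{cells_per_leaf} pavement-cell areas whose mean ties cell number x
#' cell size to the leaf area.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genotype_effects data.frame with columns \code{genotype},
#'   \code{control_mult}, \code{stress_mult} (and optional
#'   \code{cell_area_mult}); must contain the reference genotype
#'   \code{wild_type}. Default: wild type only, with
#'   \code{stress_mult = config$stress_area_multiplier}.
#' @param seed integer root seed (sub-stream "phenotypes").
#' @param wild_type reference genotype label (default "WT").
#' @return list of class \code{phenotype_sim}: \code{plants} (genotype,
#'   treatment, repeat, plant_id, rosette_mm2), \code{leaves} (long leaf
#'   series: + leaf, leaf_mm2), \code{cells} (plant_id, leaf,
#'   cell_area_um2).
#' @export
#' @examples
#' sim <- simulate_phenotypes(seed = 1)
#' with(sim$plants, tapply(rosette_mm2, treatment, mean))
simulate_phenotypes <- function(config = sim_config(),
                                genotype_effects = NULL, seed = 1L,
                                wild_type = "WT") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genotype_effects))
    genotype_effects <- data.frame(
      genotype = wild_type, control_mult = 1,
      stress_mult = config$stress_area_multiplier,
      stringsAsFactors = FALSE)
  if (!wild_type %in% genotype_effects$genotype)
    stop("missing reference genotype: ", wild_type, call. = FALSE)
  if (any(genotype_effects$control_mult <= 0) ||
      any(genotype_effects$stress_mult <= 0))
    stop("genotype multipliers must be > 0", call. = FALSE)
  if (is.null(genotype_effects$cell_area_mult))
    genotype_effects$cell_area_mult <- 1

  prof <- .leaf_profile(config$n_leaves)
  sdl <- config$plant_sdlog

  with_substream(seed, "phenotypes", {
    plants <- list(); leaves <- list(); cells <- list()
    pid <- 0L
    for (r in seq_len(config$n_repeats)) {
      rep_eff <- stats::rlnorm(1, -config$repeat_sdlog^2 / 2,
                               config$repeat_sdlog)
      for (gi in seq_len(nrow(genotype_effects))) {
        gn <- genotype_effects$genotype[gi]
        for (tr in c("control", "mannitol")) {
          mult <- genotype_effects$control_mult[gi] *
            (if (tr == "mannitol") genotype_effects$stress_mult[gi] else 1)
          target <- config$base_area_mm2 * mult * rep_eff
          for (p in seq_len(config$n_plants)) {
            pid <- pid + 1L
            id <- sprintf("P%04d", pid)
            leaf_mm2 <- stats::rlnorm(config$n_leaves,
                                      log(target * prof) - sdl^2 / 2, sdl)
            rosette <- sum(leaf_mm2)
            pr <- data.frame(genotype = gn, treatment = tr,
                             plant_id = id, rosette_mm2 = rosette,
                             stringsAsFactors = FALSE)
            pr[["repeat"]] <- r
            plants[[length(plants) + 1L]] <- pr
            lv <- data.frame(genotype = gn, treatment = tr,
                             plant_id = id,
                             leaf = seq_len(config$n_leaves),
                             leaf_mm2 = leaf_mm2,
                             stringsAsFactors = FALSE)
            lv[["repeat"]] <- r
            leaves[[length(leaves) + 1L]] <- lv
            mca <- config$cell_area_um2 *
              genotype_effects$cell_area_mult[gi]
            cell_areas <- stats::rlnorm(
              config$cells_per_leaf,
              log(mca) - config$cell_sdlog^2 / 2, config$cell_sdlog)
            cells[[length(cells) + 1L]] <- data.frame(
              plant_id = id, leaf = 3L, cell_area_um2 = cell_areas,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    structure(list(plants = do.call(rbind, plants),
                   leaves = do.call(rbind, leaves),
                   cells = do.call(rbind, cells)),
              class = "phenotype_sim")
  })
}

#' @export
print.phenotype_sim <- function(x, ...) {
  cat("Phenotype simulation:", nrow(x$plants), "plants,",
      length(unique(x$plants$genotype)), "genotype(s),",
      length(unique(x$plants[["repeat"]])), "repeats\n")
  invisible(x)
}

#' Simulate double-cross rosette tables for the interaction test
#'
#' Generates the four design cells of one cross experiment -- reference
#' (P1 = P2 = 0), the two single crosses and the double cross -- with mean
#' log2 areas satisfying the additivity relation plus the configured
#' interaction coefficient:
#' \code{E[log2 dc] = E[log2 sc1] + E[log2 sc2] - E[log2 ref] +
#' interaction}.
#'
#' @param config a \code{\link{sim_config}} (uses \code{n_plants_cross},
#'   \code{n_repeats}, \code{plant_sdlog}, \code{repeat_sdlog},
#'   \code{base_area_mm2}).
#' @param effect1_log2,effect2_log2 single-cross effects on log2 area
#'   (e.g. -1 for a 50\% reduction).
#' @param interaction_log2 deviation from additivity on the log2 scale
#'   (0 = additive).
#' @param seed integer root seed (sub-stream "cross").
#' @return data.frame with columns \code{genotype}, \code{p1}, \code{p2},
#'   \code{repeat}, \code{plant_id}, \code{rosette_mm2}.
#' @export
simulate_cross <- function(config = sim_config(), effect1_log2 = -1,
                           effect2_log2 = -1, interaction_log2 = 0,
                           seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cells <- data.frame(
    genotype = c("ref", "sc1", "sc2", "dc"),
    p1 = c(0L, 1L, 0L, 1L), p2 = c(0L, 0L, 1L, 1L),
    mu_log2 = log2(config$base_area_mm2) +
      c(0, effect1_log2, effect2_log2,
        effect1_log2 + effect2_log2 + interaction_log2),
    stringsAsFactors = FALSE)
  sd_log2 <- config$plant_sdlog / log(2)
  with_substream(seed, "cross", {
    rows <- list()
    pid <- 0L
    for (r in seq_len(config$n_repeats)) {
      rep_eff <- stats::rnorm(1, 0, config$repeat_sdlog / log(2))
      for (i in seq_len(nrow(cells))) {
        for (p in seq_len(config$n_plants_cross)) {
          pid <- pid + 1L
          rr <- data.frame(genotype = cells$genotype[i],
                           p1 = cells$p1[i], p2 = cells$p2[i],
                           plant_id = sprintf("X%04d", pid),
                           rosette_mm2 = 2^(cells$mu_log2[i] + rep_eff +
                                              stats::rnorm(1, 0, sd_log2)),
                           stringsAsFactors = FALSE)
          rr[["repeat"]] <- r
          rows[[length(rows) + 1L]] <- rr
        }
      }
    }
    do.call(rbind, rows)
  })
}
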