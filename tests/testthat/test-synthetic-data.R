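# Generator: ground-truth networks, dynamics, counts, TEAs, phenotypes.

test_that("ground-truth construction honours structure, signs and motifs", {
  net <- make_ground_truth(seed = 1)
  expect_length(net$nodes, 20L)
  expect_equal(sum(net$hub_flag), 5L)
  expect_true(all(diag(net$adjacency) == 0))
  expect_equal(sum(net$adjacency != 0), 45L)
  # out-degree concentrated on hubs
  expect_equal(sum(net$adjacency[net$hub_flag, ] != 0), 39L)
  # repressor out-weights strictly negative
  expect_true(all(net$adjacency[net$repressor, ][
    net$adjacency[net$repressor, ] != 0] < 0))
  # at least one incoherent FFL with a delayed inhibitory arm
  ffl <- find_feedforward_loops(as_signed_network(net))
  inc <- ffl[ffl$coherence == "incoherent", ]
  expect_gt(nrow(inc), 0L)
  expect_true(all(net$onset_delay[inc$y] > net$onset_delay[inc$x]))

  # determinism: same (config, seed) -> identical networks
  expect_identical(make_ground_truth(seed = 7), make_ground_truth(seed = 7))
  expect_false(identical(make_ground_truth(seed = 7)$adjacency,
                         make_ground_truth(seed = 8)$adjacency))

  # zero repressors: all weights positive, every FFL coherent
  net0 <- make_ground_truth(seed = 3, n_nodes = 10, n_hubs = 3,
                            require_iffl = FALSE, n_repressors = 0)
  expect_true(all(net0$adjacency >= 0))
  ffl0 <- find_feedforward_loops(as_signed_network(net0))
  if (nrow(ffl0)) expect_true(all(ffl0$coherence == "coherent"))

  # impossible motif request
  expect_error(make_ground_truth(seed = 1, n_nodes = 10, n_hubs = 3,
                                 require_iffl = TRUE, n_repressors = 0),
               "repressor")
  expect_error(make_ground_truth(seed = 1, n_nodes = 2), "n_nodes")
})

test_that("dynamics reproduce fixed points, closed forms and clamps", {
  # single unregulated node at its fixed point stays put without stimulus
  net <- make_ground_truth(seed = 5, n_nodes = 3, n_hubs = 1,
                           require_iffl = FALSE, n_repressors = 0)
  net$adjacency[] <- 0
  tr0 <- simulate_dynamics(net, stimulus = NULL, grid = c(1, 5, 20))
  expect_equal(tr0$states,
               matrix(rep(net$basal / net$decay, each = 3), 3,
                      dimnames = dimnames(tr0$states)),
               tolerance = 1e-9)

  # step increase A in production matches basal/d + (A/d)(1 - e^(-dt))
  net$onset_delay[] <- 0
  A <- 80
  net$stim_weight[] <- A
  grid <- seq(0.2, 10, by = 0.2)
  tr <- simulate_dynamics(net, stimulus = list(t_on = 0), grid = grid)
  d <- net$decay[1]
  expected <- net$basal[1] / d + (A / d) * (1 - exp(-d * grid))
  expect_lt(max(abs(tr$states[, 1] - expected) / expected), 1e-3)

  # clamped node constant at clamp level for all t > 0
  netb <- make_ground_truth(seed = 1)
  trc <- simulate_dynamics(netb, stimulus = NULL,
                           perturbation = list(node = "ERF6", level = 250),
                           grid = c(0.5, 2, 8, 24))
  expect_true(all(trc$states[, "ERF6"] == 250))
  expect_error(simulate_dynamics(netb, perturbation = list(node = "nope"),
                                 grid = 1), "node")
})

test_that("count emission matches NB moments, housekeeping contract, determinism", {
  cfg <- sim_config(nb_dispersion = 0, sf_sdlog = 0, batch_sdlog = 0)
  lv <- c(g1 = 20, g2 = 60)
  trajs <- list(control = const_traj(lv), stress = const_traj(lv * 2))
  design <- data.frame(line = "WT",
                       treatment = rep(c("control", "mannitol"), each = 2),
                       time_h = 1, stringsAsFactors = FALSE)
  design[["repeat"]] <- rep(1:2, 2)
  design$traj_id <- rep(c("control", "stress"), each = 2)

  # dispersion -> 0, unit size factors: empirical mean over many draws
  # within 2% of gain * level
  big <- design[rep(1, 2500), ]   # 2500 control samples of gene g1/g2
  ct <- simulate_nanostring(trajs, big, cfg, seed = 11)
  mu_hat <- rowMeans(ct$counts[c("g1", "g2"), ])
  expect_lt(abs(mu_hat[["g1"]] - cfg$gain * 20) / (cfg$gain * 20), 0.02)
  expect_lt(abs(mu_hat[["g2"]] - cfg$gain * 60) / (cfg$gain * 60), 0.02)

  # housekeeping level recovered within Monte-Carlo tolerance
  hk_means <- rowMeans(ct$counts[cfg$housekeeping_ids, , drop = FALSE])
  expect_true(all(abs(hk_means - cfg$hk_mean) / cfg$hk_mean < 0.02))

  # identical seed -> identical table; different seed differs
  c1 <- simulate_nanostring(trajs, design, sim_config(), seed = 5)
  c2 <- simulate_nanostring(trajs, design, sim_config(), seed = 5)
  c3 <- simulate_nanostring(trajs, design, sim_config(), seed = 6)
  expect_identical(c1, c2)
  expect_false(identical(c1$counts, c3$counts))

  # sampling outside the trajectory span errors
  bad <- design; bad$time_h <- 99
  expect_error(simulate_nanostring(trajs, bad, cfg, seed = 1),
               "outside trajectory span")
})

test_that("housekeeping counts are condition-independent by construction", {
  cfg <- sim_config(nb_dispersion = 0, sf_sdlog = 0, batch_sdlog = 0)
  lv <- c(g1 = 20)
  trajs <- list(control = const_traj(lv), stress = const_traj(lv * 8))
  design <- data.frame(line = "WT",
                       treatment = rep(c("control", "mannitol"), each = 400),
                       time_h = 1, stringsAsFactors = FALSE)
  design[["repeat"]] <- 1L
  design$traj_id <- rep(c("control", "stress"), each = 400)
  ct <- simulate_nanostring(trajs, design, cfg, seed = 2)
  hk <- ct$counts[cfg$housekeeping_ids[1], ]
  byarm <- tapply(hk, ct$meta$treatment, mean)
  expect_lt(abs(byarm[["control"]] - byarm[["mannitol"]]) / cfg$hk_mean,
            0.05)
})

test_that("TEA generator: null, positive-weight and emergent-pair behaviour", {
  cfg <- sim_config()
  net <- make_ground_truth(seed = 1)

  # zero-weight effector -> mean ratio about 1
  expect_equal(net$adjacency["WRKY30", "STZ"], 0)
  means <- sapply(1:60, function(s) {
    raw <- simulate_tea(net, "WRKY30", "STZ", cfg, seed = s)
    r <- relative_luminescence(raw)
    mean(r$ratio[r$effector1 == "WRKY30"])
  })
  expect_lt(abs(mean(means) - 1), 0.05)

  # positive-weight effector -> mean ratio > 1 in >= 95% of seeded runs
  pos <- sapply(1:100, function(s) {
    raw <- simulate_tea(net, "ERF6", "STZ", cfg, seed = s)
    r <- relative_luminescence(raw)
    mean(r$ratio[r$effector1 == "ERF6"]) > 1
  })
  expect_gte(mean(pos), 0.95)

  # emergent pair: both singles ~1, pair significantly > 1
  netz <- net
  netz$adjacency["WRKY48", "ERF6"] <- 0
  netz$adjacency["ERF9", "ERF6"] <- 0
  pr <- data.frame(effector_a = "WRKY48", effector_b = "ERF9",
                   promoter = "ERF6", pair_weight = 15)
  raw <- simulate_tea(netz, list("WRKY48", "ERF9", c("WRKY48", "ERF9")),
                      "ERF6", cfg, seed = 9, pair_rules = pr)
  ratios <- relative_luminescence(raw)
  singles <- tea_single_calls(raw)
  verdicts <- sapply(singles, `[[`, "verdict")
  expect_true(all(verdicts == "none"))
  pair_rows <- ratios[!is.na(ratios$effector2), ]
  pm <- tapply(pair_rows$ratio, pair_rows$experiment, mean)
  pc <- call_single_regulation(pm, effector = "WRKY48+ERF9",
                               promoter = "ERF6")
  expect_equal(pc$verdict, "activation")

  expect_error(simulate_tea(net, "ERF6", "NOPE", cfg, seed = 1),
               "unknown promoter")
  expect_error(simulate_tea(net, "NOPE", "ERF6", cfg, seed = 1),
               "unknown effector")
})

test_that("phenotype generator plants the stress reduction and additivity", {
  cfg <- sim_config()
  # wild-type default: estimated reduction about 30%
  reds <- sapply(1:30, function(s) {
    sim <- simulate_phenotypes(cfg, seed = s)
    m <- tapply(sim$plants$rosette_mm2, sim$plants$treatment, mean)
    1 - m[["mannitol"]] / m[["control"]]
  })
  se <- sd(reds) / sqrt(length(reds))
  expect_lt(abs(mean(reds) - 0.30), 3 * se + 0.01)

  # genotype identical to wild type -> relative reduction about 1
  ge <- data.frame(genotype = c("WT", "twin"), control_mult = 1,
                   stress_mult = cfg$stress_area_multiplier,
                   stringsAsFactors = FALSE)
  rr <- sapply(1:30, function(s) {
    sim <- simulate_phenotypes(cfg, ge, seed = 100 + s)
    relative_reduction(sim$plants[sim$plants$genotype == "twin", ],
                       sim$plants[sim$plants$genotype == "WT", ])
  })
  expect_lt(abs(mean(rr) - 1), 3 * sd(rr) / sqrt(length(rr)) + 0.02)

  # leaf areas sum to the rosette by construction
  sim <- simulate_phenotypes(cfg, seed = 3)
  sums <- tapply(sim$leaves$leaf_mm2, sim$leaves$plant_id, sum)
  expect_equal(as.numeric(sums[sim$plants$plant_id]),
               sim$plants$rosette_mm2)
  # cell samples: ~100 cells per leaf 3
  expect_true(all(table(sim$cells$plant_id) == cfg$cells_per_leaf))

  # interaction coefficient 0 -> double-cross log2 mean additive within SE
  cr <- simulate_cross(cfg, -0.8, -0.6, interaction_log2 = 0, seed = 4)
  mu <- tapply(log2(cr$rosette_mm2), cr$genotype, mean)
  dev <- mu[["dc"]] - mu[["sc1"]] - mu[["sc2"]] + mu[["ref"]]
  it <- interaction_test(cr)
  expect_lt(abs(dev), 3 * it$se)

  expect_error(simulate_phenotypes(cfg, data.frame(
    genotype = "mutant", control_mult = 1, stress_mult = 0.7)),
    "missing reference genotype")

  # determinism of the phenotype stream
  expect_identical(simulate_phenotypes(cfg, seed = 12),
                   simulate_phenotypes(cfg, seed = 12))
})

test_that("ground truth JSON export round-trips", {
  net <- make_ground_truth(seed = 2)
  f <- tempfile(fileext = ".json")
  write_ground_truth(net, f)
  back <- read_ground_truth(f)
  expect_equal(back$adjacency, net$adjacency)
  expect_equal(back$hub_flag, net$hub_flag)
  expect_equal(back$onset_delay, net$onset_delay)
  unlink(f)
})
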