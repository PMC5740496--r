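# GOF contrast model, edge calling, affected fraction, edge union.

# build an expression table for line/control x times x repeats from a
# generator function value(line, t, r) (single gene "g")
gof_expr <- function(value, times = c(1, 2), n_rep = 2,
                     lines = c("GFP-GR", "X-GR")) {
  cols <- list(); meta <- list(); k <- 0L
  for (ln in lines) for (t in times) for (r in seq_len(n_rep)) {
    k <- k + 1L
    id <- sprintf("s%03d", k)
    cols[[id]] <- matrix(value(ln, t, r), 1, dimnames = list("g", NULL))
    meta[[k]] <- data.frame(sample = id, line = ln, treatment = "dex",
                            time_h = t, stringsAsFactors = FALSE)
    meta[[k]][["repeat"]] <- r
  }
  log2m <- do.call(cbind, cols)
  colnames(log2m) <- names(cols)
  structure(list(log2 = log2m,
                 size_factors = rep(1, k), pseudocount = 0,
                 meta = do.call(rbind, meta)),
            class = "expression_table")
}

test_that("balanced contrasts equal cell-mean differences; block absorbs shifts", {
  cellmean <- function(ln, t) 2 + (ln == "X-GR") * (t == 2) * 1.5 +
    0.3 * (t == 2)
  expr <- gof_expr(function(ln, t, r) cellmean(ln, t) + 0.1 * r)
  est <- fit_line_time_model(expr, "X-GR", genes = "g")
  expect_equal(est$estimate[est$time_h == 1], 0, tolerance = 1e-10)
  expect_equal(est$estimate[est$time_h == 2], 1.5, tolerance = 1e-10)

  # adding a constant to every sample of one repeat leaves estimates intact
  expr2 <- expr
  shift_cols <- expr2$meta$sample[expr2$meta[["repeat"]] == 2]
  expr2$log2[, shift_cols] <- expr2$log2[, shift_cols] + 5
  est2 <- fit_line_time_model(expr2, "X-GR", genes = "g")
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-10)
  expect_equal(est2$p, est$p, tolerance = 1e-8)
})

test_that("coefficients match a brute-force normal-equations solve", {
  set.seed(42)
  expr <- gof_expr(function(ln, t, r)
    1 + 0.5 * (ln == "X-GR") + 0.2 * t + 0.1 * r + rnorm(1, 0, 0.3))
  est <- fit_line_time_model(expr, "X-GR", genes = "g")

  # oracle: explicit design matrix and solve(t(X) %*% X) %*% t(X) %*% y
  meta <- expr$meta
  f_line <- factor(meta$line, levels = c("GFP-GR", "X-GR"))
  f_time <- factor(meta$time_h)
  f_rep <- factor(meta[["repeat"]])
  X <- model.matrix(~ f_rep + f_line * f_time)
  y <- expr$log2["g", meta$sample]
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  # contrast at t = 2: line main effect + interaction
  expect_equal(est$estimate[est$time_h == 2],
               unname(beta["f_lineX-GR", 1] +
                        beta["f_lineX-GR:f_time2", 1]),
               tolerance = 1e-8)
  expect_equal(est$estimate[est$time_h == 1],
               unname(beta["f_lineX-GR", 1]), tolerance = 1e-8)

  # missing cell -> rank-deficiency error
  expr3 <- expr
  drop <- expr3$meta$line == "X-GR" & expr3$meta$time_h == 2
  expr3$meta <- expr3$meta[!drop, ]
  expr3$log2 <- expr3$log2[, expr3$meta$sample, drop = FALSE]
  expect_error(fit_line_time_model(expr3, "X-GR", genes = "g"),
               "rank-deficient|fewer than 2")
})

test_that("edge calling thresholds, self-edge exclusion and monotonicity", {
  est <- data.frame(regulator = "ERF6",
                    target = c("STZ", "ZAT6", "ERF6", "MYB51"),
                    time_h = 2,
                    estimate = c(1.2, -0.8, 3.0, 0.4),
                    se = 0.2, p = c(0.001, 0.01, 0.001, 0.2),
                    q = c(0.05, 0.2, 0.001, 0.4),
                    stringsAsFactors = FALSE)
  net <- call_edges(est, fdr_threshold = 0.1)
  expect_equal(net$target, "STZ")        # q = 0.05 called, 0.2 not
  expect_equal(net$sign, 1)
  expect_false("ERF6" %in% net$target)   # never its own target

  # lowering the threshold never adds edges
  for (thr in c(0.2, 0.1, 0.05, 0.01)) {
    lo <- call_edges(est, fdr_threshold = thr / 2)
    hi <- call_edges(est, fdr_threshold = thr)
    expect_true(all(paste(lo$target, lo$time_h) %in%
                      paste(hi$target, hi$time_h)))
  }
})

test_that("affected fraction counts targets above |log2FC| threshold", {
  est <- data.frame(regulator = "R",
                    target = rep(paste0("t", 1:5), each = 2),
                    time_h = rep(c(1, 2), 5),
                    estimate = c(1.2, 0.1,  -1.4, 0,  0.5, 0.9,
                                 0.2, 1.01, 0.3, 0.4),
                    se = 0.1, p = 0.5, q = 0.5, stringsAsFactors = FALSE)
  expect_equal(unname(affected_fraction(est)), 0.6)
  est$estimate <- rep(2, 10)
  expect_equal(unname(affected_fraction(est)), 1.0)
  est$estimate <- rep(0.2, 10)
  expect_equal(unname(affected_fraction(est)), 0.0)
})

test_that("edge union deduplicates and keeps the earliest significant sign", {
  dyn <- data.frame(
    regulator = c("A", "A", "A", "B"),
    target = c("X", "X", "Y", "Z"),
    time_h = c(1, 4, 2, 1),
    log2fc = c(1.5, -2, 0.9, 1.1),
    q = c(0.05, 0.01, 0.02, 0.03),
    sign = c(1, -1, 1, 1), stringsAsFactors = FALSE)
  class(dyn) <- c("dynamic_network", "data.frame")
  un <- union_edges(dyn, times = c(1, 2, 4))
  expect_equal(nrow(un), 3L)                    # A->X deduplicated
  expect_equal(un$sign[un$regulator == "A" & un$target == "X"], 1)
  expect_equal(un$first_time_h[un$regulator == "A" & un$target == "X"], 1)
  # disjoint edges at different times are both retained
  expect_setequal(paste(un$regulator, un$target),
                  c("A X", "A Y", "B Z"))
})

test_that("null simulations are calibrated and strong effects are recovered", {
  cfg <- sim_config()
  # calibration: control vs relabelled control, 500 single-gene runs
  trajs <- list(control = const_traj(c(g = 30), times = c(1, 2)),
                gof = const_traj(c(g = 30), times = c(1, 2)))
  d <- gof_design("X-GR", times = c(1, 2))
  hits <- vapply(1:500, function(s) {
    ct <- simulate_nanostring(trajs, d, cfg, seed = s)
    expr <- normalize_housekeeping(ct)
    est <- fit_line_time_model(expr, "X-GR", genes = "g")
    est$p[1] < 0.05
  }, logical(1))
  mc2 <- 2 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(hits) - 0.05), mc2 + 0.005)

  # recovery: strong planted weights, default noise, 3 repeats
  net <- make_ground_truth(seed = 1, weight_range = c(40, 60))
  regs <- names(which(rowSums(net$adjacency != 0) > 0))
  ests <- lapply(regs, function(r)
    simulate_gof_experiment(net, r, cfg, seed = 99))
  un <- union_edges(call_edges(ests, 0.1), times = c(1, 2, 4))
  truth <- paste(net$nodes[which(net$adjacency != 0, arr.ind = TRUE)[, 1]],
                 net$nodes[which(net$adjacency != 0, arr.ind = TRUE)[, 2]])
  called <- paste(un$regulator, un$target)
  tp <- sum(called %in% truth)
  expect_gte(tp / length(called), 0.8)   # precision
  expect_gte(tp / length(truth), 0.8)    # recall

  # union recall is at least each per-time recall
  dyn <- call_edges(ests, 0.1)
  rec_t <- sapply(c(1, 2, 4), function(t) {
    sub <- dyn[dyn$time_h == t, ]
    sum(paste(sub$regulator, sub$target) %in% truth) / length(truth)
  })
  expect_true(all(tp / length(truth) >= rec_t))
})

test_that("a planted incoherent FFL produces a rise-then-fall target series", {
  # X -> Z (+, fast), X -> Y (+), Y -| Z (strong, delayed by Y's build-up)
  nodes <- c("X", "Y", "Z")
  adj <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  adj["X", "Z"] <- 50; adj["X", "Y"] <- 50; adj["Y", "Z"] <- -80
  net <- structure(list(
    nodes = nodes, adjacency = adj,
    hub_flag = setNames(c(TRUE, FALSE, FALSE), nodes),
    repressor = setNames(c(FALSE, TRUE, FALSE), nodes),
    onset_delay = setNames(c(0.45, 1.3, 0.45), nodes),
    onset_group = setNames(c(1L, 3L, 1L), nodes),
    basal = setNames(c(10, 2, 10), nodes),     # repressor low at baseline
    decay = setNames(c(1, 0.25, 1), nodes),    # and slow to accumulate
    hill_k = 100, hill_n = 2,
    stim_weight = setNames(rep(80, 3), nodes),
    clamp_level = 250, seed = 1L), class = "ground_truth_network")
  grid <- c(0.5, 1, 2, 4, 8, 24)
  ctrl <- simulate_dynamics(net, NULL, grid = grid)
  gof <- simulate_dynamics(net, NULL,
                           perturbation = list(node = "X", level = 250),
                           grid = grid)
  lfc <- log2(gof$states[, "Z"] / ctrl$states[, "Z"])
  peak <- which.max(lfc)
  expect_gt(lfc[peak], 1)                    # clear early induction
  expect_gt(peak, 1)                         # rises to an interior peak
  expect_lt(peak, length(lfc))               # then falls again
  expect_lt(lfc[length(lfc)], lfc[peak] - 0.5)
})
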