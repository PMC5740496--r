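# Rosette / leaf / cell growth statistics, stress-sensitivity
# normalization, and the log2-additivity genetic-interaction test.

#' Two-way rosette growth model with repeat block
#'
#' Linear model on log2 rosette area with fixed effects genotype, treatment,
#' their interaction and repeat as a categorical block; reports the line
#' effect versus the wild type per treatment (as a percent difference of
#' modelled means), the interaction term, and Tukey studentized-range
#' adjusted pairwise comparisons of the four genotype x treatment cells.
#'
#' @param records data.frame with columns \code{genotype},
#'   \code{treatment}, \code{repeat}, \code{rosette_mm2}.
#' @param line genotype of interest.
#' @param wild_type reference genotype.
#' @return list of class \code{rosette_fit}: \code{effects} (per-treatment
#'   percent effect), \code{interaction} (estimate on log2 scale, se, p),
#'   \code{tukey} data.frame of pairwise cell comparisons.
#' @export
rosette_growth_test <- function(records, line, wild_type = "WT") {
  need <- c("genotype", "treatment", "repeat", "rosette_mm2")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  sub <- records[records$genotype %in% c(line, wild_type), , drop = FALSE]
  tab <- table(sub$genotype, sub$treatment)
  if (length(tab) < 4L || any(tab == 0))
    stop("empty genotype x treatment cell", call. = FALSE)
  if (length(unique(sub[["repeat"]])) < 2L)
    stop("need >= 2 repeats", call. = FALSE)

  g <- factor(sub$genotype, levels = c(wild_type, line))
  tr <- factor(sub$treatment)
  rp <- factor(sub[["repeat"]])
  y <- log2(sub$rosette_mm2)
  fit <- stats::lm(y ~ rp + g * tr)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  df_res <- fit$df.residual
  s2 <- sum(stats::residuals(fit)^2) / df_res

  treatments <- levels(tr)
  contrast_row <- function(gn, tn) {
    nd <- data.frame(rp = factor(levels(rp)[1], levels = levels(rp)),
                     g = factor(gn, levels = levels(g)),
                     tr = factor(tn, levels = levels(tr)))
    stats::model.matrix(~ rp + g * tr, nd)[1, ]
  }
  effects <- lapply(treatments, function(tn) {
    cvec <- contrast_row(line, tn) - contrast_row(wild_type, tn)
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    list(treatment = tn, log2_effect = est, percent = (2^est - 1) * 100,
         se = se, p = 2 * stats::pt(-abs(tval), df_res))
  })
  names(effects) <- treatments

  ia <- grep(":", names(cf), value = TRUE)
  interaction <- list(estimate = unname(cf[ia[1]]),
                      se = sqrt(V[ia[1], ia[1]]),
                      p = 2 * stats::pt(-abs(cf[ia[1]] /
                                               sqrt(V[ia[1], ia[1]])),
                                        df_res))

  # Tukey studentized-range comparisons among the 4 cell means
  cells <- expand.grid(g = levels(g), tr = levels(tr),
                       stringsAsFactors = FALSE)
  cell_rows <- lapply(seq_len(nrow(cells)),
                      function(i) contrast_row(cells$g[i], cells$tr[i]))
  cell_n <- mapply(function(gn, tn) sum(sub$genotype == gn &
                                          sub$treatment == tn),
                   cells$g, cells$tr)
  k <- nrow(cells)
  comp <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      cvec <- cell_rows[[i]] - cell_rows[[j]]
      est <- sum(cvec * cf)
      se_tk <- sqrt(s2 / 2 * (1 / cell_n[i] + 1 / cell_n[j]))
      q <- abs(est) / se_tk
      comp[[length(comp) + 1L]] <- data.frame(
        cell_a = paste(cells$g[i], cells$tr[i], sep = "."),
        cell_b = paste(cells$g[j], cells$tr[j], sep = "."),
        diff_log2 = est,
        p_tukey = stats::ptukey(q, k, df_res, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(effects = effects, interaction = interaction,
                 tukey = do.call(rbind, comp), fit = fit),
            class = "rosette_fit")
}

#' @export
print.rosette_fit <- function(x, ...) {
  cat("Rosette growth model (log2 area ~ repeat + genotype * treatment)\n")
  for (e in x$effects)
    cat(sprintf("  %-10s line effect %+.1f%% (p = %.3g)\n",
                e$treatment, e$percent, e$p))
  cat(sprintf("  interaction %.3f log2 units (p = %.3g)\n",
              x$interaction$estimate, x$interaction$p))
  invisible(x)
}

#' Stress-sensitivity relative to the wild type
#'
#' The line's stress-induced area reduction divided by the wild type's:
#' \code{(1 - mean(line, stress)/mean(line, control)) /
#' (1 - mean(wt, stress)/mean(wt, control))}. The wild type scores 1 by
#' construction; a line losing 60\% where the wild type loses 30\% scores 2.
#'
#' @param line_records,wt_records data.frames with \code{treatment} and
#'   \code{rosette_mm2} (\code{control} and \code{mannitol} rows each).
#' @param stress_treatment,control_treatment treatment labels.
#' @return scalar relative reduction.
#' @export
#' @examples
#' wt <- data.frame(treatment = c("control", "mannitol"),
#'                  rosette_mm2 = c(100, 70))
#' ln <- data.frame(treatment = c("control", "mannitol"),
#'                  rosette_mm2 = c(100, 40))
#' relative_reduction(ln, wt)   # 2
relative_reduction <- function(line_records, wt_records,
                               stress_treatment = "mannitol",
                               control_treatment = "control") {
  m <- function(df, tr) {
    v <- df$rosette_mm2[df$treatment == tr]
    if (!length(v)) stop("empty genotype x treatment cell", call. = FALSE)
    mean(v)
  }
  wt_red <- 1 - m(wt_records, stress_treatment) /
    m(wt_records, control_treatment)
  if (wt_red <= 0)
    stop("wild-type reduction <= 0: relative reduction undefined",
         call. = FALSE)
  line_red <- 1 - m(line_records, stress_treatment) /
    m(line_records, control_treatment)
  line_red / wt_red
}

#' Per-leaf genotype contrasts with Monte-Carlo Dunnett-type adjustment
#'
#' At each leaf position, a fixed-block linear model on log2 leaf area
#' (\code{~ repeat + genotype}) contrasts every test genotype against the
#' wild type. Family-wise adjustment across genotypes at each leaf uses a
#' seeded Monte-Carlo max-|t| null (multivariate t with the contrast
#' correlation), the same construction as Dunnett's test.
#'
#' @param records data.frame with \code{genotype}, \code{repeat},
#'   \code{leaf} (position, old to young), \code{leaf_mm2}.
#' @param lines test genotype(s).
#' @param wild_type reference genotype.
#' @param n_mc Monte-Carlo draws for the max-|t| null (default 4000).
#' @param mc_seed seed of the adjustment draws (fixed for reproducibility).
#' @return data.frame: \code{leaf}, \code{genotype}, \code{estimate} (log2),
#'   \code{se}, \code{p}, \code{p_adj}. Leaves missing in a genotype are
#'   skipped with a warning.
#' @export
leaf_series_compare <- function(records, lines, wild_type = "WT",
                                n_mc = 4000L, mc_seed = 20171221L) {
  need <- c("genotype", "repeat", "leaf", "leaf_mm2")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  leaves <- sort(unique(records$leaf))
  out <- list()
  for (lf in leaves) {
    sub <- records[records$leaf == lf &
                     records$genotype %in% c(lines, wild_type), ,
                   drop = FALSE]
    have <- unique(sub$genotype)
    miss <- setdiff(c(lines, wild_type), have)
    if (length(miss)) {
      warning("leaf ", lf, " missing genotype(s): ",
              paste(miss, collapse = ", "), "; skipped")
      next
    }
    g <- factor(sub$genotype, levels = c(wild_type, lines))
    rp <- factor(sub[["repeat"]])
    y <- log2(sub$leaf_mm2)
    fit <- stats::lm(y ~ rp + g)
    cf <- stats::coef(fit); V <- stats::vcov(fit)
    idx <- grep("^g", names(cf))
    est <- cf[idx]; Vg <- V[idx, idx, drop = FALSE]
    se <- sqrt(diag(Vg))
    tval <- est / se
    df_res <- fit$df.residual
    p <- 2 * stats::pt(-abs(tval), df_res)
    # MC max-|t| null: z ~ MVN(0, corr), scaled by a shared chi draw
    corr <- Vg / tcrossprod(se)
    L <- chol(corr)
    p_adj <- with_substream(mc_seed, paste0("leaf", lf), {
      z <- matrix(stats::rnorm(n_mc * length(est)), n_mc) %*% L
      sc <- sqrt(stats::rchisq(n_mc, df_res) / df_res)
      maxt <- apply(abs(z / sc), 1, max)
      vapply(abs(tval), function(tt) mean(maxt >= tt), 0)
    })
    p_adj <- pmax(p_adj, p)   # FWE adjustment never below raw p
    out[[length(out) + 1L]] <- data.frame(
      leaf = lf, genotype = sub("^g", "", names(cf)[idx]),
      estimate = unname(est), se = unname(se), p = unname(p),
      p_adj = unname(p_adj), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Decompose leaf area into cell number and cell size
#'
#' Estimated pavement cell number = leaf area / mean cell area, with units
#' converted (leaf in mm^2, cells in micrometre^2 by default). Optionally
#' compares two genotypes' samples on the log scale.
#'
#' @param leaf_area leaf area of the measured leaf.
#' @param cell_area_sample vector of sampled cell areas (>= 30 cells).
#' @param leaf_unit,cell_unit "mm2" or "um2"; differing units require the
#'   built-in conversion (1 mm^2 = 1e6 um^2).
#' @return list: \code{mean_cell_area_um2}, \code{cell_number}, \code{n_cells_sampled}.
#' @export
#' @examples
#' cellular_decomposition(40, rep(1600, 100))$cell_number   # 25000
cellular_decomposition <- function(leaf_area, cell_area_sample,
                                   leaf_unit = "mm2", cell_unit = "um2") {
  if (length(cell_area_sample) < 30L)
    stop("need >= 30 sampled cells", call. = FALSE)
  units <- c(mm2 = 1e6, um2 = 1)    # to um^2
  if (!leaf_unit %in% names(units) || !cell_unit %in% names(units))
    stop("unit mismatch: units must be mm2 or um2", call. = FALSE)
  leaf_um2 <- leaf_area * units[[leaf_unit]]
  mca <- mean(cell_area_sample) * units[[cell_unit]]
  list(mean_cell_area_um2 = mca,
       cell_number = leaf_um2 / mca,
       n_cells_sampled = length(cell_area_sample))
}

#' Compare cellular phenotypes of two genotypes on the log scale
#'
#' Welch t tests on log2 cell number and log2 mean cell area across plants.
#'
#' @param decomp_a,decomp_b lists of \code{\link{cellular_decomposition}}
#'   results (one per plant) for the two genotypes.
#' @return data.frame with rows cell_number and cell_area: log2 ratio
#'   (a vs b) and p value.
#' @export
compare_cellular <- function(decomp_a, decomp_b) {
  get <- function(lst, f) vapply(lst, function(d) log2(d[[f]]), 0)
  rows <- lapply(c(cell_number = "cell_number",
                   cell_area = "mean_cell_area_um2"), function(f) {
    a <- get(decomp_a, f); b <- get(decomp_b, f)
    p <- if (stats::sd(c(a, b)) == 0 || (stats::sd(a) == 0 &&
                                         stats::sd(b) == 0)) {
      if (abs(mean(a) - mean(b)) < .Machine$double.eps^0.5) 1 else 0
    } else stats::t.test(a, b)$p.value
    data.frame(log2_ratio = mean(a) - mean(b), p = p)
  })
  out <- do.call(rbind, rows)
  out$quantity <- names(rows)
  out[c("quantity", "log2_ratio", "p")]
}

#' Genetic-interaction (log2-additivity) test for double crosses
#'
#' Linear model on log2 rosette area with dummy indicators P1, P2 (presence
#' of each parental transgene), their interaction, and repeat as a block.
#' Under additivity E[log2 RA_dc] = E[log2 RA_sc1] + E[log2 RA_sc2] -
#' E[log2 RA_ref], so the interaction coefficient directly measures the
#' deviation from additivity: synergistic when positive (p < alpha),
#' negative when negative (p < alpha), additive otherwise.
#'
#' @param cross_records data.frame with columns \code{p1}, \code{p2} (0/1),
#'   \code{repeat}, \code{rosette_mm2}; all four design cells present with
#'   >= 2 plants each.
#' @param alpha significance level (default 0.05).
#' @return object of class \code{interaction_result}: \code{coefficient}
#'   (log2 scale), \code{se}, \code{p}, \code{classification}.
#' @export
interaction_test <- function(cross_records, alpha = 0.05) {
  need <- c("p1", "p2", "repeat", "rosette_mm2")
  stopifnot(is.data.frame(cross_records),
            all(need %in% names(cross_records)))
  cells <- table(cross_records$p1, cross_records$p2)
  if (length(cells) < 4L || any(cells < 2L))
    stop("missing design cell: all four P1 x P2 cells need >= 2 plants",
         call. = FALSE)
  y <- log2(cross_records$rosette_mm2)
  p1 <- cross_records$p1; p2 <- cross_records$p2
  rp <- factor(cross_records[["repeat"]])
  fit <- if (nlevels(rp) > 1L) stats::lm(y ~ rp + p1 * p2)
         else stats::lm(y ~ p1 * p2)
  cf <- stats::coef(fit)
  se <- sqrt(stats::vcov(fit)["p1:p2", "p1:p2"])
  est <- unname(cf["p1:p2"])
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), fit$df.residual)
  classification <- if (p < alpha && est > 0) "synergistic"
                    else if (p < alpha && est < 0) "negative"
                    else "additive"
  structure(list(coefficient = est, se = se, p = p,
                 classification = classification, fit = fit),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "Genetic interaction: %.3f log2 units (se %.3f, p = %.3g) -> %s\n",
    x$coefficient, x$se, x$p, x$classification))
  invisible(x)
}

#' Expected double-cross reduction under additivity
#'
#' On the multiplicative (log-additive) model, two single-cross reductions
#' r1 and r2 combine to \code{1 - (1 - r1) * (1 - r2)}: two 50\% reductions
#' predict a 75\% double reduction.
#'
#' @param r1,r2 single-cross reductions, each in [0, 1).
#' @return expected double-cross reduction.
#' @export
#' @examples
#' expected_double_reduction(0.5, 0.5)   # 0.75
expected_double_reduction <- function(r1, r2) {
  if (any(c(r1, r2) < 0) || any(c(r1, r2) >= 1))
    stop("reductions must lie in [0, 1)", call. = FALSE)
  1 - (1 - r1) * (1 - r2)
}
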