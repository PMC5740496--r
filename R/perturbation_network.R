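# Edge calling from inducible-overexpression (GOF) time courses.
#
# Per target gene: fixed-effect linear model on log2 normalized values with
# repeat as a categorical block and line, time and their interaction as
# fixed effects; Wald contrasts line - control at each time; BH adjustment
# over the whole per-line family (all targets x all times). Edges are called
# at FDR < 0.1 with provisional sign = sign of the contrast estimate.

#' Fit per-gene line-versus-control contrasts over time
#'
#' @param expr an \code{\link{expression_table}} containing the
#'   overexpression line and the control line.
#' @param line overexpression line label (sample metadata \code{line}).
#' @param control_line control line label.
#' @param times time points at which contrasts are estimated; default all
#'   shared times.
#' @param regulator the TF overexpressed in \code{line}; defaults to the
#'   part of \code{line} before "-GR". Used to label edges.
#' @param genes target genes (default all rows of \code{expr}).
#' @return data.frame of class \code{line_time_estimates}: \code{regulator},
#'   \code{target}, \code{time_h}, \code{estimate} (log2 line - control),
#'   \code{se}, \code{p}, \code{q}.
#' @export
fit_line_time_model <- function(expr, line, control_line = "GFP-GR",
                                times = NULL, regulator = NULL,
                                genes = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  meta <- expr$meta
  keep <- meta$line %in% c(line, control_line)
  meta <- meta[keep, , drop = FALSE]
  if (is.null(times)) times <- sort(unique(meta$time_h))
  meta <- meta[meta$time_h %in% times, , drop = FALSE]
  if (is.null(regulator)) regulator <- sub("-GR$", "", line)
  if (is.null(genes)) genes <- rownames(expr$log2)

  cells <- table(meta$line, meta$time_h)
  if (!all(dim(cells) == c(2L, length(times))) || any(cells == 0))
    stop("rank-deficient design: missing cell for line x time ",
         paste(rownames(cells)[which(cells == 0, arr.ind = TRUE)[, 1]],
               colnames(cells)[which(cells == 0, arr.ind = TRUE)[, 2]],
               sep = " x ", collapse = "; "), call. = FALSE)
  if (any(cells < 2L))
    stop("fewer than 2 repeats in a line x time cell", call. = FALSE)

  f_line <- factor(meta$line, levels = c(control_line, line))
  f_time <- factor(meta$time_h, levels = times)
  f_rep <- factor(meta[["repeat"]])
  X <- stats::model.matrix(~ f_rep + f_line * f_time)
  XtX_inv <- solve(crossprod(X))
  H <- XtX_inv %*% t(X)
  df_res <- nrow(X) - ncol(X)

  # contrast rows: difference of the design rows of (line, t) and
  # (control, t) at a common repeat level -- the block cancels.
  contrasts <- lapply(times, function(t) {
    nd <- data.frame(f_rep = factor(levels(f_rep)[1], levels = levels(f_rep)),
                     f_line = factor(c(line, control_line),
                                     levels = levels(f_line)),
                     f_time = factor(t, levels = times))
    M <- stats::model.matrix(~ f_rep + f_line * f_time, nd)
    M[1, ] - M[2, ]
  })
  cmat <- do.call(rbind, contrasts)
  cvar <- rowSums((cmat %*% XtX_inv) * cmat)  # c' (X'X)^-1 c per contrast

  samp <- meta$sample
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    y <- expr$log2[genes[i], samp]
    beta <- drop(H %*% y)
    resid <- y - drop(X %*% beta)
    s2 <- sum(resid^2) / df_res
    est <- drop(cmat %*% beta)
    se <- sqrt(s2 * cvar)
    tval <- ifelse(se > 0, est / se, 0)
    p <- 2 * stats::pt(-abs(tval), df_res)
    p[se == 0 & abs(est) < .Machine$double.eps^0.5] <- 1
    rows[[i]] <- data.frame(regulator = regulator, target = genes[i],
                            time_h = times, estimate = est, se = se, p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("line_time_estimates", "data.frame")
  out
}

#' Call network edges from line-time contrasts
#'
#' An edge regulator -> target at time t is called when the FDR-adjusted
#' contrast satisfies q < \code{fdr_threshold} and the target is not the
#' regulator itself; the provisional sign is the sign of the estimate.
#'
#' @param estimates one or several \code{\link{fit_line_time_model}} results
#'   (a data.frame or a list thereof, rbind-ed).
#' @param fdr_threshold FDR calling threshold, default 0.1.
#' @return data.frame of class \code{dynamic_network}: \code{regulator},
#'   \code{target}, \code{time_h}, \code{log2fc}, \code{q}, \code{sign}.
#' @export
call_edges <- function(estimates, fdr_threshold = 0.1) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  keep <- estimates$q < fdr_threshold & estimates$target != estimates$regulator
  out <- data.frame(regulator = estimates$regulator[keep],
                    target = estimates$target[keep],
                    time_h = estimates$time_h[keep],
                    log2fc = estimates$estimate[keep],
                    q = estimates$q[keep],
                    sign = sign(estimates$estimate[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dynamic_network", "data.frame")
  out
}

#' Fraction of other TFs affected by a regulator
#'
#' For each regulator, the fraction of its (non-self) targets whose contrast
#' magnitude exceeds \code{lfc_threshold} at any measured time.
#'
#' @param estimates \code{line_time_estimates} (one or several, rbind-ed).
#' @param lfc_threshold absolute log2FC threshold, default 1.
#' @return named numeric vector, one fraction per regulator.
#' @export
affected_fraction <- function(estimates, lfc_threshold = 1.0) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  estimates <- estimates[estimates$target != estimates$regulator, ,
                         drop = FALSE]
  out <- c(tapply(seq_len(nrow(estimates)), estimates$regulator,
                  function(i) {
    sub <- estimates[i, , drop = FALSE]
    mx <- tapply(abs(sub$estimate), sub$target, max)
    mean(mx > lfc_threshold)
  }))
  out
}

#' Union of per-time edges for TEA follow-up
#'
#' Deduplicates edges over the listed time points by (regulator, target);
#' the provisional sign (and reported log2FC/q) is taken at the earliest
#' significant time.
#'
#' @param dyn_net a \code{\link{call_edges}} result.
#' @param times time points to union over (default 1, 2 and 4 h, the early
#'   window used to nominate edges for transactivation follow-up).
#' @return data.frame of class \code{edge_union}: \code{regulator},
#'   \code{target}, \code{sign}, \code{first_time_h}, \code{log2fc},
#'   \code{q}.
#' @export
union_edges <- function(dyn_net, times = c(1, 2, 4)) {
  miss <- setdiff(times, unique(dyn_net$time_h))
  sub <- dyn_net[dyn_net$time_h %in% times, , drop = FALSE]
  sub <- sub[order(sub$regulator, sub$target, sub$time_h), , drop = FALSE]
  first <- !duplicated(sub[c("regulator", "target")])
  out <- data.frame(regulator = sub$regulator[first],
                    target = sub$target[first],
                    sign = sub$sign[first],
                    first_time_h = sub$time_h[first],
                    log2fc = sub$log2fc[first],
                    q = sub$q[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("edge_union", "data.frame")
  out
}

#' Write a dynamic network or edge union as an interaction TSV
#'
#' Column layout (regulator, target, time_h, log2fc, q, sign) importable as
#' a Cytoscape-style interaction file.
#'
#' @param edges a \code{dynamic_network} or \code{edge_union} data.frame.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
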