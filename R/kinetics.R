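# Wild-type stress time-course statistics: per-gene-per-time t tests with
# Benjamini-Hochberg adjustment, onset-group classification against the
# log2FC > 1 threshold, and late-response scenario classification.

# two-sample t on log2 values; Student (pooled) by default, optionally
# paired by repeat. Degenerate zero-variance cases: equal means -> p = 1.
.t_stat <- function(a, b, paired = FALSE) {
  if (paired) {
    d <- a - b
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    est <- mean(d); df <- n - 1
  } else {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    est <- mean(a) - mean(b); df <- na + nb - 2
  }
  if (!is.finite(se) || se == 0) {
    p <- if (abs(est) < .Machine$double.eps^0.5) 1 else 0
    return(list(estimate = est, se = se, t = if (p == 1) 0 else Inf * sign(est),
                p = p, df = df))
  }
  t <- est / se
  list(estimate = est, se = se, t = t,
       p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Stress versus control differential statistics over a time course
#'
#' For every gene and sampled time, a two-sided Student t test on the log2
#' normalized values (stress arm versus control arm), with Benjamini-
#' Hochberg adjustment. The adjustment family is all genes within one time
#' point by default ("time"), or all gene x time records ("global").
#'
#' @param expr an \code{\link{expression_table}} holding both arms.
#' @param stress_treatment,control_treatment treatment labels in the sample
#'   metadata.
#' @param paired if TRUE, pair samples by repeat within each time.
#' @param genes genes to test (default: all non-housekeeping rows present).
#' @param fdr_family "time" (default) or "global".
#' @return data.frame of class \code{timecourse_stats}: \code{gene},
#'   \code{time_h}, \code{log2fc}, \code{se}, \code{p}, \code{q},
#'   \code{n_repeats}.
#' @export
timecourse_differential <- function(expr, stress_treatment = "mannitol",
                                    control_treatment = "control",
                                    paired = FALSE, genes = NULL,
                                    fdr_family = c("time", "global")) {
  stopifnot(inherits(expr, "expression_table"))
  fdr_family <- match.arg(fdr_family)
  meta <- expr$meta
  if (is.null(genes)) genes <- rownames(expr$log2)
  times <- sort(unique(meta$time_h))
  rows <- vector("list", length(genes) * length(times))
  k <- 0L
  for (t in times) {
    sa <- meta$sample[meta$treatment == stress_treatment & meta$time_h == t]
    sb <- meta$sample[meta$treatment == control_treatment & meta$time_h == t]
    if (length(sa) < 2L || length(sb) < 2L)
      stop("fewer than 2 repeats per arm at time ", t, " h", call. = FALSE)
    if (paired) {
      ra <- meta[["repeat"]][match(sa, meta$sample)]
      rb <- meta[["repeat"]][match(sb, meta$sample)]
      common <- intersect(ra, rb)
      sa <- sa[match(common, ra)]; sb <- sb[match(common, rb)]
    }
    for (g in genes) {
      k <- k + 1L
      st <- .t_stat(expr$log2[g, sa], expr$log2[g, sb], paired = paired)
      rows[[k]] <- data.frame(gene = g, time_h = t, log2fc = st$estimate,
                              se = st$se, p = st$p,
                              n_repeats = length(sa),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  if (fdr_family == "time") {
    for (t in times) {
      i <- out$time_h == t
      out$q[i] <- stats::p.adjust(out$p[i], method = "BH")
    }
  } else {
    out$q <- stats::p.adjust(out$p, method = "BH")
  }
  class(out) <- c("timecourse_stats", "data.frame")
  out
}

#' Classify genes into onset groups
#'
#' The onset of a gene is the earliest sampled time at which its log2 fold
#' change strictly exceeds \code{threshold}; its group is the rank of the
#' smallest boundary time >= that onset. Genes that never cross within the
#' last boundary time get group \code{NA} ("none").
#'
#' @param stats a data.frame with \code{gene}, \code{time_h}, \code{log2fc}
#'   (e.g. from \code{\link{timecourse_differential}}); must cover all
#'   \code{boundary_times}.
#' @param threshold log2FC crossing threshold (default 1, strict).
#' @param boundary_times the onset-group boundaries, default
#'   40 min / 1 h / 2 h / 4 h.
#' @return data.frame: \code{gene}, \code{onset_time_h}, \code{group}
#'   (integer rank or NA).
#' @export
#' @examples
#' s <- data.frame(gene = "g", time_h = c(0.33, 0.67, 1),
#'                 log2fc = c(0.2, 1.4, 3))
#' classify_onset(s)   # crosses at 40 min -> group 1
classify_onset <- function(stats, threshold = 1.0,
                           boundary_times = c(0.67, 1, 2, 4)) {
  stopifnot(all(c("gene", "time_h", "log2fc") %in% names(stats)))
  boundary_times <- sort(boundary_times)
  have <- sort(unique(stats$time_h))
  gaps <- setdiff(boundary_times, have)
  if (length(gaps))
    stop("missing time points: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  genes <- unique(stats$gene)
  res <- lapply(genes, function(g) {
    sub <- stats[stats$gene == g, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    cross <- sub$time_h[sub$log2fc > threshold]
    onset <- if (length(cross)) min(cross) else NA_real_
    grp <- if (is.na(onset) || onset > max(boundary_times)) NA_integer_
           else which(boundary_times >= onset)[1]
    data.frame(gene = g,
               onset_time_h = if (is.na(grp)) NA_real_ else onset,
               group = grp, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify late-response scenarios
#'
#' Over the late sampled times, a gene is classified as
#' \emph{decline} when it is no longer significantly upregulated at the last
#' time (q >= alpha), otherwise \emph{rebound} when its log2FC series has a
#' strict interior local minimum among the late times (both neighbours
#' strictly greater), otherwise \emph{sustained}.
#'
#' @param stats a \code{timecourse_stats}-like data.frame with \code{gene},
#'   \code{time_h}, \code{log2fc}, \code{q}.
#' @param late_times the late sampling times, default 12/16/24/48 h; the
#'   largest is the end-point significance test.
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame: \code{gene}, \code{scenario}.
#' @export
classify_late_behavior <- function(stats, late_times = c(12, 16, 24, 48),
                                   alpha = 0.05) {
  stopifnot(all(c("gene", "time_h", "log2fc", "q") %in% names(stats)))
  late_times <- sort(late_times)
  gaps <- setdiff(late_times, unique(stats$time_h))
  if (length(gaps))
    stop("missing time points: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  t_end <- max(late_times)
  genes <- unique(stats$gene)
  res <- lapply(genes, function(g) {
    sub <- stats[stats$gene == g & stats$time_h %in% late_times, ,
                 drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    q_end <- sub$q[sub$time_h == t_end]
    fc <- sub$log2fc
    scenario <- if (q_end >= alpha) {
      "decline"
    } else {
      n <- length(fc)
      interior <- seq(2L, n - 1L)
      local_min <- any(fc[interior] < fc[interior - 1L] &
                         fc[interior] < fc[interior + 1L])
      if (local_min) "rebound" else "sustained"
    }
    data.frame(gene = g, scenario = scenario, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Count significantly upregulated genes at a time point
#'
#' @param stats a data.frame with \code{gene}, \code{time_h}, \code{log2fc},
#'   \code{q}.
#' @param time time point (hours).
#' @param alpha FDR threshold.
#' @return integer count of genes with q < alpha and log2fc > 0.
#' @export
count_significant <- function(stats, time, alpha = 0.05) {
  sub <- stats[stats$time_h == time, , drop = FALSE]
  if (!nrow(sub)) stop("no records at time ", time, " h", call. = FALSE)
  sum(sub$q < alpha & sub$log2fc > 0)
}
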