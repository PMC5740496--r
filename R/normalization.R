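# Housekeeping-gene normalization and fold-change conventions.
#
# Size factors are multiplicative, estimated from the geometric mean of the
# housekeeping counts per sample divided by the grand geometric mean; values
# are reported as log2(count / size factor + pseudocount). The pseudocount
# (0.5) keeps zero counts finite and, applied after scaling, preserves exact
# invariance to per-sample global rescaling.

geomean <- function(x) exp(mean(log(x)))

#' Normalize a count table against housekeeping genes
#'
#' @param counts a \code{\link{count_table}}.
#' @param hk_ids housekeeping gene identifiers; defaults to the five AGI
#'   identifiers of the standard probe set (AT1G13320, AT2G32170, AT2G28390,
#'   AT5G15710, AT4G24550).
#' @param pseudocount added to every count before the log2 (default 0.5).
#' @return an object of class \code{expression_table}: \code{log2} matrix
#'   (genes x samples), \code{size_factors}, \code{pseudocount} and the
#'   sample \code{meta}.
#' @export
#' @examples
#' # doubling every count of one sample leaves its normalized values unchanged
normalize_housekeeping <- function(counts,
                                   hk_ids = c("AT1G13320", "AT2G32170",
                                              "AT2G28390", "AT5G15710",
                                              "AT4G24550"),
                                   pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_table"))
  hk <- intersect(hk_ids, rownames(counts$counts))
  if (!length(hk))
    stop("no housekeeping gene found in the count table", call. = FALSE)
  hk_counts <- counts$counts[hk, , drop = FALSE]
  zero_samp <- colnames(hk_counts)[apply(hk_counts == 0, 2, all)]
  if (length(zero_samp))
    stop("housekeeping genes all zero in sample ", zero_samp[1],
         call. = FALSE)
  per_sample <- apply(hk_counts + (hk_counts == 0) * 0.5, 2, geomean)
  sf <- per_sample / geomean(per_sample)
  log2mat <- log2(sweep(counts$counts, 2, sf, "/") + pseudocount)
  structure(list(log2 = log2mat, size_factors = sf,
                 pseudocount = pseudocount, meta = counts$meta),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", nrow(x$log2), "genes x", ncol(x$log2),
      "samples (log2, housekeeping-normalized)\n")
  cat("  size factors: ", paste(round(range(x$size_factors), 3),
                                collapse = " - "), "\n")
  invisible(x)
}

#' Per-gene log2 fold change between two sample groups
#'
#' Mean log2 expression of group A minus group B. With paired repeats this
#' equals the mean of the per-repeat differences.
#'
#' @param expr an \code{expression_table}.
#' @param group_a_samples,group_b_samples disjoint non-empty character
#'   vectors of sample ids.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(expr, group_a_samples, group_b_samples) {
  stopifnot(inherits(expr, "expression_table"))
  if (!length(group_a_samples) || !length(group_b_samples))
    stop("empty sample group", call. = FALSE)
  if (length(intersect(group_a_samples, group_b_samples)))
    stop("sample groups must be disjoint", call. = FALSE)
  a <- expr$log2[, group_a_samples, drop = FALSE]
  b <- expr$log2[, group_b_samples, drop = FALSE]
  rowMeans(a) - rowMeans(b)
}

#' qPCR delta-delta-Ct fold change
#'
#' dCt = Ct(gene) - mean Ct(housekeeping genes) within each well group;
#' ddCt = dCt(control) - dCt(treatment); fold change = 2^ddCt (100\%
#' amplification efficiency assumed).
#'
#' @param ct_table data.frame with columns \code{well}, \code{gene},
#'   \code{ct} (cycle threshold values, > 0).
#' @param hk_ids housekeeping gene ids present in every well group.
#' @param control_wells,treatment_wells well identifiers of the two groups.
#' @return data.frame with one row per non-housekeeping gene: \code{gene},
#'   \code{dct_control}, \code{dct_treatment}, \code{ddct},
#'   \code{fold_change}.
#' @export
ddct <- function(ct_table, hk_ids, control_wells, treatment_wells) {
  stopifnot(is.data.frame(ct_table),
            all(c("well", "gene", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  grp <- function(wells) ct_table[ct_table$well %in% wells, , drop = FALSE]
  dct_of <- function(sub) {
    hk <- sub[sub$gene %in% hk_ids, , drop = FALSE]
    if (!nrow(hk))
      stop("missing housekeeping well in one group", call. = FALSE)
    hk_mean <- mean(hk$ct)
    tg <- sub[!sub$gene %in% hk_ids, , drop = FALSE]
    tapply(tg$ct, tg$gene, mean) - hk_mean
  }
  dc <- dct_of(grp(control_wells))
  dt <- dct_of(grp(treatment_wells))
  genes <- intersect(names(dc), names(dt))
  dd <- dc[genes] - dt[genes]
  data.frame(gene = genes,
             dct_control = unname(dc[genes]),
             dct_treatment = unname(dt[genes]),
             ddct = unname(dd),
             fold_change = unname(2^dd),
             stringsAsFactors = FALSE)
}
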