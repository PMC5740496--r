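# Count-table container and TSV round trip.
#
# TSV dialect: tab-separated, UTF-8, '#'-prefixed comment lines. Sample
# metadata travels in '#meta' comment lines above the header; the count
# block has first column `gene_id` and one column per sample.

.meta_cols <- c("sample", "line", "treatment", "time_h", "repeat")

#' Construct a count table
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param meta data.frame with one row per sample and columns
#'   \code{sample}, \code{line}, \code{treatment} (control/mannitol/dex),
#'   \code{time_h}, \code{repeat}.
#' @return an object of class \code{count_table}.
#' @export
count_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  missing_cols <- setdiff(.meta_cols, names(meta))
  if (length(missing_cols))
    stop("missing metadata: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!setequal(meta$sample, colnames(counts)) ||
      anyDuplicated(meta$sample))
    stop("metadata samples must match count columns exactly", call. = FALSE)
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.na(meta[.meta_cols])))
    stop("metadata contains missing values", call. = FALSE)
  structure(list(counts = counts, meta = meta), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  lines:     ", paste(unique(x$meta$line), collapse = ", "), "\n")
  cat("  treatments:", paste(unique(x$meta$treatment), collapse = ", "), "\n")
  cat("  times (h): ", paste(sort(unique(x$meta$time_h)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a count table as annotated TSV
#'
#' @param table a \code{count_table}.
#' @param path file path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#meta\t", paste(.meta_cols, collapse = "\t")), con)
  for (i in seq_len(nrow(table$meta))) {
    writeLines(paste0("#meta\t",
                      paste(unlist(table$meta[i, .meta_cols]),
                            collapse = "\t")), con)
  }
  writeLines(paste(c("gene_id", colnames(table$counts)), collapse = "\t"),
             con)
  for (g in rownames(table$counts)) {
    writeLines(paste(c(g, format(table$counts[g, ], scientific = FALSE,
                                 trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_count_table
#' @param path file path of a TSV written by \code{write_count_table} (or
#'   following the same dialect).
#' @export
read_count_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- lines[startsWith(lines, "#meta\t")]
  body <- lines[!startsWith(lines, "#")]
  if (length(meta_lines) < 2L)
    stop("missing metadata: no #meta block found", call. = FALSE)
  meta_raw <- lapply(strsplit(meta_lines, "\t", fixed = TRUE),
                     function(x) x[-1])
  header <- meta_raw[[1]]
  missing_cols <- setdiff(.meta_cols, header)
  if (length(missing_cols))
    stop("missing metadata: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  meta <- as.data.frame(do.call(rbind, meta_raw[-1]),
                        stringsAsFactors = FALSE)
  names(meta) <- header
  meta$time_h <- as.numeric(meta$time_h)
  meta[["repeat"]] <- as.integer(meta[["repeat"]])

  head_fields <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (head_fields[1] != "gene_id")
    stop("first column must be gene_id", call. = FALSE)
  samples <- head_fields[-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  genes <- vapply(rows, `[`, "", 1L)
  counts <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-1]))
    bad <- which(is.na(vals) | vals != round(vals))
    if (length(bad))
      stop(sprintf("non-integer count at gene %s, sample %s", genes[i],
                   samples[bad[1]]), call. = FALSE)
    counts[i, ] <- vals
  }
  count_table(counts, meta)
}
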