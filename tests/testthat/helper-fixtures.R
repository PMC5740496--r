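# Shared fixtures and independent oracles for the suite.

# --- independent brute-force motif oracles (naive enumeration, kept
# deliberately separate from the package's detectors) -----------------------

brute_ffl <- function(edges) {
  # edges: data.frame source, target, sign
  sg <- function(a, b) {
    i <- which(edges$source == a & edges$target == b)
    if (length(i)) edges$sign[i[1]] else 0L
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  out <- list()
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (x == y || y == z || x == z) next
    if (sg(x, y) != 0 && sg(y, z) != 0 && sg(x, z) != 0) {
      out[[length(out) + 1L]] <- data.frame(
        x = x, y = y, z = z,
        coherence = if (sg(x, z) == sg(x, y) * sg(y, z)) "coherent"
                    else "incoherent",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(x = character(0), y = character(0),
                                      z = character(0),
                                      coherence = character(0)))
  do.call(rbind, out)
}

brute_cycles <- function(edges, max_len = 4L) {
  # enumerate all node tuples as candidate cycles, canonical rotation =
  # lexicographically smallest start node
  sg <- function(a, b) {
    i <- which(edges$source == a & edges$target == b)
    if (length(i)) edges$sign[i[1]] else 0L
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  found <- list()
  for (len in 2:max_len) {
    idx <- rep(list(nodes), len)
    tuples <- do.call(expand.grid,
                      c(idx, list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(tuples))) {
      path <- as.character(unlist(tuples[r, ]))
      if (anyDuplicated(path)) next
      if (path[1] != min(path)) next   # canonical rotation only
      s <- 1L; ok <- TRUE
      for (i in seq_len(len)) {
        a <- path[i]; b <- path[if (i == len) 1L else i + 1L]
        w <- sg(a, b)
        if (w == 0L) { ok <- FALSE; break }
        s <- s * w
      }
      if (ok)
        found[[length(found) + 1L]] <- data.frame(
          cycle = paste(c(path, path[1]), collapse = "->"),
          length = len, net_sign = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) return(data.frame(cycle = character(0),
                                        length = integer(0),
                                        net_sign = integer(0)))
  do.call(rbind, found)
}

random_signed_edges <- function(n_nodes, p = 0.2) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
  rownames(e) <- NULL
  e
}

# --- small data fixtures ---------------------------------------------------

# paper-like confirmed network fixture: 45 edges, 39 from 5 designated hubs
fixture_core_network <- function() {
  hubs <- c("H1", "H2", "H3", "H4", "H5")
  others <- sprintf("T%02d", 1:14)
  edges <- list()
  hub_deg <- c(9, 8, 8, 7, 7)   # sums to 39
  for (i in seq_along(hubs)) {
    tg <- others[((seq_len(hub_deg[i]) + 2 * i) %% length(others)) + 1]
    tg <- unique(tg)
    extra <- setdiff(others, tg)
    tg <- c(tg, extra)[seq_len(hub_deg[i])]
    edges[[hubs[i]]] <- tg
  }
  edges[["T01"]] <- c("T02", "T03")
  edges[["T04"]] <- c("T05", "T06")
  edges[["T07"]] <- c("T08", "T09")
  df <- do.call(rbind, lapply(names(edges), function(s)
    data.frame(source = s, target = edges[[s]], sign = 1L,
               stringsAsFactors = FALSE)))
  stopifnot(nrow(df) == 45L)
  df
}

# minimal count table: g genes x s samples with the 5 housekeeping rows
fixture_count_table <- function(counts_core, hk_level = 500) {
  hk <- c("AT1G13320", "AT2G32170", "AT2G28390", "AT5G15710", "AT4G24550")
  m <- rbind(counts_core,
             matrix(hk_level, length(hk), ncol(counts_core),
                    dimnames = list(hk, colnames(counts_core))))
  meta <- data.frame(sample = colnames(m), line = "WT",
                     treatment = "control", time_h = 1,
                     stringsAsFactors = FALSE)
  meta[["repeat"]] <- seq_len(ncol(m))
  count_table(m, meta)
}

# regulation_call constructed directly from a verdict + mean
fake_call <- function(verdict, mean_log2, effector = "A",
                      promoter = "P", p = if (verdict == "none") 0.5
                      else 0.01) {
  structure(list(effector = effector, promoter = promoter,
                 verdict = verdict, mean_log2 = mean_log2, p = p, n = 3L),
            class = "regulation_call")
}

# fast minimal trajectories object: constant state per gene
const_traj <- function(levels, times = c(1, 2, 4)) {
  states <- matrix(rep(levels, each = length(times)), length(times),
                   dimnames = list(NULL, names(levels)))
  structure(list(times = times, states = states, stimulus = NULL,
                 perturbation = NULL), class = "trajectories")
}
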