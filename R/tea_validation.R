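# Transient expression assay (TEA) analysis: batch-wise relative
# luminescence, single-effector regulation calls, pairwise-combination
# scenario classification, and confirmation/signing of the in-planta
# network.

#' Batch-wise relative luminescence
#'
#' Each replicate activity is divided by the mean activity of the neutral
#' control construct measured in the same experiment (batch) and on the same
#' reporter promoter.
#'
#' @param raw data.frame with columns \code{effector1}, \code{effector2}
#'   (\code{NA} or "" when absent), \code{promoter}, \code{experiment},
#'   \code{replicate}, \code{activity} (> 0).
#' @param control_construct effector1 label of the neutral control
#'   (default "GUS", i.e. 35S::GUS).
#' @return the input with an added \code{ratio} column; control rows keep
#'   their own ratio (activity / control mean).
#' @export
relative_luminescence <- function(raw, control_construct = "GUS") {
  need <- c("effector1", "promoter", "experiment", "replicate", "activity")
  stopifnot(is.data.frame(raw), all(need %in% names(raw)))
  if (any(raw$activity <= 0)) stop("activities must be > 0", call. = FALSE)
  key <- paste(raw$promoter, raw$experiment, sep = "\r")
  is_ctrl <- raw$effector1 == control_construct
  ctrl_mean <- tapply(raw$activity[is_ctrl], key[is_ctrl], mean)
  missing_batch <- setdiff(unique(key), names(ctrl_mean))
  if (length(missing_batch))
    stop("missing batch control for promoter/experiment: ",
         gsub("\r", " / ", missing_batch[1]), call. = FALSE)
  raw$ratio <- raw$activity / as.numeric(ctrl_mean[key])
  raw
}

# per-experiment mean ratios for one construct on one promoter
.experiment_means <- function(ratios, effector1, effector2 = NA,
                              promoter) {
  e2 <- if (is.na(effector2) || !nzchar(effector2)) c(NA, "") else effector2
  e2col <- ratios$effector2
  if (is.null(e2col)) e2col <- rep(NA_character_, nrow(ratios))
  pick <- ratios$effector1 == effector1 &
    (if (all(is.na(e2) | e2 == "")) is.na(e2col) | e2col == "" |
       !nzchar(ifelse(is.na(e2col), "", e2col))
     else !is.na(e2col) & e2col == effector2) &
    ratios$promoter == promoter
  sub <- ratios[pick, , drop = FALSE]
  if (!nrow(sub)) return(numeric(0))
  c(tapply(sub$ratio, sub$experiment, mean))
}

#' Single-effector regulation call
#'
#' One-sample two-sided t test of the log2 per-experiment mean ratios
#' against 0; verdict "activation" or "repression" by the sign of the mean
#' when p < alpha, otherwise "none".
#'
#' @param ratios_by_experiment numeric vector of per-experiment mean
#'   relative activities (>= 3 independent experiments).
#' @param alpha significance level (default 0.05).
#' @param effector,promoter optional labels carried through to the result.
#' @return object of class \code{regulation_call}: list with
#'   \code{verdict}, \code{mean_log2}, \code{p}, \code{n}, labels.
#' @export
#' @examples
#' call_single_regulation(c(3.0, 4.0, 3.5))$verdict   # activation
call_single_regulation <- function(ratios_by_experiment, alpha = 0.05,
                                   effector = NA_character_,
                                   promoter = NA_character_) {
  x <- log2(ratios_by_experiment)
  if (length(x) < 3L)
    stop("need >= 3 independent experiment means", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    p <- if (abs(m) < .Machine$double.eps^0.5) 1 else 0
  } else {
    tt <- stats::t.test(x, mu = 0)
    p <- tt$p.value
  }
  verdict <- if (p < alpha) {
    if (m > 0) "activation" else "repression"
  } else "none"
  structure(list(effector = effector, promoter = promoter,
                 verdict = verdict, mean_log2 = m, p = p, n = length(x)),
            class = "regulation_call")
}

#' @export
print.regulation_call <- function(x, ...) {
  cat(sprintf("TEA call %s -> %s: %s (mean log2 ratio %.2f, p = %.3g, n = %d)\n",
              x$effector, x$promoter, x$verdict, x$mean_log2, x$p, x$n))
  invisible(x)
}

#' Classify the joint effect of two effectors on one promoter
#'
#' Formalises the five verbally described pairwise scenarios as a decision
#' tree on the single and pair calls (all on the same promoter), using a
#' log2-scale \code{margin} (default 0.5, about 1.4-fold):
#' \itemize{
#'   \item \emph{emergent}: both singles "none", pair active;
#'   \item \emph{enhancement}: pair active in the direction of the stronger
#'     single and at least \code{margin} stronger than it;
#'   \item \emph{elimination}: a single is active but the pair is "none";
#'   \item \emph{dominance}: singles disagree (or one is "none") and the
#'     pair sits within \code{margin} of the stronger single;
#'   \item \emph{attenuation}: the pair keeps the stronger single's
#'     direction but lies strictly between the two single means, at least
#'     \code{margin} away from the stronger one;
#'   \item \emph{additive} otherwise.
#' }
#' The classification is symmetric in the two effectors.
#'
#' @param call_a,call_b single-effector \code{\link{call_single_regulation}}
#'   results.
#' @param pair_call the pair's \code{regulation_call} on the same promoter.
#' @param margin log2-scale margin (default 0.5).
#' @return object of class \code{pair_scenario}: list with \code{scenario}
#'   and the three calls.
#' @export
classify_pair_effect <- function(call_a, call_b, pair_call, margin = 0.5) {
  proms <- c(call_a$promoter, call_b$promoter, pair_call$promoter)
  proms <- proms[!is.na(proms)]
  if (length(unique(proms)) > 1L)
    stop("promoter mismatch between calls", call. = FALSE)

  active_a <- call_a$verdict != "none"
  active_b <- call_b$verdict != "none"
  pair_active <- pair_call$verdict != "none"
  mp <- pair_call$mean_log2

  # order singles by effect magnitude; ties keep (a, b) order
  if (abs(call_b$mean_log2) > abs(call_a$mean_log2)) {
    strong <- call_b; weak <- call_a
  } else {
    strong <- call_a; weak <- call_b
  }
  ms <- strong$mean_log2; mw <- weak$mean_log2

  act_single <- if (active_a && !active_b) call_a
                else if (active_b && !active_a) call_b else NULL

  scenario <- if (!active_a && !active_b) {
    if (pair_active) "emergent" else "additive"
  } else if (!is.null(act_single) && pair_active &&
             sign(mp) == sign(act_single$mean_log2) &&
             abs(mp) >= abs(act_single$mean_log2) + margin) {
    "enhancement"
  } else if (!pair_active) {
    "elimination"
  } else if ((!active_a || !active_b ||
              sign(call_a$mean_log2) != sign(call_b$mean_log2)) &&
             sign(mp) == sign(ms) && abs(mp - ms) < margin) {
    "dominance"
  } else if (sign(mp) == sign(ms) &&
             mp > min(ms, mw) && mp < max(ms, mw) &&
             abs(mp - ms) >= margin) {
    "attenuation"
  } else "additive"

  structure(list(scenario = scenario, call_a = call_a, call_b = call_b,
                 pair_call = pair_call, margin = margin),
            class = "pair_scenario")
}

#' @export
print.pair_scenario <- function(x, ...) {
  cat(sprintf("Pair %s + %s on %s: %s\n", x$call_a$effector,
              x$call_b$effector, x$pair_call$promoter, x$scenario))
  invisible(x)
}

#' Confirm in-planta edges with transactivation calls
#'
#' An edge of the expression-based union is \emph{confirmed-single} when its
#' single-effector TEA verdict is not "none"; the final edge sign is taken
#' from the TEA verdict, overriding the in-planta provisional sign (the
#' assay without the GR fusion better reflects the endogenous activity).
#' Edges not confirmed singly become \emph{confirmed-pair} when the
#' regulator participates in an enhancement, emergent or attenuation
#' pairwise scenario on that promoter. Edges with no TEA record are flagged
#' untested.
#'
#' @param union_edges an \code{\link{union_edges}} result.
#' @param single_calls list of \code{regulation_call}s (fields
#'   \code{effector}, \code{promoter} set).
#' @param pair_calls optional list of \code{pair_scenario}s.
#' @return list of class \code{confirmed_network}: \code{edges} data.frame
#'   (\code{regulator}, \code{target}, \code{sign}, \code{confirmation} in
#'   single/pair/none, \code{tested}), and \code{summary} with counts
#'   (tested, confirmed_single, confirmed_pair, total_confirmed).
#' @export
confirm_edges <- function(union_edges, single_calls, pair_calls = list()) {
  skey <- vapply(single_calls,
                 function(cl) paste(cl$effector, cl$promoter, sep = "\r"),
                 "")
  edges <- as.data.frame(union_edges, stringsAsFactors = FALSE)
  n <- nrow(edges)
  confirmation <- character(n)
  final_sign <- edges$sign
  tested <- logical(n)
  for (i in seq_len(n)) {
    k <- paste(edges$regulator[i], edges$target[i], sep = "\r")
    j <- match(k, skey)
    if (is.na(j)) {
      confirmation[i] <- "none"; tested[i] <- FALSE
      next
    }
    tested[i] <- TRUE
    cl <- single_calls[[j]]
    if (cl$verdict != "none") {
      confirmation[i] <- "single"
      final_sign[i] <- if (cl$verdict == "activation") 1 else -1
    } else {
      in_pair <- any(vapply(pair_calls, function(ps) {
        ps$pair_call$promoter %in% edges$target[i] &&
          edges$regulator[i] %in% c(ps$call_a$effector,
                                    ps$call_b$effector) &&
          ps$scenario %in% c("enhancement", "emergent", "attenuation")
      }, logical(1)))
      if (in_pair) {
        confirmation[i] <- "pair"
        # sign from the pair verdict: the joint regulation's direction
        pc <- Filter(function(ps)
          ps$pair_call$promoter %in% edges$target[i] &&
            edges$regulator[i] %in% c(ps$call_a$effector,
                                      ps$call_b$effector) &&
            ps$scenario %in% c("enhancement", "emergent", "attenuation"),
          pair_calls)[[1]]
        final_sign[i] <- if (pc$pair_call$mean_log2 >= 0) 1 else -1
      } else confirmation[i] <- "none"
    }
  }
  edges$sign <- final_sign
  edges$confirmation <- confirmation
  edges$tested <- tested
  summary <- list(tested = sum(tested),
                  confirmed_single = sum(confirmation == "single"),
                  confirmed_pair = sum(confirmation == "pair"),
                  total_confirmed = sum(confirmation != "none"))
  structure(list(edges = edges, summary = summary),
            class = "confirmed_network")
}

#' @export
print.confirmed_network <- function(x, ...) {
  s <- x$summary
  cat("Confirmed network:", nrow(x$edges), "candidate edges;",
      s$tested, "tested,", s$confirmed_single, "confirmed single,",
      s$confirmed_pair, "confirmed via pairs =>", s$total_confirmed,
      "confirmed\n")
  invisible(x)
}

#' Write a confirmed network as TSV
#'
#' @param confirmed a \code{confirmed_network}.
#' @param path output path.
#' @export
write_confirmed_network <- function(confirmed, path) {
  utils::write.table(confirmed$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
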