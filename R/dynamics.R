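# Deterministic network dynamics.
#
# dx_i/dt = max(0, basal_i + g_i(t) * [s_i * stim(t) + sum_j act(x_j; w_ji)
#                 - sum_j rep(x_j; w_ji)] + (1 - g_i(t)) * R_i*) - delta_i x_i
#
# with saturating Hill regulation act/rep(x) = |w| * x^n / (K^n + x^n).
# R_i* is the node's regulatory input at the pre-stress steady state, and
# g_i(t) = 1[t >= onset_delay_i] while a stimulus schedule is active: until
# its lag elapses a node keeps transcribing from its pre-stress inputs, so
# the stress-borne signal (direct or network-relayed) reaches each node only
# after its configured delay. Without a stimulus (e.g. DEX-clamp experiments)
# the gate is open and the live network acts immediately.
# Integration: classical fixed-step RK4.

hill <- function(x, k, n) {
  x <- pmax(x, 0)
  xn <- x^n
  xn / (k^n + xn)
}

# regulatory input per node given state x: sum of signed saturating terms
.reg_input <- function(adj, x, k, n) {
  drop(hill(x, k, n) %*% adj)
}

#' Pre-stress steady state of a ground-truth network
#'
#' Solves the fixed point x* = max(0, basal + R(x*)) / decay by damped
#' iteration; used to initialise every simulation and as the control
#' operating point of the delay gate.
#'
#' @param network a \code{\link{make_ground_truth}} network.
#' @param tol convergence tolerance on the state.
#' @return named numeric vector of steady-state concentrations.
#' @export
steady_state <- function(network, tol = 1e-10) {
  x <- network$basal / network$decay
  for (i in 1:1000) {
    prod <- pmax(0, network$basal +
                   .reg_input(network$adjacency, x, network$hill_k,
                              network$hill_n))
    x_new <- 0.5 * x + 0.5 * prod / network$decay
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

#' Simulate network dynamics
#'
#' Integrates the Hill-kinetics ODE system under an optional stress stimulus
#' (a unit step at t = 0, received by each node after its onset delay) and an
#' optional perturbation clamping one node at a fixed level (modelling
#' DEX-induced overexpression).
#'
#' @param network a \code{ground_truth_network}.
#' @param stimulus \code{NULL} (control) or \code{list(t_on = 0)} for a step
#'   stress input at t = 0.
#' @param perturbation \code{NULL} or \code{list(node =, level =, from = 0)}:
#'   the named node is held at \code{level} from time \code{from} onwards
#'   (default level: the network's \code{clamp_level}).
#' @param grid sampling times (hours) at which states are returned; must be
#'   non-negative.
#' @param step_h internal fixed RK4 step (hours).
#'
#' @return an object of class \code{trajectories}: \code{times}, a
#'   \code{states} matrix (time x node), and the stimulus/perturbation
#'   descriptors.
#' @export
#' @examples
#' net <- make_ground_truth(seed = 1)
#' tr <- simulate_dynamics(net, stimulus = list(t_on = 0),
#'                         grid = c(0.33, 0.67, 1, 2, 4))
#' round(tr$states[, "ERF6"], 1)
simulate_dynamics <- function(network, stimulus = NULL, perturbation = NULL,
                              grid = network_default_grid(), step_h = 0.01) {
  stopifnot(inherits(network, "ground_truth_network"))
  grid <- sort(as.numeric(grid))
  if (any(grid < 0)) stop("grid times must be >= 0", call. = FALSE)
  nodes <- network$nodes
  n <- length(nodes)
  adj <- network$adjacency
  k <- network$hill_k; hn <- network$hill_n
  basal <- network$basal; decay <- network$decay
  delays <- network$onset_delay
  stim_on <- !is.null(stimulus)
  t_on <- if (stim_on) (if (is.null(stimulus$t_on)) 0 else stimulus$t_on) else Inf
  sw <- network$stim_weight

  clamp_idx <- NA_integer_; clamp_level <- NA_real_; clamp_from <- 0
  if (!is.null(perturbation)) {
    if (is.null(perturbation$node) || !perturbation$node %in% nodes)
      stop("perturbation$node must name a network node", call. = FALSE)
    clamp_idx <- match(perturbation$node, nodes)
    clamp_level <- if (is.null(perturbation$level)) network$clamp_level
                   else perturbation$level
    clamp_from <- if (is.null(perturbation$from)) 0 else perturbation$from
  }

  x0 <- steady_state(network)
  r_star <- .reg_input(adj, x0, k, hn)   # pre-stress regulatory operating point

  deriv <- function(t, x) {
    live <- .reg_input(adj, x, k, hn) +
      if (stim_on && t >= t_on) sw else 0
    gate <- if (stim_on) as.numeric(t >= delays + t_on) else 1
    prod <- pmax(0, basal + gate * live + (1 - gate) * r_star)
    dx <- prod - decay * x
    if (!is.na(clamp_idx) && t >= clamp_from) dx[clamp_idx] <- 0
    dx
  }

  t_end <- max(grid)
  n_steps <- max(1L, ceiling(t_end / step_h))
  h <- if (t_end > 0) t_end / n_steps else step_h
  dense_t <- seq(0, by = h, length.out = n_steps + 1L)
  states <- matrix(NA_real_, n_steps + 1L, n, dimnames = list(NULL, nodes))
  x <- x0
  if (!is.na(clamp_idx) && clamp_from <= 0) x[clamp_idx] <- clamp_level
  states[1L, ] <- x
  for (s in seq_len(n_steps)) {
    t <- dense_t[s]
    k1 <- deriv(t, x)
    k2 <- deriv(t + h / 2, x + h / 2 * k1)
    k3 <- deriv(t + h / 2, x + h / 2 * k2)
    k4 <- deriv(t + h, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.na(clamp_idx) && dense_t[s + 1L] >= clamp_from)
      x[clamp_idx] <- clamp_level
    if (any(!is.finite(x)))
      stop(sprintf("integration error: non-finite state for node %s at t = %.3f h",
                   nodes[which(!is.finite(x))[1]], dense_t[s + 1L]),
           call. = FALSE)
    if (any(x < -1e-8))
      stop(sprintf("integration error: negative state for node %s at t = %.3f h",
                   nodes[which(x < -1e-8)[1]], dense_t[s + 1L]), call. = FALSE)
    x[x < 0] <- 0
    states[s + 1L, ] <- x
  }

  out <- matrix(NA_real_, length(grid), n, dimnames = list(NULL, nodes))
  for (j in seq_len(n)) {
    out[, j] <- stats::approx(dense_t, states[, j], xout = grid,
                              rule = 2)$y
  }
  structure(list(times = grid, states = out,
                 stimulus = if (stim_on) list(t_on = t_on) else NULL,
                 perturbation = perturbation),
            class = "trajectories")
}

network_default_grid <- function() c(0.33, 0.67, 1, 2, 4, 8, 12, 16, 24, 48)

#' @export
print.trajectories <- function(x, ...) {
  cat("Trajectories:", ncol(x$states), "nodes at", length(x$times),
      "times (", min(x$times), "-", max(x$times), "h )\n")
  if (!is.null(x$perturbation))
    cat("  clamp:", x$perturbation$node, "at", x$perturbation$level, "\n")
  if (!is.null(x$stimulus)) cat("  stress step at t =", x$stimulus$t_on, "h\n")
  invisible(x)
}

# State of gene `gene` at sampled time `time_h`; errors outside the span.
traj_state <- function(traj, gene, time_h) {
  i <- match(time_h, traj$times)
  if (any(is.na(i)))
    stop("sampling time outside trajectory span: ",
         paste(time_h[is.na(i)], collapse = ", "), call. = FALSE)
  traj$states[i, gene]
}
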