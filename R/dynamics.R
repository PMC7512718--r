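#' One synchronous update of the spreading dynamics
#'
#' Applies the discrete-time Markov-chain update
#' \deqn{p_i(t+1) = (1 - \mu_i) p_i(t) + \eta_i(P_i(t)) (1 - p_i(t))}
#' once, for all nodes simultaneously (every node reads the time-`t`
#' state). The unit hypercube is positively invariant: states in `[0, 1]`
#' stay in `[0, 1]`, and the all-zero extinction state is a fixed point.
#'
#' @param p numeric state vector in `[0, 1]`.
#' @param params a [node_params()].
#' @param net a [spread_network()].
#' @param kernel a transition kernel (default [contact_kernel()]).
#' @return The updated state vector.
#' @examples
#' net <- toy_network("triangle")
#' par <- node_params(rep(0.5, 3), rep(0.5, 3), rep(0.5, 3))
#' spread_step(c(1, 0, 0), par, net)
#' @export
spread_step <- function(p, params, net, kernel = contact_kernel()) {
  stopifnot_probability(p, "p")
  eta <- kernel_eta(kernel, p, params, net)
  (1 - params$mu) * p + eta * (1 - p)
}

#' Network-average prevalence
#'
#' The arithmetic mean of the per-node infection probabilities,
#' \eqn{\rho(t) = N^{-1} \sum_i p_i(t)}.
#'
#' @param p numeric state vector.
#' @return Scalar in `[0, 1]`.
#' @export
prevalence <- function(p) mean(p)

#' Simulate a spreading trajectory
#'
#' Iterates [spread_step()] for `n_steps` steps, recording the prevalence
#' at every step. When a [control_policy()] is supplied, the monitored
#' states (the controlled nodes' own probabilities; monitored set =
#' controlled set) are read before each update, the output-feedback law
#' recomputes the controlled parameter entries, and the step is taken with
#' those parameters. Zero-dynamics policies rewrite the parameters once up
#' front (equivalent to unlinking the controlled nodes).
#'
#' @param net a [spread_network()].
#' @param params a [node_params()] (the constant, uncontrolled values).
#' @param p0 initial state vector in `[0, 1]`.
#' @param n_steps number of update steps (`>= 0`).
#' @param kernel transition kernel (default [contact_kernel()]).
#' @param policy optional [control_policy()]; `NULL` means open loop.
#' @param record_states logical; keep the full per-node state at every
#'   step (rows of `states` are time points). Defaults to `TRUE` for
#'   networks of at most 1000 nodes.
#' @return An object of class `spread_trajectory`: list with `t`
#'   (`0:n_steps`), `rho` (prevalence at each time), `p_final`, optionally
#'   `states`, and for feedback policies a `control` summary with the
#'   largest emitted control-to-bound ratio `max_ratio` and smallest
#'   emitted control `min_value` across the whole run.
#' @export
simulate_spread <- function(net, params, p0, n_steps,
                            kernel = contact_kernel(), policy = NULL,
                            record_states = net$n_nodes <= 1000L) {
  stopifnot_probability(p0, "p0")
  if (length(p0) != net$n_nodes) {
    stop("`p0` length does not match network size", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 0L) stop("`n_steps` must be >= 0", call. = FALSE)

  if (!is.null(policy) && policy$mode %in% c("zero-beta", "zero-r")) {
    params <- apply_zero_dynamics(params, policy)
    policy <- NULL
  }
  feedback <- !is.null(policy) && policy$mode %in% c("fb-beta", "fb-r")
  if (!is.null(policy) && policy$mode == "none") policy <- NULL

  p <- as.numeric(p0)
  rho <- numeric(n_steps + 1L)
  rho[1L] <- prevalence(p)
  states <- if (record_states) {
    m <- matrix(NA_real_, n_steps + 1L, net$n_nodes)
    m[1L, ] <- p
    m
  }
  max_ratio <- -Inf
  min_value <- Inf
  for (s in seq_len(n_steps)) {
    if (feedback) {
      step_params <- params
      if (policy$mode == "fb-beta") {
        u <- feedback_beta(p, policy)
        step_params$beta[policy$controlled] <- u
      } else {
        u <- feedback_r(p, policy)
        step_params$r[policy$controlled] <- u
      }
      if (length(u)) {
        max_ratio <- max(max_ratio, max(u / policy$upper_bounds))
        min_value <- min(min_value, min(u))
      }
      p <- spread_step(p, step_params, net, kernel)
    } else {
      p <- spread_step(p, params, net, kernel)
    }
    rho[s + 1L] <- prevalence(p)
    if (record_states) states[s + 1L, ] <- p
  }
  structure(
    list(
      t = 0:n_steps,
      rho = rho,
      p_final = p,
      states = states,
      control = if (feedback) {
        list(max_ratio = max_ratio, min_value = min_value, n_steps = n_steps)
      }
    ),
    class = "spread_trajectory"
  )
}

#' @export
print.spread_trajectory <- function(x, ...) {
  cat(sprintf(
    "<spread_trajectory: %d steps, rho(0) = %.4g, rho(final) = %.4g>\n",
    length(x$t) - 1L, x$rho[1L], x$rho[length(x$rho)]
  ))
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' One row per time step with columns `t,rho`; when the trajectory carries
#' full states (networks of at most 1000 nodes by default) one additional
#' column `p<k>` per node (0-based node labels).
#'
#' @param traj a [simulate_spread()] trajectory.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$t, rho = traj$rho)
  if (!is.null(traj$states)) {
    st <- as.data.frame(traj$states)
    names(st) <- paste0("p", seq_len(ncol(st)) - 1L)
    df <- cbind(df, st)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' First passage of the prevalence below a threshold
#'
#' @param traj a [simulate_spread()] trajectory.
#' @param threshold extinction threshold on the prevalence.
#' @return The first time index `t` with `rho(t) < threshold`, or `NA` if
#'   the trajectory never crosses it.
#' @export
extinction_time <- function(traj, threshold = 1e-3) {
  hit <- which(traj$rho < threshold)
  if (length(hit) == 0L) return(NA_integer_)
  traj$t[hit[1L]]
}

#' Self-consistent fixed point of the spreading dynamics
#'
#' Nontrivial stationary states satisfy
#' \eqn{p_i^* = \eta_i(P^*) / (\mu_i + \eta_i(P^*))} componentwise. This
#' solver applies plain Picard iteration of that map until the max-norm
#' change drops below `tol`. The extinction state `p = 0` is always a
#' fixed point (and is returned unchanged from `p_init = 0`); starting
#' from an interior point converges to the endemic state when one exists.
#' Nodes with `mu + eta = 0` are left at their current value (any value is
#' stationary for them).
#'
#' @param net a [spread_network()].
#' @param params a [node_params()].
#' @param kernel transition kernel (default [contact_kernel()]).
#' @param p_init starting vector; defaults to `rep(0.5, n)`.
#' @param tol max-norm convergence tolerance (default `1e-10`).
#' @param max_iter iteration cap; on non-convergence the last iterate is
#'   returned with a warning and `converged = FALSE`.
#' @return List with `p` (the fixed point reached), `residual` (last
#'   max-norm change), `iterations` and `converged`.
#' @export
fixed_point <- function(net, params, kernel = contact_kernel(),
                        p_init = NULL, tol = 1e-10, max_iter = 10000L) {
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  p <- if (is.null(p_init)) rep(0.5, net$n_nodes) else as.numeric(p_init)
  stopifnot_probability(p, "p_init")
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    eta <- kernel_eta(kernel, p, params, net)
    denom <- params$mu + eta
    p_new <- ifelse(denom > 0, eta / denom, p)
    residual <- max(abs(p_new - p))
    p <- p_new
    iter <- iter + 1L
    if (residual < tol) break
  }
  converged <- residual < tol
  if (!converged) {
    warning(sprintf(
      "fixed-point iteration did not converge in %d iterations (residual %.3g)",
      max_iter, residual
    ), call. = FALSE)
  }
  list(p = p, residual = residual, iterations = iter, converged = converged)
}
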