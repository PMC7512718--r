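# Output-feedback control of the spreading process.
#
# Control acts on node parameters: beta-control lowers the infection rate
# of a controlled node (affecting only that node's own transition
# probability), r-control lowers its contact probability (removing its
# contribution from every neighbour's transition probability). The
# admissible range for a controlled parameter is [0, ubar), where ubar is
# the exact value at which the node's stability condition holds with
# equality; any feedback that stays strictly below ubar stabilizes
# extinction.

#' Critical infection-rate bound per node
#'
#' \eqn{\bar\beta_i = \mu_i / \sum_{j \in V_i} r_j}: the infection rate at
#' which node `i`'s row-condition sum equals `mu_i` exactly. Any constant
#' `beta_i < beta_bar_i` makes the row condition pass. Isolated nodes (or
#' nodes all of whose neighbours have `r = 0`) have no finite bound and
#' need no control; they get `NA`.
#'
#' @param params a [node_params()].
#' @param net a [spread_network()].
#' @return Numeric vector of per-node bounds (`NA` where undefined).
#' @examples
#' net <- toy_network("path_2")
#' par <- node_params(mu = c(0.25, 0.5), beta = c(0.9, 0.9), r = c(0.3, 0.5))
#' beta_bar(par, net)[1] # 0.25 / 0.5 = 0.5
#' @export
beta_bar <- function(params, net) {
  denom <- edge_aggregate(net, params$r[net$to], net$from)
  ifelse(denom > 0, params$mu / denom, NA_real_)
}

#' Critical contact-probability bound per node
#'
#' \eqn{\bar r_i = \mu_i / \sum_{j \in V_i} \beta_j}: the contact
#' probability at which node `i`'s column-condition sum equals `mu_i`
#' exactly; any constant `r_i < r_bar_i` makes the column condition pass.
#' `NA` where the neighbour infection rates sum to zero.
#'
#' @inheritParams beta_bar
#' @return Numeric vector of per-node bounds (`NA` where undefined).
#' @export
r_bar <- function(params, net) {
  denom <- edge_aggregate(net, params$beta[net$to], net$from)
  ifelse(denom > 0, params$mu / denom, NA_real_)
}

#' Construct a control policy
#'
#' A `control_policy` fixes the control mode, the controlled node set
#' (which is also the monitored set: the feedback for node `i` reads only
#' `p_i`), the gain, and the per-node admissible upper bounds.
#'
#' Modes: `"fb-beta"` applies the linear output feedback
#' `beta_i(t) = gamma * beta_bar_i * (1 - p_i(t))`; `"fb-r"` the analogous
#' law on `r_i`; `"zero-beta"` / `"zero-r"` clamp the controlled parameter
#' to zero (zero dynamics - equivalent to unlinking the node);
#' `"none"` leaves the dynamics open loop. Row-condition violators pair
#' with beta-control, column-condition violators with r-control.
#'
#' @param mode one of `"none"`, `"fb-beta"`, `"fb-r"`, `"zero-beta"`,
#'   `"zero-r"`.
#' @param controlled integer vector of controlled (= monitored) node
#'   indices, e.g. from [select_controlled_nodes()].
#' @param params a [node_params()] (constant uncontrolled values), used to
#'   precompute the bounds; required for feedback modes.
#' @param net a [spread_network()]; required for feedback modes.
#' @param gamma feedback gain, strictly inside `(0, 1)` (default 0.9).
#' @return An object of class `control_policy` with elements `mode`,
#'   `controlled`, `monitored` (identical), `gamma` and `upper_bounds`
#'   (per-controlled-node `beta_bar` or `r_bar`; feedback modes only).
#' @export
control_policy <- function(mode = c("none", "fb-beta", "fb-r",
                                    "zero-beta", "zero-r"),
                           controlled = integer(0), params = NULL,
                           net = NULL, gamma = 0.9) {
  mode <- match.arg(mode)
  controlled <- as.integer(controlled)
  upper_bounds <- NULL
  if (mode %in% c("fb-beta", "fb-r")) {
    if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma < 1)) {
      stop("`gamma` must lie strictly in (0, 1)", call. = FALSE)
    }
    if (is.null(params) || is.null(net)) {
      stop("feedback modes need `params` and `net` to precompute bounds",
           call. = FALSE)
    }
    ub <- if (mode == "fb-beta") beta_bar(params, net) else r_bar(params, net)
    upper_bounds <- ub[controlled]
    if (anyNA(upper_bounds)) {
      stop(paste("a controlled node has no finite control bound (isolated",
                 "or zero-parameter neighbourhood); such nodes cannot",
                 "violate the stability condition and need no control"),
           call. = FALSE)
    }
  }
  structure(
    list(mode = mode, controlled = controlled, monitored = controlled,
         gamma = gamma, upper_bounds = upper_bounds),
    class = "control_policy"
  )
}

#' @export
print.control_policy <- function(x, ...) {
  cat(sprintf("<control_policy: mode %s, %d controlled nodes, gamma %.3g>\n",
              x$mode, length(x$controlled), x$gamma))
  invisible(x)
}

#' Linear output-feedback law on the infection rate
#'
#' `beta_i(t) = gamma * beta_bar_i * (1 - p_i(t))` for each controlled
#' node, clipped into `[0, 1]` (the parameter is a probability; clipping
#' only ever lowers the value, so the strict admissibility bound
#' `u_i(t) < beta_bar_i` is preserved). Depends only on the controlled
#' node's own measured state.
#'
#' @param p current full state vector.
#' @param policy a [control_policy()] with mode `"fb-beta"`.
#' @return Numeric vector of `beta` values, one per controlled node.
#' @export
feedback_beta <- function(p, policy) {
  if (policy$mode != "fb-beta") {
    stop("`policy` must have mode \"fb-beta\"", call. = FALSE)
  }
  pmin(1, policy$gamma * policy$upper_bounds * (1 - p[policy$controlled]))
}

#' Linear output-feedback law on the contact probability
#'
#' `r_i(t) = gamma * r_bar_i * (1 - p_i(t))`, clipped into `[0, 1]`;
#' mirror of [feedback_beta()].
#'
#' @param p current full state vector.
#' @param policy a [control_policy()] with mode `"fb-r"`.
#' @return Numeric vector of `r` values, one per controlled node.
#' @export
feedback_r <- function(p, policy) {
  if (policy$mode != "fb-r") {
    stop("`policy` must have mode \"fb-r\"", call. = FALSE)
  }
  pmin(1, policy$gamma * policy$upper_bounds * (1 - p[policy$controlled]))
}

#' Zero-dynamics parameter transform
#'
#' Sets `beta_i = 0` (mode `"zero-beta"`) or `r_i = 0` (mode `"zero-r"`)
#' for every controlled node, leaving all other entries untouched. Zeroing
#' either parameter is equivalent to unlinking the node from the spreading
#' process on the corresponding side: `beta_i = 0` makes node `i`
#' uninfectable, `r_i = 0` removes its contribution from every
#' neighbour's transition probability.
#'
#' @param params a [node_params()].
#' @param policy a [control_policy()] with a zero-dynamics mode.
#' @return A modified [node_params()].
#' @export
apply_zero_dynamics <- function(params, policy) {
  if (!policy$mode %in% c("zero-beta", "zero-r")) {
    stop("`policy` must have a zero-dynamics mode", call. = FALSE)
  }
  if (policy$mode == "zero-beta") {
    params$beta[policy$controlled] <- 0
  } else {
    params$r[policy$controlled] <- 0
  }
  params
}

#' Closed-loop simulation
#'
#' Convenience wrapper around [simulate_spread()] with a policy: at each
#' step the monitored states are read, the feedback law recomputes the
#' controlled parameter entries (or, for zero-dynamics modes, the
#' parameters are rewritten once up front), and the synchronous update is
#' taken. The emitted controls always satisfy
#' `0 <= u_i(t) <= gamma * ubar_i < ubar_i`; the trajectory's `control`
#' element records the extreme ratios actually emitted.
#'
#' @param net a [spread_network()].
#' @param params a [node_params()].
#' @param p0 initial state.
#' @param policy a [control_policy()].
#' @param n_steps horizon.
#' @param kernel transition kernel (default [contact_kernel()]).
#' @return A `spread_trajectory` (see [simulate_spread()]).
#' @export
closed_loop_simulate <- function(net, params, p0, policy, n_steps,
                                 kernel = contact_kernel()) {
  simulate_spread(net, params, p0, n_steps, kernel = kernel, policy = policy)
}
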