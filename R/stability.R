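# Stability certificates for the extinction state.
#
# The nonlinear dynamics is dominated entrywise by the linear system
# x(t+1) = (E_mu + M_U) x(t), with E_mu = diag(1 - mu_i) and M_U the
# kernel's slope-bound matrix. Extinction is globally asymptotically
# stable when the spectral radius of that matrix is below one; Gerschgorin
# localisation turns this into per-node sufficient conditions (row and
# column sums of M_U against mu_i) that also identify which nodes must be
# controlled.

#' Per-node row-sum stability condition
#'
#' Node `i` passes iff \eqn{\sum_j m_{ij} a_{ij} < \mu_i} strictly (for
#' the contact kernel: `beta_i * sum of neighbour r_j < mu_i`). If every
#' node passes, extinction is globally asymptotically stable. Equality is
#' classified as a violation: the certificate requires strict inequality,
#' and soundness is preferred over minimality of the selected set.
#'
#' @param params a [node_params()].
#' @param net a [spread_network()].
#' @param kernel transition kernel (default [contact_kernel()]).
#' @return List with `pass` (logical vector) and `margin`
#'   (`mu_i - sum_j m_ij`; positive means pass).
#' @examples
#' net <- toy_network("star_5")
#' par <- node_params(rep(0.5, 6), rep(0.5, 6), rep(0.5, 6))
#' row_condition(par, net)$pass # hub fails: 0.5 * (5 * 0.5) >= 0.5
#' @export
row_condition <- function(params, net, kernel = contact_kernel()) {
  margin <- params$mu - slope_bound_row_sums(kernel, params, net)
  list(pass = margin > 0, margin = margin)
}

#' Per-node column-sum stability condition
#'
#' Node `i` passes iff \eqn{\sum_j m_{ji} a_{ji} < \mu_i} strictly (for
#' the contact kernel: `r_i * sum of neighbour beta_j < mu_i`). A second,
#' independent sufficient certificate for global extinction, obtained by
#' bounding the column sums of the linear comparison system.
#'
#' @inheritParams row_condition
#' @return List with `pass` and `margin` (`mu_i - sum_j m_ji`).
#' @export
col_condition <- function(params, net, kernel = contact_kernel()) {
  margin <- params$mu - slope_bound_col_sums(kernel, params, net)
  list(pass = margin > 0, margin = margin)
}

#' Spectral radius of the linear comparison matrix
#'
#' Computes \eqn{\sigma(E_\mu + M_U)} by power iteration. The matrix is
#' nonnegative, and the diagonal `1 - mu_i` makes the iteration aperiodic,
#' so starting from the all-ones vector converges to the Perron root.
#'
#' @inheritParams row_condition
#' @param tol relative tolerance on the eigenvalue estimate
#'   (default `1e-10`).
#' @param max_iter iteration cap; non-convergence warns with the iterate
#'   count attached.
#' @return Scalar spectral-radius estimate.
#' @export
spectral_radius <- function(params, net, kernel = contact_kernel(),
                            tol = 1e-10, max_iter = 100000L) {
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  M <- kernel_slope_bound(kernel, params, net)
  d <- 1 - params$mu
  x <- rep(1, net$n_nodes)
  sigma <- 0
  for (iter in seq_len(max_iter)) {
    y <- d * x + as.numeric(M %*% x)
    nrm <- max(y)
    if (nrm == 0) return(0) # nilpotent-in-one-step edge case
    sigma_new <- sum(y * x) / sum(x * x)
    x <- y / nrm
    if (abs(sigma_new - sigma) <= tol * max(abs(sigma_new), 1e-300)) {
      return(sigma_new)
    }
    sigma <- sigma_new
  }
  warning(sprintf("power iteration did not converge in %d iterations",
                  max_iter), call. = FALSE)
  sigma
}

#' Gerschgorin upper bound on the spectral radius
#'
#' Returns \eqn{\max_i [(1 - \mu_i) + \sum_j m_{ij} a_{ij}]}: every
#' eigenvalue of `E_mu + M_U` lies in a disc centred at `1 - mu_i` with
#' radius the `i`-th row sum of `M_U`, so this never falls below the
#' spectral radius. Below one, it certifies extinction (and is exactly the
#' all-nodes row condition).
#'
#' @inheritParams row_condition
#' @return Scalar upper bound.
#' @export
gerschgorin_bound <- function(params, net, kernel = contact_kernel()) {
  max(1 - params$mu + slope_bound_row_sums(kernel, params, net))
}

#' Trajectory of the bounding linear dynamics
#'
#' `mode = "row"` iterates the full linear comparison system
#' `x(t+1) = (E_mu + M_U) x(t)`; started from the same nonnegative point
#' it dominates the nonlinear spreading trajectory entrywise at every
#' step. `mode = "col"` iterates the decoupled scalar recursions
#' `w_i(t+1) = [(1 - mu_i) + sum_j m_ji a_ji] w_i(t)` that underlie the
#' column certificate: their guarantee is on the network average (one
#' step of the nonlinear dynamics never exceeds the `w`-weighted average),
#' so when every coefficient is below one the average prevalence decays
#' geometrically.
#'
#' @param x0 nonnegative starting vector.
#' @inheritParams row_condition
#' @param n_steps number of steps.
#' @param mode `"row"` or `"col"`.
#' @return Matrix with `n_steps + 1` rows (time) and one column per node.
#' @export
linear_bound_trajectory <- function(x0, params, net,
                                    kernel = contact_kernel(),
                                    n_steps = 50L, mode = c("row", "col")) {
  mode <- match.arg(mode)
  if (any(x0 < 0)) stop("`x0` must be nonnegative", call. = FALSE)
  x <- as.numeric(x0)
  out <- matrix(NA_real_, n_steps + 1L, net$n_nodes)
  out[1L, ] <- x
  if (mode == "row") {
    M <- kernel_slope_bound(kernel, params, net)
    d <- 1 - params$mu
    for (s in seq_len(n_steps)) {
      x <- d * x + as.numeric(M %*% x)
      out[s + 1L, ] <- x
    }
  } else {
    g <- 1 - params$mu + slope_bound_col_sums(kernel, params, net)
    for (s in seq_len(n_steps)) {
      x <- g * x
      out[s + 1L, ] <- x
    }
  }
  out
}

#' Select the nodes that must be controlled
#'
#' Returns exactly the violator set of the chosen per-node condition. If
#' those nodes are controlled (and monitored - the monitored set equals
#' the controlled set), the dynamics restricted to the remaining nodes
#' (the zero dynamics) has the extinction state as its unique
#' asymptotically stable fixed point, because every remaining node
#' satisfies the condition by construction.
#'
#' @inheritParams row_condition
#' @param criterion `"row"` or `"col"`.
#' @return Integer vector of (1-based) node indices.
#' @export
select_controlled_nodes <- function(params, net, kernel = contact_kernel(),
                                    criterion = c("row", "col")) {
  criterion <- match.arg(criterion)
  cond <- switch(criterion,
                 row = row_condition(params, net, kernel),
                 col = col_condition(params, net, kernel))
  which(!cond$pass)
}

#' Full stability report
#'
#' Bundles both per-node margins, both violator sets and the spectral
#' radius of the linear comparison matrix into one object.
#'
#' @inheritParams row_condition
#' @param compute_spectral_radius logical; skip the power iteration on
#'   very large networks if not needed.
#' @return An object of class `stability_report` with `row_margin`,
#'   `col_margin`, `violators_row`, `violators_col` and `spectral_radius`
#'   (`NA` when skipped).
#' @export
stability_report <- function(params, net, kernel = contact_kernel(),
                             compute_spectral_radius = TRUE) {
  rc <- row_condition(params, net, kernel)
  cc <- col_condition(params, net, kernel)
  structure(
    list(
      row_margin = rc$margin,
      col_margin = cc$margin,
      violators_row = which(!rc$pass),
      violators_col = which(!cc$pass),
      spectral_radius = if (compute_spectral_radius) {
        spectral_radius(params, net, kernel)
      } else {
        NA_real_
      }
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  n <- length(x$row_margin)
  cat(sprintf(
    paste0("<stability_report: %d nodes; row violators %d, col violators",
           " %d; spectral radius %s>\n"),
    n, length(x$violators_row), length(x$violators_col),
    format(x$spectral_radius, digits = 6)
  ))
  invisible(x)
}

#' Write a stability report as CSV
#'
#' Columns `node,row_margin,col_margin,controlled_row,controlled_col`
#' (0-based node labels; the `controlled_*` columns flag condition
#' violators with 1).
#'
#' @param report a [stability_report()].
#' @param path file path.
#' @export
write_stability_report <- function(report, path) {
  n <- length(report$row_margin)
  df <- data.frame(
    node = seq_len(n) - 1L,
    row_margin = report$row_margin,
    col_margin = report$col_margin,
    controlled_row = as.integer(seq_len(n) %in% report$violators_row),
    controlled_col = as.integer(seq_len(n) %in% report$violators_col)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
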