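# Transition-kernel abstraction.
#
# A transition kernel describes how a node's probability of becoming
# infected in one step depends on its neighbours' states: it must supply
# eta (the per-node transition probability, with eta = 0 when no neighbour
# is infected) and a per-edge bound m_ij on |d eta_i / d p_j|, the
# "slope bound", which drives every stability certificate.

#' Contact-based transition kernel
#'
#' The concrete kernel of the heterogeneous contact model: node `i` escapes
#' infection only if every infectious contact attempt fails, giving
#' \deqn{\eta_i = 1 - \prod_{j \in V_i} (1 - \beta_i r_j p_j),}
#' where the product runs over the neighbours of `i`. Its slope bound is
#' \eqn{m_{ij} = \beta_i r_j} on every edge: the derivative of `eta_i` in
#' `p_j` is \eqn{\beta_i r_j} times a product of factors in `[0, 1]`.
#'
#' @return An object of class `c("contact_kernel", "transition_kernel")`.
#' @export
contact_kernel <- function() {
  structure(list(), class = c("contact_kernel", "transition_kernel"))
}

#' Kernel generics
#'
#' `kernel_eta` evaluates the per-node transition probability at state `p`;
#' `kernel_slope_bound` returns the sparse matrix `M_U` of per-edge slope
#' bounds `m_ij` (same sparsity pattern as the adjacency, generally not
#' symmetric).
#'
#' @param kernel a transition kernel, e.g. [contact_kernel()].
#' @param p numeric state vector in `[0, 1]`.
#' @param params a [node_params()].
#' @param net a [spread_network()].
#' @return `kernel_eta`: numeric vector of transition probabilities;
#'   `kernel_slope_bound`: a `Matrix::sparseMatrix`.
#' @export
kernel_eta <- function(kernel, p, params, net) UseMethod("kernel_eta")

#' @rdname kernel_eta
#' @export
kernel_slope_bound <- function(kernel, params, net) {
  UseMethod("kernel_slope_bound")
}

#' @rdname kernel_eta
#' @export
kernel_eta.contact_kernel <- function(kernel, p, params, net) {
  contact_eta(p, params, net)
}

#' @rdname kernel_eta
#' @export
kernel_slope_bound.contact_kernel <- function(kernel, params, net) {
  contact_slope_bound(params, net)
}

#' Contact-model transition probability
#'
#' Evaluates \eqn{\eta_i = 1 - \prod_{j \in V_i}(1 - \beta_i r_j p_j)} for
#' every node in one vectorised pass over the directed incidence list.
#' Products are accumulated as sums of `log1p(-x)` per destination node;
#' each factor lies in `[0, 1]`, and a zero factor (a neighbour that
#' infects with certainty) correctly forces `eta = 1`.
#'
#' @param p state vector (per-node infection probability).
#' @inheritParams kernel_eta
#' @return Numeric vector of per-node transition probabilities in `[0, 1]`;
#'   isolated nodes and the all-zero state give 0.
#' @examples
#' net <- toy_network("path_2")
#' par <- node_params(mu = c(0.5, 0.5), beta = c(0.5, 0.3), r = c(0.2, 0.4))
#' contact_eta(c(0, 0.5), par, net) # node 1: 1 - (1 - 0.5*0.4*0.5) = 0.1
#' @export
contact_eta <- function(p, params, net) {
  if (length(p) != net$n_nodes) {
    stop("state length does not match network size", call. = FALSE)
  }
  if (params$n_nodes != net$n_nodes) {
    stop("parameter length does not match network size", call. = FALSE)
  }
  terms <- params$beta[net$from] * params$r[net$to] * p[net$to]
  -expm1(edge_aggregate(net, log1p(-terms), net$from))
}

#' Contact-model slope-bound matrix
#'
#' Sparse matrix `M_U` with `m_ij = beta_i * r_j` on every edge `(i, j)`
#' and zero elsewhere. The row sums `beta_i * sum(r_j over neighbours)`
#' and column sums `r_i * sum(beta_j over neighbours)` are the quantities
#' compared against `mu_i` by the stability certificates.
#'
#' @inheritParams kernel_eta
#' @return A `Matrix::sparseMatrix` with the adjacency's sparsity pattern.
#' @export
contact_slope_bound <- function(params, net) {
  if (params$n_nodes != net$n_nodes) {
    stop("parameter length does not match network size", call. = FALSE)
  }
  Matrix::sparseMatrix(
    i = net$from, j = net$to,
    x = params$beta[net$from] * params$r[net$to],
    dims = c(net$n_nodes, net$n_nodes)
  )
}

# Row and column sums of the slope-bound matrix without materialising it;
# used on million-node networks where a single pass over the incidence
# list suffices.
slope_bound_row_sums <- function(kernel, params, net) {
  if (inherits(kernel, "contact_kernel")) {
    edge_aggregate(net, params$beta[net$from] * params$r[net$to], net$from)
  } else {
    as.numeric(Matrix::rowSums(kernel_slope_bound(kernel, params, net)))
  }
}

slope_bound_col_sums <- function(kernel, params, net) {
  if (inherits(kernel, "contact_kernel")) {
    edge_aggregate(net, params$beta[net$from] * params$r[net$to], net$to)
  } else {
    as.numeric(Matrix::colSums(kernel_slope_bound(kernel, params, net)))
  }
}
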