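# Independent scalar-loop oracles and random-fixture builders. These stay
# deliberately naive (dense matrices, double loops) so they share no code
# path with the vectorised implementation they check.

dense_adjacency <- function(net) {
  A <- matrix(0, net$n_nodes, net$n_nodes)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges[e, 1L]; j <- net$edges[e, 2L]
    A[i, j] <- 1; A[j, i] <- 1
  }
  A
}

# eta_i = 1 - prod_j (1 - beta_i r_j p_j a_ij), scalar loops
eta_oracle <- function(p, params, A) {
  n <- nrow(A)
  eta <- numeric(n)
  for (i in seq_len(n)) {
    prod_term <- 1
    for (j in seq_len(n)) {
      if (A[i, j] == 1) {
        prod_term <- prod_term * (1 - params$beta[i] * params$r[j] * p[j])
      }
    }
    eta[i] <- 1 - prod_term
  }
  eta
}

# p_i(t+1) = (1 - mu_i) p_i + eta_i (1 - p_i), scalar loop
step_oracle <- function(p, params, A) {
  eta <- eta_oracle(p, params, A)
  (1 - params$mu) * p + eta * (1 - p)
}

# Erdos-Renyi-style random fixture (not necessarily connected)
random_net <- function(n, p_edge = 0.3) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  spread_network(pairs[keep, , drop = FALSE], n_nodes = n)
}

random_params <- function(n, low = 0.2, high = 0.7) {
  node_params(stats::runif(n, low, high), stats::runif(n, low, high),
              stats::runif(n, low, high))
}

# Parameters guaranteed to satisfy the chosen certificate on every node:
# scale the controlled parameter to 90% of its critical bound.
certified_params <- function(net, criterion = "row") {
  n <- net$n_nodes
  params <- random_params(n)
  if (criterion == "row") {
    bb <- beta_bar(params, net)
    params$beta <- ifelse(is.na(bb), params$beta, pmin(1, 0.9 * bb))
  } else {
    rb <- r_bar(params, net)
    params$r <- ifelse(is.na(rb), params$r, pmin(1, 0.9 * rb))
  }
  params
}
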