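#' Per-node spreading parameters
#'
#' Bundles the three heterogeneous node parameter vectors of the
#' contact-based SIS model: recovery probability `mu` (chance an infected
#' node recovers in one step), infection rate `beta` (susceptibility of the
#' node to an infectious contact) and contact probability `r` (chance the
#' node attempts contact with a neighbour). All entries are probabilities
#' in `[0, 1]`.
#'
#' @param mu,beta,r numeric vectors of equal length with entries in `[0, 1]`.
#' @return An object of class `node_params`: a list with elements `mu`,
#'   `beta`, `r` and `n_nodes`.
#' @examples
#' node_params(mu = c(0.5, 0.5), beta = c(0.3, 0.2), r = c(0.4, 0.6))
#' @export
node_params <- function(mu, beta, r) {
  stopifnot_probability(mu, "mu")
  stopifnot_probability(beta, "beta")
  stopifnot_probability(r, "r")
  if (length(beta) != length(mu) || length(r) != length(mu)) {
    stop("`mu`, `beta` and `r` must have equal length", call. = FALSE)
  }
  structure(
    list(mu = as.numeric(mu), beta = as.numeric(beta), r = as.numeric(r),
         n_nodes = length(mu)),
    class = "node_params"
  )
}

#' @export
print.node_params <- function(x, ...) {
  cat(sprintf("<node_params: %d nodes; mean mu %.3f, beta %.3f, r %.3f>\n",
              x$n_nodes, mean(x$mu), mean(x$beta), mean(x$r)))
  invisible(x)
}

#' Draw node parameters iid uniform
#'
#' Each of `mu`, `beta`, `r` is drawn independently and identically
#' uniform on `[low, high]`, independent across nodes and across the three
#' parameters. The defaults match the heterogeneous-population scenario
#' used throughout the experiment drivers.
#'
#' @param n_nodes number of nodes.
#' @param low,high bounds of the uniform interval, `0 <= low <= high <= 1`.
#' @param seed optional integer seed (caller's RNG state is restored).
#' @return A [node_params()].
#' @export
sample_node_params <- function(n_nodes, low = 0.2, high = 0.7, seed = NULL) {
  if (low > high || low < 0 || high > 1) {
    stop("need 0 <= low <= high <= 1", call. = FALSE)
  }
  with_seed(seed, node_params(
    mu = stats::runif(n_nodes, low, high),
    beta = stats::runif(n_nodes, low, high),
    r = stats::runif(n_nodes, low, high)
  ))
}

#' Read / write node parameters as CSV
#'
#' CSV with header `node,mu,beta,r`; the `node` column is 0-based in files
#' (rows may appear in any order), 1-based in memory.
#'
#' @param path file path.
#' @return `read_node_params` returns a [node_params()];
#'   `write_node_params` invisibly returns `path`.
#' @export
read_node_params <- function(path) {
  df <- utils::read.csv(path)
  need <- c("node", "mu", "beta", "r")
  if (!all(need %in% names(df))) {
    stop("parameter CSV must have header node,mu,beta,r", call. = FALSE)
  }
  df <- df[order(df$node), ]
  if (!identical(as.integer(df$node), seq_len(nrow(df)) - 1L)) {
    stop("`node` column must contain each 0-based index exactly once",
         call. = FALSE)
  }
  node_params(df$mu, df$beta, df$r)
}

#' @rdname read_node_params
#' @param params a [node_params()] to write.
#' @export
write_node_params <- function(params, path) {
  utils::write.csv(
    data.frame(node = seq_len(params$n_nodes) - 1L,
               mu = params$mu, beta = params$beta, r = params$r),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
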