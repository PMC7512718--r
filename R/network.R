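#' Construct a spreading-substrate network from an edge list
#'
#' A `spread_network` is an undirected simple graph: the substrate on which
#' the spreading process runs. Edges are stored once (as pairs `i < j`) and
#' additionally as a directed incidence list (both orientations, sorted by
#' target node) so that per-node products and sums over neighbours can be
#' computed in a single vectorised pass even for networks with millions of
#' nodes. Duplicate and reversed pairs are collapsed; self-loops are
#' rejected.
#'
#' @param edges two-column integer matrix (or data.frame) of 1-based node
#'   index pairs, one undirected edge per row.
#' @param n_nodes number of nodes; defaults to the largest index present.
#' @return An object of class `spread_network` with elements `n_nodes`,
#'   `edges` (deduplicated, `i < j`), `from`/`to` (directed incidence,
#'   each undirected edge appearing in both orientations, sorted by `from`)
#'   and `degree` (integer vector of neighbour counts).
#' @examples
#' net <- spread_network(rbind(c(1, 2), c(2, 3), c(1, 3)))
#' net$degree
#' @export
spread_network <- function(edges, n_nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have two columns", call. = FALSE)
  if (anyNA(edges) || any(edges != floor(edges))) {
    stop("edge endpoints must be integers", call. = FALSE)
  }
  storage.mode(edges) <- "integer"
  if (any(edges < 1L)) stop("node indices must be >= 1", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (is.null(n_nodes)) n_nodes <- if (nrow(edges)) max(edges) else 0L
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) && max(edges) > n_nodes) {
    stop("edge endpoint exceeds `n_nodes`", call. = FALSE)
  }
  # canonical orientation i < j, then deduplicate
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(lo + (hi - 1) * as.double(n_nodes))
  lo <- lo[keep]; hi <- hi[keep]
  from <- c(lo, hi)
  to <- c(hi, lo)
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  structure(
    list(
      n_nodes = n_nodes,
      edges = cbind(i = lo, j = hi),
      from = from,
      to = to,
      degree = tabulate(from, n_nodes)
    ),
    class = "spread_network"
  )
}

#' @export
print.spread_network <- function(x, ...) {
  cat(sprintf(
    "<spread_network: %d nodes, %d edges, degree range [%s, %s]>\n",
    x$n_nodes, nrow(x$edges),
    if (x$n_nodes) min(x$degree) else NA, if (x$n_nodes) max(x$degree) else NA
  ))
  invisible(x)
}

#' Sparse adjacency matrix of a network
#'
#' @param net a [spread_network()].
#' @return A symmetric sparse 0/1 `Matrix::sparseMatrix` with zero diagonal.
#' @export
adjacency_matrix <- function(net) {
  Matrix::sparseMatrix(
    i = net$from, j = net$to, x = 1,
    dims = c(net$n_nodes, net$n_nodes)
  )
}

#' Generate a preferential-attachment (Barabasi-Albert) network
#'
#' Grows a scale-free network: starting from `m0` seed nodes linked
#' randomly, each subsequent node attaches `m` edges to existing nodes
#' chosen with probability proportional to their current degree
#' (preferential attachment, implemented via the repeated-node-list method).
#' The `m` targets of a new node are distinct (draws producing a duplicate
#' target are rejected and resampled), so the graph is simple and every
#' non-seed node starts with degree exactly `m`.
#'
#' The seed graph is built as a uniformly random attachment tree on the
#' `m0` seed nodes (guaranteeing connectivity) plus each remaining seed
#' pair independently with probability 1/2. At large `n_nodes` the emergent
#' degree structure is insensitive to this choice.
#'
#' @param n_nodes total number of nodes (`>= m0`).
#' @param m0 seed-graph size (default 9).
#' @param m edges attached by each new node (default 3, `1 <= m <= m0`).
#' @param seed optional integer; when given, the generator runs under this
#'   seed and restores the caller's RNG state (same seed, same graph).
#' @return A [spread_network()].
#' @examples
#' net <- ba_network(200, m0 = 9, m = 3, seed = 1)
#' min(net$degree[10:200]) # every non-seed node attaches with 3 edges
#' @export
ba_network <- function(n_nodes, m0 = 9L, m = 3L, seed = NULL) {
  n_nodes <- as.integer(n_nodes); m0 <- as.integer(m0); m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (m > m0) stop("`m` must not exceed `m0`", call. = FALSE)
  if (m0 > n_nodes) stop("`m0` must not exceed `n_nodes`", call. = FALSE)
  with_seed(seed, {
    # --- seed graph: random attachment tree + extra pairs w.p. 1/2 ---
    perm <- sample.int(m0)
    se_i <- integer(m0 - 1L); se_j <- integer(m0 - 1L)
    for (k in seq_len(m0 - 1L)) {
      a <- perm[k + 1L]
      b <- perm[sample.int(k, 1L)]
      se_i[k] <- min(a, b); se_j[k] <- max(a, b)
    }
    if (m0 >= 2L) {
      prs <- utils::combn(m0, 2L)
      extra <- which(stats::runif(ncol(prs)) < 0.5)
      key <- function(i, j) i + (j - 1) * as.double(m0)
      have <- key(se_i, se_j)
      for (cc in extra) {
        a <- prs[1L, cc]; b <- prs[2L, cc]
        if (!(key(a, b) %in% have)) {
          se_i <- c(se_i, a); se_j <- c(se_j, b)
          have <- c(have, key(a, b))
        }
      }
    }
    n_seed <- length(se_i)
    total <- n_seed + m * max(0L, n_nodes - m0)
    ei <- integer(total); ej <- integer(total)
    ei[seq_len(n_seed)] <- se_i; ej[seq_len(n_seed)] <- se_j
    # --- growth: repeated-node list, one entry per half-edge ---
    rep_list <- integer(2L * total)
    len <- 2L * n_seed
    rep_list[seq_len(len)] <- c(se_i, se_j)
    epos <- n_seed
    if (n_nodes > m0) {
      for (v in (m0 + 1L):n_nodes) {
        repeat {
          tg <- rep_list[floor(stats::runif(m) * len) + 1L]
          if (!anyDuplicated(tg)) break
        }
        ei[(epos + 1L):(epos + m)] <- tg
        ej[(epos + 1L):(epos + m)] <- v
        epos <- epos + m
        rep_list[(len + 1L):(len + 2L * m)] <- c(tg, rep.int(v, m))
        len <- len + 2L * m
      }
    }
    spread_network(cbind(ei, ej), n_nodes = n_nodes)
  })
}

#' Read / write plain-text edge lists
#'
#' Format: one undirected edge per line as two whitespace- or tab-separated
#' 0-based node indices; lines starting with `#` are ignored. On read,
#' duplicate and reversed pairs are tolerated and collapsed; the writer
#' emits each edge once with `i < j`. In-memory node indices are 1-based
#' (R convention); the 0-based convention applies to files only.
#'
#' @param path file path.
#' @param n_nodes optional node count for `read_edge_list` (defaults to the
#'   largest index seen plus one).
#' @return `read_edge_list` returns a [spread_network()];
#'   `write_edge_list` invisibly returns `path`.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(spread_network(matrix(integer(0), ncol = 2L),
                          n_nodes = if (is.null(n_nodes)) 0L else n_nodes))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop(sprintf("malformed edge-list line(s): e.g. %s",
                 dQuote(lines[which(bad)[1L]])), call. = FALSE)
  }
  ij <- matrix(suppressWarnings(as.numeric(unlist(parts))),
               ncol = 2L, byrow = TRUE)
  if (anyNA(ij) || any(ij != floor(ij))) {
    stop("edge-list entries must be integers", call. = FALSE)
  }
  if (any(ij < 0)) stop("negative node index in edge list", call. = FALSE)
  if (any(ij[, 1L] == ij[, 2L])) {
    stop("self-loop entry in edge list", call. = FALSE)
  }
  spread_network(ij + 1L,
                 n_nodes = if (is.null(n_nodes)) max(ij) + 1L else n_nodes)
}

#' @rdname read_edge_list
#' @param net a [spread_network()] to write.
#' @export
write_edge_list <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d", net$edges[, 1L] - 1L, net$edges[, 2L] - 1L),
             con)
  invisible(path)
}

#' Deterministic toy networks for examples and tests
#'
#' Catalogue: `"path_2"` (two nodes, one edge), `"triangle"`,
#' `"star_k"` (hub plus `k` leaves, e.g. `"star_5"`), `"complete_k"`
#' (e.g. `"complete_4"`), and `"two_cliques_bridge"` (two 4-cliques joined
#' by a single bridge edge).
#'
#' @param name catalogue name.
#' @return A [spread_network()].
#' @examples
#' toy_network("star_5")$degree
#' @export
toy_network <- function(name) {
  if (name == "path_2") {
    return(spread_network(cbind(1L, 2L)))
  }
  if (name == "triangle") {
    return(spread_network(rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))))
  }
  if (grepl("^star_[0-9]+$", name)) {
    k <- as.integer(sub("star_", "", name))
    if (k < 1L) stop("star size must be >= 1", call. = FALSE)
    return(spread_network(cbind(1L, 2L:(k + 1L))))
  }
  if (grepl("^complete_[0-9]+$", name)) {
    k <- as.integer(sub("complete_", "", name))
    if (k < 2L) stop("complete-graph size must be >= 2", call. = FALSE)
    return(spread_network(t(utils::combn(k, 2L))))
  }
  if (name == "two_cliques_bridge") {
    e <- rbind(t(utils::combn(1:4, 2L)), t(utils::combn(5:8, 2L)), c(4L, 5L))
    return(spread_network(e))
  }
  stop(sprintf("unknown toy network %s", dQuote(name)), call. = FALSE)
}
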