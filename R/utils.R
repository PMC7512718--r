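# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialisation so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Sum `x` (one value per directed edge, ordered like net$from/net$to) into a
# length-n vector indexed by the grouping node vector `by`.
edge_aggregate <- function(net, x, by) {
  out <- numeric(net$n_nodes)
  if (length(x) == 0L) return(out)
  s <- rowsum(x, by, reorder = TRUE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

stopifnot_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be numeric in [0, 1] with no missing values", name),
         call. = FALSE)
  }
  invisible(x)
}
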