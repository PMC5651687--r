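# Independent oracles used across the suite.

# Closed-form weight after t solo correct training trials (coactivation 1,
# no other active units): W_t = 1 - (1 - beta)^t, derived by unrolling
# W <- W + beta * (1 - W) from W_0 = 0.
solo_weight <- function(t, beta) 1 - (1 - beta)^t

# Run t solo training trials of one relation through the engine: a two-unit
# network where the single comparison is always the correct one.
solo_train <- function(t, params) {
  net <- eq_network(c("S", "C"))
  tr <- trial_spec("S", "C", "C", phase = "train")
  for (i in seq_len(t)) net <- run_trial(net, tr, params)$network
  net$weights["S", "C"]
}

# Hand-rolled BFS shortest path length on a role graph, independent of the
# igraph-backed implementation.
bfs_path_length <- function(edges, from, to) {
  if (from == to) return(0L)
  frontier <- from
  seen <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character()
    for (v in frontier) {
      for (e in edges) {
        if (v %in% e) {
          other <- setdiff(e, v)
          if (other == to) return(d)
          if (!other %in% seen) nxt <- c(nxt, other)
        }
      }
    }
    seen <- c(seen, nxt)
    frontier <- unique(nxt)
  }
  Inf
}

expect_symmetric_bounded <- function(net, params = eq_params()) {
  w <- net$weights
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= params$weight_min & w <= params$weight_max))
}
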