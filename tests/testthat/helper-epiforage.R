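# Shared fixtures and independent oracles, built in code at test time.

# Breadth-first search over the neighbor table, independent of the
# shortest-path machinery used by build_environment().
bfs_distances <- function(env, from_id) {
  dist <- rep(NA_integer_, nrow(env$states))
  dist[from_id] <- 0L
  frontier <- from_id
  depth <- 0L
  while (length(frontier) > 0L) {
    depth <- depth + 1L
    nxt <- unique(as.vector(env$neighbors[frontier, ]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- depth
    frontier <- nxt
  }
  dist
}

# Scalar-loop Chebyshev nearest-key scan, independent of recall().
scan_nearest <- function(keys, query) {
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(keys))) {
    d <- max(abs(keys[i, ] - query))
    if (d < best_d) {
      best_d <- d
      best_i <- i
    }
  }
  list(index = best_i, distance = best_d)
}

grid_id <- function(env, x, y) env$id_grid[x + 1L, y + 1L]

# A bank pre-filled with given states (one write per state, action 1).
filled_bank <- function(encoding, capacity, state_ids, rule = "oldest") {
  bank <- memory_bank(capacity, encoding, rule)
  for (s in state_ids) write_event(bank, s, 1L, 1)
  bank
}

# A bank whose policy is deterministic-optimal: for every non-reward state,
# a single huge return on an action that decreases geodesic distance.
optimal_bank <- function(env, encoding) {
  bank <- memory_bank(nrow(env$states), encoding)
  dists <- env$geodesic[, env$reward_id]
  for (s in seq_len(nrow(env$states))) {
    if (s == env$reward_id) next
    nb <- env$neighbors[s, ]
    a <- which(dists[nb] == dists[s] - 1)[1]
    write_event(bank, s, a, 100)
  }
  bank
}
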