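#' State encodings
#'
#' A state encoding assigns every available state of a gridworld a unique
#' activity vector, used as the key space of the episodic memory. Two
#' *unstructured* encodings carry no relational information (onehot, random
#' uniform), and two *structured* encodings place states that are close in
#' the environment close in key space (place-cell population code, successor
#' representation).
#'
#' @name state_encoding
#' @return All constructors return a `state_encoding`: a list with `kind`,
#'   `table` (one row per available state, rownames `"x,y"`), and `params`.
NULL

new_state_encoding <- function(kind, table, env, params = list()) {
  rownames(table) <- paste0(env$states$x, ",", env$states$y)
  structure(list(kind = kind, table = table, layout = env$layout,
                 params = params),
            class = "state_encoding")
}

#' @export
print.state_encoding <- function(x, ...) {
  cat("<state_encoding>", x$kind, "|", nrow(x$table), "states x",
      ncol(x$table), "units\n")
  invisible(x)
}

#' @describeIn state_encoding Onehot keys: row i has a single 1 at index i.
#'   Any two distinct states are at Chebyshev distance exactly 1.
#' @param env A `gridworld`.
#' @export
onehot_encoding <- function(env) {
  n <- nrow(env$states)
  new_state_encoding("onehot", diag(n), env)
}

#' @describeIn state_encoding Random keys: entries drawn i.i.d. uniform on
#'   `[0, 1)`; dimension equals the number of available states so all
#'   encodings share key dimensionality. Reproducible from `seed` without
#'   disturbing the caller's RNG stream.
#' @param seed Integer seed for the random table.
#' @export
random_encoding <- function(env, seed) {
  n <- nrow(env$states)
  tab <- with_preserved_rng({
    set.seed(seed)
    matrix(stats::runif(n * n), nrow = n)
  })
  new_state_encoding("random", tab, env, params = list(seed = seed))
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' @describeIn state_encoding Place-cell population code: one Gaussian-tuned
#'   unit per available state, centred on that state's grid-normalised
#'   coordinates (grid units / 20). Unit i's activity at agent position
#'   (x, y) is `exp(-((x-xi)^2 + (y-yi)^2) / (2 sigma^2)) / (2 pi sigma^2)`.
#'   Fields ignore walls: activity depends only on Euclidean distance.
#' @param sigma Place-field width in grid-normalised units; the default 0.05
#'   is the size of one cell (1/20).
#' @export
place_cell_encoding <- function(env, sigma = 0.05) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  cx <- env$states$x / env$width
  cy <- env$states$y / env$width
  d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
  tab <- exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  new_state_encoding("place_cell", tab, env, params = list(sigma = sigma))
}

#' Random-walk transition matrix
#'
#' The state-transition matrix `T(s, s')` under the uniform random-walk
#' policy: each of the four actions has probability 1/4, and blocked actions
#' (walls, boundary) leave the agent in place, producing self-transitions.
#'
#' @param env A `gridworld`.
#' @return A row-stochastic `n x n` matrix over available states.
#' @export
random_walk_transitions <- function(env) {
  n <- nrow(env$states)
  tm <- matrix(0, n, n)
  for (a in 1:4) {
    idx <- cbind(seq_len(n), env$neighbors[, a])
    tm[idx] <- tm[idx] + 0.25
  }
  tm
}

#' @describeIn state_encoding Successor representation: state s's key is row
#'   s of `M = (I - gamma T)^{-1}`, the expected discounted future occupancy
#'   of every state under the random walk. Computed by a linear solve; each
#'   row sums to `1/(1-gamma)`. Sensitive to walls through `T`.
#' @param gamma Discount factor in `[0, 1)`; default 0.98.
#' @export
successor_encoding <- function(env, gamma = 0.98) {
  if (gamma < 0 || gamma >= 1) {
    stop("gamma must lie in [0, 1)", call. = FALSE)
  }
  tm <- random_walk_transitions(env)
  n <- nrow(tm)
  m <- solve(diag(n) - gamma * tm)
  new_state_encoding("successor", m, env, params = list(gamma = gamma))
}

#' Construct a state encoding by name
#'
#' @param env A `gridworld`.
#' @param kind One of `"onehot"`, `"random"`, `"place_cell"`, `"successor"`.
#' @param sigma,gamma,seed Parameters forwarded to the matching constructor.
#' @export
make_encoding <- function(env, kind = c("onehot", "random", "place_cell",
                                        "successor"),
                          sigma = 0.05, gamma = 0.98, seed = 1L) {
  switch(match.arg(kind),
    onehot = onehot_encoding(env),
    random = random_encoding(env, seed = seed),
    place_cell = place_cell_encoding(env, sigma = sigma),
    successor = successor_encoding(env, gamma = gamma)
  )
}

#' Chebyshev distance between activity vectors
#'
#' The L-infinity norm `max_i |p_i - q_i|`, the retrieval metric of the
#' episodic memory.
#'
#' @param p,q Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
chebyshev_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop("dimension mismatch: ", length(p), " vs ", length(q), call. = FALSE)
  }
  max(abs(p - q))
}

#' Pairwise Chebyshev distances of an encoding table
#'
#' Precomputes the full state-by-state Chebyshev distance matrix of an
#' encoding. Because memory keys and queries are always rows of the same
#' table, retrieval reduces to lookups in this matrix; `run_simulation()`
#' computes it once per run.
#'
#' @param encoding A `state_encoding`.
#' @return A symmetric `n x n` matrix with zero diagonal.
#' @export
encoding_distances <- function(encoding) {
  tab <- encoding$table
  n <- nrow(tab)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m <- abs(tab - matrix(tab[i, ], n, ncol(tab), byrow = TRUE))
    d[i, ] <- m[cbind(seq_len(n), max.col(m, ties.method = "first"))]
  }
  d
}

# Chebyshev distance from one query vector to each row of a key matrix,
# accumulated column-wise so no n x D temporary is materialised per call.
chebyshev_to_rows <- function(keys, query) {
  d <- abs(keys[, 1] - query[1])
  for (j in seq_len(ncol(keys))[-1]) {
    d <- pmax(d, abs(keys[, j] - query[j]))
  }
  unname(d)
}
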