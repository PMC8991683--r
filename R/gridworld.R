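#' Build a foraging gridworld environment
#'
#' Constructs one of the four 20x20 lattice environments used throughout the
#' package: `open_field` (no obstacles), `separated_field` (a vertical wall
#' with a single gap), `four_rooms` (a cross of walls with four doorways; 365
#' available states), and `tunnel` (a one-row corridor walled above and
#' below). Obstacle cells are removed from the state graph, so no edges
#' connect them to available states; actions that would move the agent into an
#' obstacle or off the grid return the current state unchanged.
#'
#' Every available state carries a step penalty of -0.01 except the single
#' reward state, worth +10; episodes are capped at 250 reward receipts.
#'
#' @param layout One of `"open_field"`, `"separated_field"`, `"four_rooms"`,
#'   `"tunnel"`.
#' @param reward_state Integer vector `c(x, y)` (0-indexed) for the reward
#'   location, or `NULL` for the layout default `(14, 14)`. Must not be an
#'   obstacle.
#' @return An object of class `gridworld`: a list with the state table
#'   (`states`, a tibble of `id`, `x`, `y`), the obstacle set, the action
#'   lookup (`neighbors`, states x 4 matrix of next-state ids in the order
#'   Down, Up, Left, Right), the geodesic distance matrix over available
#'   states, and the reward/penalty/step-cap parameters.
#' @examples
#' env <- build_environment("four_rooms")
#' nrow(env$states) # 365 available states
#' @export
build_environment <- function(layout = c("open_field", "separated_field",
                                         "four_rooms", "tunnel"),
                              reward_state = NULL) {
  layout <- match.arg(layout)
  w <- grid_side
  h <- grid_side
  obstacles <- layout_obstacles(layout)

  all_xy <- expand.grid(x = 0:(w - 1L), y = 0:(h - 1L))
  # order states row-major in y so ids are stable and documented
  all_xy <- all_xy[order(all_xy$y, all_xy$x), ]
  is_obstacle <- paste(all_xy$x, all_xy$y) %in% paste(obstacles[, 1], obstacles[, 2])
  states <- tibble::tibble(
    id = seq_len(sum(!is_obstacle)),
    x = all_xy$x[!is_obstacle],
    y = all_xy$y[!is_obstacle]
  )
  n <- nrow(states)
  stopifnot(n + nrow(obstacles) == w * h)

  # grid -> state-id lookup, NA on obstacles
  id_grid <- matrix(NA_integer_, nrow = w, ncol = h)
  id_grid[cbind(states$x + 1L, states$y + 1L)] <- states$id

  if (is.null(reward_state)) reward_state <- default_reward_state
  reward_state <- as.integer(reward_state)
  reward_id <- id_grid[reward_state[1] + 1L, reward_state[2] + 1L]
  if (is.na(reward_id)) {
    stop("reward_state (", reward_state[1], ",", reward_state[2],
         ") is an obstacle or off-grid", call. = FALSE)
  }

  # action semantics: Down (0,-1), Up (0,+1), Left (-1,0), Right (+1,0)
  deltas <- action_deltas()
  neighbors <- matrix(0L, nrow = n, ncol = 4L,
                      dimnames = list(NULL, rownames(deltas)))
  for (a in 1:4) {
    nx <- states$x + deltas[a, 1]
    ny <- states$y + deltas[a, 2]
    inside <- nx >= 0L & nx < w & ny >= 0L & ny < h
    target <- rep(NA_integer_, n)
    target[inside] <- id_grid[cbind(nx[inside] + 1L, ny[inside] + 1L)]
    blocked <- is.na(target)
    target[blocked] <- states$id[blocked] # bounce back
    neighbors[, a] <- target
  }

  # geodesic distances on the obstacle-respecting lattice graph
  edges <- do.call(rbind, lapply(1:4, function(a) {
    cbind(states$id, neighbors[, a])
  }))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::components(g)$no != 1L || igraph::vcount(g) != n) {
    stop("available-state graph of layout '", layout, "' is not connected",
         call. = FALSE)
  }
  geodesic <- igraph::distances(g)

  structure(
    list(
      layout = layout,
      width = w, height = h,
      obstacles = tibble::tibble(x = as.integer(obstacles[, 1]),
                                 y = as.integer(obstacles[, 2])),
      states = states,
      id_grid = id_grid,
      neighbors = neighbors,
      reward_state = reward_state,
      reward_id = reward_id,
      step_penalty = -0.01,
      reward_value = 10,
      max_steps = 250L,
      geodesic = geodesic
    ),
    class = "gridworld"
  )
}

#' Action direction vectors
#'
#' The four cardinal displacement vectors in the canonical action order
#' Down, Up, Left, Right.
#'
#' @return A 4 x 2 matrix with rows `(0,-1), (0,1), (-1,0), (1,0)`.
#' @export
action_deltas <- function() {
  matrix(c(0L, -1L, 0L, 1L, -1L, 0L, 1L, 0L), nrow = 4, byrow = TRUE,
         dimnames = list(c("down", "up", "left", "right"), c("dx", "dy")))
}

#' @export
print.gridworld <- function(x, ...) {
  cat("<gridworld>", x$layout, sprintf("%dx%d", x$width, x$height),
      "|", nrow(x$states), "available states,",
      nrow(x$obstacles), "obstacles | reward at (",
      x$reward_state[1], ",", x$reward_state[2], ")\n")
  invisible(x)
}

state_id_at <- function(env, xy) {
  id <- env$id_grid[xy[1] + 1L, xy[2] + 1L]
  if (is.na(id)) {
    stop("(", xy[1], ",", xy[2], ") is not an available state", call. = FALSE)
  }
  id
}

as_state_id <- function(env, state) {
  if (length(state) == 2L) state_id_at(env, as.integer(state)) else as.integer(state)
}

#' Take one step in a gridworld
#'
#' Applies the deterministic lattice dynamics: the agent moves to the adjacent
#' cell in the action's direction unless that cell is an obstacle or outside
#' the grid, in which case it stays in place.
#'
#' @param env A `gridworld`.
#' @param state A state: either a length-2 `c(x, y)` coordinate or a state id.
#' @param action Action index 1..4 (Down, Up, Left, Right) or one of the
#'   names `"down"`, `"up"`, `"left"`, `"right"`.
#' @return The resulting state as `c(x, y)` when `state` was a coordinate,
#'   otherwise as a state id.
#' @examples
#' env <- build_environment("open_field")
#' step_state(env, c(0, 0), "left") # blocked by the boundary: c(0, 0)
#' step_state(env, c(5, 5), "up")   # c(5, 6)
#' @export
step_state <- function(env, state, action) {
  if (is.character(action)) {
    action <- match(action, rownames(action_deltas()))
  }
  stopifnot(action %in% 1:4)
  as_coord <- length(state) == 2L
  id <- as_state_id(env, state)
  out <- env$neighbors[id, action]
  if (as_coord) c(env$states$x[out], env$states$y[out]) else out
}

#' Geodesic distance between two available states
#'
#' Shortest-path length (number of lattice edges) on the obstacle-respecting
#' state graph; obstacles have no edges, so paths must route around walls.
#'
#' @param env A `gridworld`.
#' @param from,to States as `c(x, y)` coordinates or state ids.
#' @return A non-negative integer path length.
#' @export
geodesic_distance <- function(env, from, to) {
  env$geodesic[as_state_id(env, from), as_state_id(env, to)]
}

#' Optimal average episode reward
#'
#' The best possible episode score averaged over uniformly random start
#' states: `R* = 10 - 0.01 * lambda`, where `lambda` is the mean geodesic
#' distance from the available states (excluding the reward state itself,
#' since episodes never start there) to the reward state. An optimal agent
#' accrues exactly one -0.01 receipt per step of the shortest path before
#' collecting the +10 reward.
#'
#' @param env A `gridworld`.
#' @return The optimal mean score `R*` in reward units.
#' @export
optimal_average_reward <- function(env) {
  d <- env$geodesic[, env$reward_id]
  lambda <- mean(d[-env$reward_id])
  env$reward_value + env$step_penalty * lambda
}
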