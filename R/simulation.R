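#' Discounted Monte-Carlo returns
#'
#' Computes `G_t = sum_k gamma^k r_{t+k}` for every timestep by the backward
#' recursion `G_t = r_t + gamma * G_{t+1}`.
#'
#' @param rewards Numeric reward sequence of an episode.
#' @param gamma Discount factor in `[0, 1)`.
#' @return Numeric vector of returns, one per timestep.
#' @examples
#' compute_returns(c(-0.01, 10), gamma = 0.98) # c(9.79, 10)
#' @export
compute_returns <- function(rewards, gamma) {
  n <- length(rewards)
  if (n == 0L) stop("empty reward sequence", call. = FALSE)
  if (any(!is.finite(rewards))) stop("non-finite rewards", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  g <- numeric(n)
  g[n] <- rewards[n]
  if (n > 1L) {
    for (t in (n - 1L):1L) g[t] <- rewards[t] + gamma * g[t + 1L]
  }
  g
}

#' Simulation configuration
#'
#' Bundles every knob of a single simulation run. Defaults follow the study
#' conditions: discount 0.98, 5000 episodes, 250-step episode cap, memory
#' snapshots taken every `snapshot_every` episodes and densely (every
#' episode) over the final `snapshot_final_window` episodes so policy-field
#' averages can be formed after the bank has reached capacity.
#'
#' @param layout Environment layout name (see [build_environment()]).
#' @param encoding Encoding kind: `"onehot"`, `"random"`, `"place_cell"`,
#'   `"successor"`.
#' @param capacity_fraction Memory capacity as a fraction of available
#'   states, in `(0, 1]`.
#' @param forgetting_rule `"oldest"` or `"random"`.
#' @param forget_on,tie_break Memory-bank timestamp and tie-breaking
#'   options (see [memory_bank()]); defaults `"update"` and `"first"`.
#' @param gamma Discount factor (also the successor-representation
#'   discount).
#' @param sigma Place-field width for the place-cell encoding.
#' @param n_episodes Number of episodes per run.
#' @param seed Integer seed; the run draws start states, actions and
#'   random-rule victims from a single stream seeded once.
#' @param encoding_seed Seed for the random encoding table (defaults to
#'   `seed`).
#' @param reward_state Optional `c(x, y)` reward location override.
#' @param snapshot_every Sparse snapshot cadence in episodes (0 = none).
#' @param snapshot_final_window Number of final episodes snapshotted densely.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(layout = "open_field", encoding = "successor",
                              capacity_fraction = 1, forgetting_rule = "oldest",
                              forget_on = "update", tie_break = "first",
                              gamma = 0.98, sigma = 0.05, n_episodes = 5000L,
                              seed = 1L, encoding_seed = NULL,
                              reward_state = NULL, snapshot_every = 50L,
                              snapshot_final_window = 400L) {
  stopifnot(n_episodes >= 1, gamma >= 0, gamma < 1,
            capacity_fraction > 0, capacity_fraction <= 1)
  structure(list(layout = layout, encoding = encoding,
                 capacity_fraction = capacity_fraction,
                 forgetting_rule = forgetting_rule,
                 forget_on = forget_on, tie_break = tie_break, gamma = gamma,
                 sigma = sigma, n_episodes = as.integer(n_episodes),
                 seed = as.integer(seed),
                 encoding_seed = if (is.null(encoding_seed)) as.integer(seed)
                                 else as.integer(encoding_seed),
                 reward_state = reward_state,
                 snapshot_every = as.integer(snapshot_every),
                 snapshot_final_window = as.integer(snapshot_final_window)),
            class = "simulation_config")
}

#' Run a single foraging episode
#'
#' The agent starts at a uniformly random available state (excluding the
#' reward state), receives the current state's reward at each timestep, and
#' terminates on reaching the reward or after 250 receipts. While the bank
#' holds at least one entry, each step recalls the nearest memory to the
#' current state and samples an action from the softmax policy over its
#' return slots; with an empty bank the agent takes uniform random actions.
#' The bank is never written during an episode (storage happens at episode
#' end via [store_episode()]), so the policy within an episode is frozen.
#'
#' @param env A `gridworld`.
#' @param bank A `memory_bank` keyed by an encoding of `env` (may be empty).
#' @param start_id Optional fixed start (state id or `c(x, y)`).
#' @return An `episode_log` list: `states` (ids visited, one per receipt),
#'   `actions`, `rewards`, `raw_score`, `success`, `steps` (actions taken;
#'   250 for failed episodes), and recall statistics (`n_recalls`,
#'   `n_exact`, `nonexact_distance_sum`, `n_nonexact`,
#'   `mean_recall_distance`).
#' @export
run_episode <- function(env, bank, start_id = NULL) {
  nbr <- env$neighbors
  rid <- env$reward_id
  max_receipts <- env$max_steps
  n_states <- nrow(env$states)

  empty <- bank$n == 0L
  plain_recall <- bank$tie_break == "first" && bank$forget_on == "update"
  if (!empty) {
    ensure_bank_distances(bank)
    if (plain_recall) {
      # the bank is frozen within an episode, so capture it once
      nb <- bank$n
      stored_dist <- bank$dist[bank$sid[seq_len(nb)], , drop = FALSE]
      posv <- bank$pos
      vals <- bank$val[seq_len(nb), , drop = FALSE]
      vals[is.na(vals)] <- 0
    }
  }

  if (is.null(start_id)) {
    s <- sample.int(n_states - 1L, 1L)
    if (s >= rid) s <- s + 1L # uniform over available states except s*
  } else {
    s <- as_state_id(env, start_id)
  }

  states <- integer(max_receipts)
  actions <- integer(max_receipts)
  rec_d <- numeric(max_receipts)
  rec_e <- logical(max_receipts)
  t <- 0L
  repeat {
    t <- t + 1L
    states[t] <- s
    if (s == rid || t == max_receipts) break
    if (empty) {
      a <- sample.int(4L, 1L)
      rec_d[t] <- NA_real_
    } else {
      if (plain_recall) {
        j <- posv[s]
        if (j > 0L) {
          d <- 0
        } else {
          dc <- stored_dist[, s]
          j <- which.min(dc)
          d <- dc[j]
        }
        v <- vals[j, ] # NA slots already zero-filled in the frozen copy
      } else {
        rec <- recall(bank, query_id = s)
        d <- rec$distance
        v <- rec$values
        v[is.na(v)] <- 0
      }
      a <- sample.int(4L, 1L, prob = exp(v - max(v)))
      rec_d[t] <- d
      rec_e[t] <- d == 0
    }
    actions[t] <- a
    s <- nbr[s, a]
  }

  success <- s == rid
  n_act <- t - 1L
  rewards <- rep(env$step_penalty, t)
  if (success) rewards[t] <- env$reward_value

  if (empty || n_act == 0L) {
    n_recalls <- 0L; n_exact <- 0L; nonexact_sum <- 0; n_nonexact <- 0L
    mean_d <- NA_real_
  } else {
    dd <- rec_d[seq_len(n_act)]
    ee <- rec_e[seq_len(n_act)]
    n_recalls <- n_act
    n_exact <- sum(ee)
    n_nonexact <- n_recalls - n_exact
    nonexact_sum <- sum(dd[!ee])
    mean_d <- mean(dd)
  }

  structure(list(
    states = states[seq_len(t)],
    actions = actions[seq_len(n_act)],
    rewards = rewards,
    raw_score = sum(rewards),
    success = success,
    steps = if (success) n_act else max_receipts,
    n_recalls = n_recalls, n_exact = n_exact,
    nonexact_distance_sum = nonexact_sum, n_nonexact = n_nonexact,
    mean_recall_distance = mean_d
  ), class = "episode_log")
}

#' Store a finished episode in the memory bank
#'
#' Computes the Monte-Carlo returns of the episode and writes one
#' state-action-return event per timestep, in ascending time order, so that
#' a state-action pair revisited within the episode ends up holding the most
#' recent return. The terminal state (where no action was taken) is not
#' written.
#'
#' @param bank A `memory_bank` (mutated in place).
#' @param episode An `episode_log` from [run_episode()].
#' @param gamma Discount factor.
#' @return The bank, invisibly.
#' @export
store_episode <- function(bank, episode, gamma = 0.98) {
  g <- compute_returns(episode$rewards, gamma)
  for (t in seq_along(episode$actions)) {
    write_event(bank, episode$states[t], episode$actions[t], g[t])
  }
  invisible(bank)
}

#' Run a full multi-episode simulation
#'
#' Builds a fresh environment, encoding and empty memory bank from the
#' config, then alternates [run_episode()] and [store_episode()] for
#' `n_episodes` episodes, logging per-episode scores, success flags, recall
#' statistics and forgetting events, and snapshotting the bank at the
#' configured cadence. Fully reproducible: a single RNG stream is seeded
#' once from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param env Optional prebuilt `gridworld` (must match `config$layout`).
#' @param distances Optional precomputed [encoding_distances()] matrix,
#'   reusable across runs that share an environment and encoding.
#' @return A `simulation_log`: `episodes` (a tibble with one row per
#'   episode), `forget_tally` (integer vector of forgetting events by
#'   forgotten state id), `snapshots` (list of `bank_snapshot()`s with their
#'   episode number), `final_bank`, and the `config`.
#' @export
run_simulation <- function(config, env = NULL, distances = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (is.null(env)) {
    env <- build_environment(config$layout, config$reward_state)
  } else {
    stopifnot(env$layout == config$layout)
  }
  enc <- make_encoding(env, config$encoding, sigma = config$sigma,
                       gamma = config$gamma, seed = config$encoding_seed)
  if (is.null(distances)) distances <- encoding_distances(enc)
  n_avail <- nrow(env$states)
  cap <- capacity_for(config$capacity_fraction, n_avail)
  bank <- memory_bank(cap, enc, config$forgetting_rule,
                      forget_on = config$forget_on,
                      tie_break = config$tie_break, distances = distances)

  ne <- config$n_episodes
  raw_score <- numeric(ne); success <- logical(ne); steps <- integer(ne)
  n_recalls <- integer(ne); n_exact <- integer(ne)
  nonexact_sum <- numeric(ne); n_nonexact <- integer(ne)
  n_forgets <- integer(ne); bank_n <- integer(ne)
  snapshots <- list()
  dense_from <- ne - config$snapshot_final_window + 1L

  forgets_before <- 0L
  for (i in seq_len(ne)) {
    ep <- run_episode(env, bank)
    store_episode(bank, ep, config$gamma)
    raw_score[i] <- ep$raw_score
    success[i] <- ep$success
    steps[i] <- ep$steps
    n_recalls[i] <- ep$n_recalls
    n_exact[i] <- ep$n_exact
    nonexact_sum[i] <- ep$nonexact_distance_sum
    n_nonexact[i] <- ep$n_nonexact
    total_forgets <- sum(bank$forget_tally)
    n_forgets[i] <- total_forgets - forgets_before
    forgets_before <- total_forgets
    bank_n[i] <- bank$n
    take_snap <- (i >= dense_from) ||
      (config$snapshot_every > 0L && i %% config$snapshot_every == 0L)
    if (take_snap) {
      snap <- bank_snapshot(bank)
      snap$episode <- i
      snapshots[[length(snapshots) + 1L]] <- snap
    }
  }

  structure(list(
    episodes = tibble::tibble(
      episode = seq_len(ne), raw_score = raw_score, success = success,
      steps = steps, n_recalls = n_recalls, n_exact = n_exact,
      nonexact_distance_sum = nonexact_sum, n_nonexact = n_nonexact,
      mean_recall_distance = ifelse(n_recalls > 0, nonexact_sum / n_recalls,
                                    NA_real_),
      n_forgets = n_forgets, bank_size = bank_n
    ),
    forget_tally = bank$forget_tally,
    snapshots = snapshots,
    final_bank = bank,
    n_available = n_avail,
    capacity = cap,
    config = config
  ), class = "simulation_log")
}

#' @export
print.simulation_log <- function(x, ...) {
  cat("<simulation_log>", x$config$layout, "/", x$config$encoding,
      sprintf("| capacity %d/%d (%s rule) | %d episodes | success rate %.2f\n",
              x$capacity, x$n_available, x$config$forgetting_rule,
              nrow(x$episodes), mean(x$episodes$success)))
  invisible(x)
}

#' Random-walk baseline scores
#'
#' Runs memory-free episodes in which every action is uniform random, under
#' the same start, reward and termination rules as the episodic agent; used
#' as the chance-level reference for normalised performance. Implemented as
#' a standalone loop, independent of [run_episode()].
#'
#' @param env A `gridworld`.
#' @param n_episodes Number of episodes.
#' @param seed Integer seed.
#' @return Numeric vector of raw episode scores.
#' @export
random_walk_baseline <- function(env, n_episodes, seed) {
  set.seed(seed)
  nbr <- env$neighbors
  rid <- env$reward_id
  maxr <- env$max_steps
  n_states <- nrow(env$states)
  pen <- env$step_penalty
  scores <- numeric(n_episodes)
  for (i in seq_len(n_episodes)) {
    s <- sample.int(n_states - 1L, 1L)
    if (s >= rid) s <- s + 1L
    t <- 0L
    repeat {
      t <- t + 1L
      if (s == rid) {
        scores[i] <- pen * (t - 1L) + env$reward_value
        break
      }
      if (t == maxr) {
        scores[i] <- pen * maxr
        break
      }
      s <- nbr[s, sample.int(4L, 1L)]
    }
  }
  scores
}
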