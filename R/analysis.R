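#' Normalised performance
#'
#' Rescales mean raw episode score to a percentage of the optimal average:
#' `100 * (mean(raw) + 2.5) / (R* + 2.5)`, where -2.5 is the score of a
#' fully failed episode (250 receipts of -0.01) and `R*` is
#' [optimal_average_reward()]. An all-fail run maps to 0%, an optimal agent
#' to 100%.
#'
#' @param raw_scores Numeric vector of raw episode scores.
#' @param env The `gridworld` the scores were collected in.
#' @return A percentage (scalar).
#' @export
normalize_performance <- function(raw_scores, env) {
  if (length(raw_scores) == 0L) stop("empty score sequence", call. = FALSE)
  r_star <- optimal_average_reward(env)
  floor_score <- env$step_penalty * env$max_steps
  100 * (mean(raw_scores) - floor_score) / (r_star - floor_score)
}

#' Preferred direction of a policy
#'
#' The policy-weighted average of the cardinal displacement vectors:
#' `z = sum_a pi(a) * dir(a)` with `dir` rows (0,-1), (0,1), (-1,0), (1,0)
#' for Down, Up, Left, Right. The uniform policy maps to (0, 0); a
#' deterministic policy to a unit cardinal vector.
#'
#' @param policy Probability vector over the four actions.
#' @return Length-2 numeric `c(x, y)`.
#' @export
preferred_direction <- function(policy) {
  stopifnot(length(policy) == 4L)
  z <- as.numeric(policy %*% action_deltas())
  names(z) <- c("x", "y")
  z
}

#' Shannon entropy of a policy
#'
#' `H = -sum_a pi(a) log pi(a)` in nats, with `0 log 0 := 0`; ranges from 0
#' (deterministic) to `log(4)` (uniform).
#'
#' @param policy Probability vector over the four actions.
#' @return Non-negative scalar.
#' @export
policy_entropy <- function(policy) {
  p <- policy[policy > 0]
  -sum(p * log(p))
}

#' Policy map of a memory bank
#'
#' Queries the bank with every available state's encoding (the same
#' nearest-key recall used for behaviour, with no special-casing of absent
#' states) and returns the per-state softmax policy together with its
#' preferred direction and entropy.
#'
#' @param bank A non-empty `memory_bank`.
#' @param env The `gridworld` whose states are queried.
#' @return A tibble with one row per available state: `state_id`, `x`, `y`,
#'   action probabilities `down`, `up`, `left`, `right`, direction
#'   components `zx`, `zy`, and `entropy`.
#' @export
policy_map <- function(bank, env) {
  n <- nrow(env$states)
  probs <- matrix(NA_real_, n, 4L)
  for (s in seq_len(n)) {
    rec <- recall(bank, query_id = s)
    probs[s, ] <- policy_from_values(rec$values)
  }
  dirs <- probs %*% action_deltas()
  plogp <- ifelse(probs > 0, probs * log(probs), 0)
  tibble::tibble(
    state_id = seq_len(n), x = env$states$x, y = env$states$y,
    down = probs[, 1], up = probs[, 2], left = probs[, 3], right = probs[, 4],
    zx = dirs[, 1], zy = dirs[, 2],
    entropy = -rowSums(plogp)
  )
}

#' Average policy fields over late-run memory snapshots
#'
#' Reconstructs the bank from each of the last `window` snapshots of a run,
#' computes its [policy_map()], and averages the preferred-direction
#' components and the entropy per state across snapshots — the standard way
#' to summarise the policy once the bank has reached its capacity limit.
#'
#' @param snapshots List of snapshots from a `simulation_log`.
#' @param env The `gridworld`.
#' @param encoding The `state_encoding` used by the run.
#' @param window Number of trailing snapshots to average (default: all).
#' @param distances Optional precomputed [encoding_distances()] matrix.
#' @return A tibble per state: `x`, `y`, mean `zx`, `zy`, mean `entropy`.
#' @export
average_policy_fields <- function(snapshots, env, encoding, window = NULL,
                                  distances = NULL) {
  if (is.null(window)) window <- length(snapshots)
  if (length(snapshots) < window) {
    stop("fewer snapshots (", length(snapshots), ") than window (", window,
         ")", call. = FALSE)
  }
  if (is.null(distances)) distances <- encoding_distances(encoding)
  use <- snapshots[seq.int(length(snapshots) - window + 1L, length(snapshots))]
  maps <- purrr::map(use, function(snap) {
    bank <- bank_from_snapshot(snap, encoding, distances = distances)
    policy_map(bank, env)
  })
  dplyr::bind_rows(maps) |>
    dplyr::group_by(.data$state_id, .data$x, .data$y) |>
    dplyr::summarise(zx = mean(.data$zx), zy = mean(.data$zy),
                     entropy = mean(.data$entropy), .groups = "drop")
}

#' Retrieval match statistics split by episode outcome
#'
#' Aggregates the per-step recall records of a run into, per outcome group
#' (successful vs failed episodes): the percentage of recall events whose
#' nearest key matched the queried state exactly, and the mean Chebyshev
#' distance of the non-matching recalls. Groups without non-matching events
#' report `NA` (not zero) for the distance.
#'
#' @param log A `simulation_log` (or its `episodes` tibble).
#' @return A tibble with columns `success`, `n_events`, `exact_pct`,
#'   `mean_nonmatch_distance`.
#' @export
match_statistics <- function(log) {
  ep <- if (inherits(log, "simulation_log")) log$episodes else log
  ep |>
    dplyr::filter(.data$n_recalls > 0) |>
    dplyr::group_by(success = .data$success) |>
    dplyr::summarise(
      n_events = sum(.data$n_recalls),
      exact_pct = 100 * sum(.data$n_exact) / sum(.data$n_recalls),
      mean_nonmatch_distance = ifelse(sum(.data$n_nonexact) > 0,
                                      sum(.data$nonexact_distance_sum) /
                                        sum(.data$n_nonexact), NA_real_),
      .groups = "drop"
    )
}

#' Sample trajectory lengths from frozen memory snapshots
#'
#' For each snapshot, reconstructs the bank and draws `per_snapshot`
#' read-only episodes (no storage, so the bank is unchanged) from uniformly
#' random start states, recording the number of steps taken, capped at 250.
#'
#' @param snapshots List of snapshots from a `simulation_log`.
#' @param env The `gridworld`.
#' @param encoding The run's `state_encoding`.
#' @param per_snapshot Episodes sampled per snapshot (default 5).
#' @param seed Integer seed.
#' @param distances Optional precomputed [encoding_distances()] matrix.
#' @return A tibble: `snapshot_episode`, `sample`, `steps`, `success`.
#' @export
sample_trajectories <- function(snapshots, env, encoding, per_snapshot = 5L,
                                seed = 1L, distances = NULL) {
  if (length(snapshots) == 0L) stop("no snapshots supplied", call. = FALSE)
  if (is.null(distances)) distances <- encoding_distances(encoding)
  set.seed(seed)
  purrr::map_dfr(snapshots, function(snap) {
    bank <- bank_from_snapshot(snap, encoding, distances = distances)
    res <- purrr::map(seq_len(per_snapshot), function(k) run_episode(env, bank))
    tibble::tibble(
      snapshot_episode = if (is.null(snap$episode)) NA_integer_ else snap$episode,
      sample = seq_len(per_snapshot),
      steps = purrr::map_int(res, "steps"),
      success = purrr::map_lgl(res, "success")
    )
  })
}

#' Per-state forgetting incidence
#'
#' Converts per-run tallies of forgetting events (counts of how often each
#' state was overwritten) into per-run frequencies (each summing to 1) and
#' averages them across runs.
#'
#' @param tallies A list of integer vectors of per-state forget counts (or
#'   of `simulation_log`s).
#' @param env The `gridworld` (for state coordinates).
#' @return A tibble: `state_id`, `x`, `y`, `frequency` (mean across runs).
#' @export
forgetting_incidence <- function(tallies, env) {
  freqs <- purrr::map(tallies, function(tl) {
    if (inherits(tl, "simulation_log")) tl <- tl$forget_tally
    total <- sum(tl)
    if (total == 0L) {
      stop("run with zero forgetting events (unlimited capacity?)",
           call. = FALSE)
    }
    tl / total
  })
  tibble::tibble(
    state_id = env$states$id, x = env$states$x, y = env$states$y,
    frequency = Reduce(`+`, freqs) / length(freqs)
  )
}

#' Relative forgetting incidence of the oldest rule vs the random rule
#'
#' The difference field `mean(oldest) - mean(random)` of per-state forgetting
#' frequencies: negative values mark states the oldest-entry rule preserves
#' relative to random forgetting (bottlenecks, states near the reward),
#' positive values states it discards more readily (periphery).
#'
#' @param oldest_tallies,random_tallies Lists of per-run tallies (or
#'   `simulation_log`s) under each rule.
#' @param env The `gridworld`.
#' @return A tibble: `state_id`, `x`, `y`, `oldest`, `random`, `difference`.
#' @export
incidence_difference <- function(oldest_tallies, random_tallies, env) {
  fo <- forgetting_incidence(oldest_tallies, env)
  fr <- forgetting_incidence(random_tallies, env)
  dplyr::mutate(
    dplyr::rename(fo, oldest = "frequency"),
    random = fr$frequency,
    difference = .data$oldest - .data$random
  )
}

#' Welch's unequal-variances t-test with Bonferroni correction
#'
#' Computes the Welch statistic `t = (mean(x) - mean(y)) / sqrt(sx2/nx +
#' sy2/ny)` with Welch-Satterthwaite degrees of freedom, the p-value from
#' the t distribution (two-sided or one-sided), and a Bonferroni-corrected
#' p-value `min(1, m * p)` for `m` planned comparisons. If both samples have
#' zero variance and equal means the statistic is undefined and `p = 1` by
#' convention.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param alternative `"two.sided"`, `"greater"` (mean of `x` exceeds mean
#'   of `y`) or `"less"`.
#' @param m_comparisons Number of planned comparisons for the Bonferroni
#'   correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `p_bonferroni`.
#' @export
welch_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                       m_comparisons = 1L) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) {
    delta <- mean(x) - mean(y)
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- length(x) + length(y) - 2
    p <- if (delta == 0) 1 else switch(alternative,
      two.sided = 0,
      greater = as.numeric(delta < 0),
      less = as.numeric(delta > 0)
    )
  } else {
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    p <- switch(alternative,
      two.sided = 2 * stats::pt(-abs(tstat), df),
      greater = stats::pt(tstat, df, lower.tail = FALSE),
      less = stats::pt(tstat, df)
    )
  }
  tibble::tibble(statistic = tstat, df = df, p_value = p,
                 p_bonferroni = min(1, m_comparisons * p))
}
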