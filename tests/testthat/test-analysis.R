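open <- build_environment("open_field")

test_that("performance normalisation is anchored and affine", {
  expect_equal(normalize_performance(rep(-2.5, 10), open), 0)
  r_star <- optimal_average_reward(open)
  expect_equal(normalize_performance(rep(r_star, 5), open), 100)
  mid <- (-2.5 + r_star) / 2
  expect_equal(normalize_performance(c(mid, mid), open), 50)
  # affine and order-preserving in the mean raw score
  lo <- normalize_performance(rep(1, 3), open)
  hi <- normalize_performance(rep(2, 3), open)
  expect_gt(hi, lo)
  expect_equal(normalize_performance(rep(1.5, 3), open), (lo + hi) / 2)
  expect_error(normalize_performance(numeric(0), open))
})

test_that("preferred direction is the policy-weighted cardinal average", {
  expect_equal(preferred_direction(c(0.25, 0.25, 0.25, 0.25)),
               c(x = 0, y = 0))
  expect_equal(preferred_direction(c(0, 1, 0, 0)), c(x = 0, y = 1)) # Up
  expect_equal(preferred_direction(c(1, 0, 0, 0)), c(x = 0, y = -1)) # Down
  expect_equal(preferred_direction(c(0, 0.5, 0, 0.5)), c(x = 0.5, y = 0.5))
  # norm never exceeds 1
  set.seed(14)
  for (k in 1:20) {
    p <- stats::rexp(4)
    p <- p / sum(p)
    expect_lte(sqrt(sum(preferred_direction(p)^2)), 1 + 1e-12)
  }
})

test_that("policy entropy spans [0, log 4] with the right anchors", {
  expect_equal(policy_entropy(rep(0.25, 4)), log(4))
  expect_equal(policy_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(policy_entropy(c(0.5, 0.5, 0, 0)), log(2))
  set.seed(15)
  for (k in 1:20) {
    p <- stats::rexp(4)
    p <- p / sum(p)
    h <- policy_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(4) + 1e-12)
  }
})

test_that("policy maps query every state through ordinary recall", {
  enc <- successor_encoding(open)
  bank <- memory_bank(400, enc)
  write_event(bank, grid_id(open, 13, 14), 4L, 9.79)
  write_event(bank, grid_id(open, 5, 5), 2L, 1.2)
  pm <- policy_map(bank, open)
  expect_equal(nrow(pm), 400)
  probs <- as.matrix(pm[, c("down", "up", "left", "right")])
  expect_equal(rowSums(probs), rep(1, 400), tolerance = 1e-12)
  # a stored state reproduces the softmax of its stored values
  row <- pm[pm$x == 13 & pm$y == 14, ]
  expect_equal(as.numeric(row[, c("down", "up", "left", "right")]),
               unname(policy_from_values(c(NA, NA, NA, 9.79))))
  expect_equal(c(row$zx, row$zy),
               unname(preferred_direction(policy_from_values(c(NA, NA, NA, 9.79)))))
})

test_that("field averaging is idempotent and windowed correctly", {
  enc <- successor_encoding(open)
  dists <- encoding_distances(enc)
  bank <- memory_bank(400, enc, distances = dists)
  set.seed(16)
  for (k in 1:60) write_event(bank, sample.int(400, 1), sample.int(4, 1), runif(1, 0, 5))
  snap <- bank_snapshot(bank)
  single <- average_policy_fields(list(snap), open, enc, distances = dists)
  pm <- policy_map(bank_from_snapshot(snap, enc, distances = dists), open)
  expect_equal(single$zx, pm$zx)
  expect_equal(single$entropy, pm$entropy)
  # identical snapshots average to themselves
  triple <- average_policy_fields(list(snap, snap, snap), open, enc,
                                  window = 3, distances = dists)
  expect_equal(triple$entropy, single$entropy)
  expect_true(all(triple$entropy >= 0 & triple$entropy <= log(4) + 1e-12))
  expect_error(average_policy_fields(list(snap), open, enc, window = 2),
               "snapshots")
})

test_that("match statistics split exact and non-exact recalls by outcome", {
  cfg <- simulation_config("open_field", "onehot", capacity_fraction = 0.5,
                           n_episodes = 80, seed = 17, snapshot_every = 0,
                           snapshot_final_window = 0)
  log <- run_simulation(cfg)
  ms <- match_statistics(log)
  expect_true(all(ms$exact_pct >= 0 & ms$exact_pct <= 100))
  # onehot geometry: any non-exact nearest key sits at distance exactly 1
  expect_true(all(ms$mean_nonmatch_distance[!is.na(ms$mean_nonmatch_distance)] == 1))

  # a fully covered unlimited bank recalls exactly everywhere
  enc <- onehot_encoding(open)
  bank <- memory_bank(400, enc)
  for (s in seq_len(400)) write_event(bank, s, 1L, 1)
  set.seed(18)
  eps <- purrr::map(1:10, ~ run_episode(open, bank))
  expect_true(all(purrr::map_int(eps, "n_exact") ==
                    purrr::map_int(eps, "n_recalls")))
})

test_that("trajectory sampling is read-only and tracks the optimal length", {
  enc <- successor_encoding(open)
  dists <- encoding_distances(enc)
  bank <- optimal_bank(open, enc)
  snap <- bank_snapshot(bank)
  tr <- sample_trajectories(list(snap, snap), open, enc, per_snapshot = 40,
                            seed = 19, distances = dists)
  expect_equal(nrow(tr), 80)
  expect_true(all(tr$steps >= 1 & tr$steps <= 250))
  expect_true(all(tr$success))
  # deterministic-optimal policies walk the geodesic: mean length ~ lambda
  lambda <- mean(open$geodesic[-open$reward_id, open$reward_id])
  se <- stats::sd(tr$steps) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$steps) - lambda), 4 * se + 0.5)
  # the sampled-from snapshot is untouched
  expect_identical(bank_snapshot(bank), snap)
})

test_that("forgetting incidence normalises per run and differences cancel", {
  t1 <- c(rep(0L, 396), 5L, 5L, 0L, 10L)
  t2 <- c(rep(1L, 400))
  fi <- forgetting_incidence(list(t1, t2), open)
  expect_equal(sum(fi$frequency), 1)
  expect_error(forgetting_incidence(list(rep(0L, 400)), open), "zero")

  dif <- incidence_difference(list(t1), list(t2), open)
  expect_equal(sum(dif$difference), 0, tolerance = 1e-12)
  expect_equal(dif$oldest - dif$random, dif$difference)
})

test_that("uniform victim selection yields uniform forgetting incidence", {
  enc <- random_encoding(open, seed = 23)
  bank <- memory_bank(50, enc, "random")
  # symmetric write load over a fixed pool of states, ~1e4 forget events
  pool <- 1:100
  set.seed(24)
  for (k in 1:23000) write_event(bank, sample(pool, 1), 1L, 1)
  counts <- bank$forget_tally[pool]
  expect_gt(sum(counts), 1e4)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.01)
})

test_that("welch test matches stats::t.test and applies Bonferroni", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  ours <- welch_test(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  one <- welch_test(x, y, alternative = "greater")
  ref1 <- stats::t.test(x, y, alternative = "greater")
  expect_equal(one$p_value, ref1$p.value, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # Bonferroni: m = 1 leaves p, larger m scales and caps at 1
  expect_equal(welch_test(x, y, m_comparisons = 1)$p_bonferroni, ours$p_value)
  expect_equal(welch_test(x, y, m_comparisons = 3)$p_bonferroni,
               min(1, 3 * ours$p_value))
  expect_error(welch_test(1, c(1, 2)))
})

test_that("moderate forgetting with structured keys raises policy coherence", {
  env <- open
  enc <- successor_encoding(env)
  dists <- encoding_distances(enc)
  run1 <- function(fr) {
    cfg <- simulation_config("open_field", "successor", capacity_fraction = fr,
                             n_episodes = 600, seed = 11, snapshot_every = 0,
                             snapshot_final_window = 50)
    log <- run_simulation(cfg, env = env, distances = dists)
    average_policy_fields(log$snapshots, env, enc, window = 50,
                          distances = dists)
  }
  coherence <- function(f) {
    z <- cbind(f$zx, f$zy)
    sims <- c()
    for (s in seq_len(nrow(z))) {
      for (nb in env$neighbors[s, ]) {
        if (nb <= s) next
        na_ <- sqrt(sum(z[s, ]^2))
        nb_ <- sqrt(sum(z[nb, ]^2))
        if (na_ > 1e-12 && nb_ > 1e-12) {
          sims <- c(sims, sum(z[s, ] * z[nb, ]) / (na_ * nb_))
        }
      }
    }
    mean(sims)
  }
  restricted <- coherence(run1(0.75))
  unrestricted <- coherence(run1(1))
  expect_gt(restricted, unrestricted)
})

test_that("structured keys keep low-entropy policies near the reward", {
  env <- open
  near <- which(env$geodesic[, env$reward_id] <= 3 &
                  seq_len(400) != env$reward_id)
  near_entropy <- function(kind, seed) {
    enc <- make_encoding(env, kind)
    dists <- encoding_distances(enc)
    cfg <- simulation_config("open_field", kind, capacity_fraction = 0.75,
                             n_episodes = 1000, seed = seed,
                             snapshot_every = 0, snapshot_final_window = 100)
    log <- run_simulation(cfg, env = env, distances = dists)
    f <- average_policy_fields(log$snapshots, env, enc, window = 100,
                               distances = dists)
    mean(f$entropy[near])
  }
  for (seed in 1:2) {
    expect_lt(near_entropy("successor", seed), near_entropy("onehot", seed))
  }
})
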