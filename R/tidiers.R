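#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation log
#'
#' @param x A `simulation_log`.
#' @param ... Unused.
#' @return The per-episode tibble with the run's condition columns attached.
#' @export
tidy.simulation_log <- function(x, ...) {
  dplyr::mutate(x$episodes,
                layout = x$config$layout, encoding = x$config$encoding,
                fraction = x$config$capacity_fraction,
                rule = x$config$forgetting_rule, seed = x$config$seed,
                .before = 1)
}

#' One-row summary of a simulation log
#'
#' @param x A `simulation_log`.
#' @param env Optional prebuilt `gridworld` (rebuilt from the config
#'   otherwise) used to normalise performance.
#' @param ... Unused.
#' @return A one-row tibble: condition, mean raw score, normalised
#'   performance, success rate, exact-match percentage, total forgetting
#'   events.
#' @export
glance.simulation_log <- function(x, env = NULL, ...) {
  if (is.null(env)) env <- build_environment(x$config$layout,
                                             x$config$reward_state)
  ep <- x$episodes
  tibble::tibble(
    layout = x$config$layout, encoding = x$config$encoding,
    fraction = x$config$capacity_fraction, rule = x$config$forgetting_rule,
    seed = x$config$seed, n_episodes = nrow(ep),
    mean_raw_score = mean(ep$raw_score),
    normalized_performance = normalize_performance(ep$raw_score, env),
    success_rate = mean(ep$success),
    exact_match_pct = 100 * sum(ep$n_exact) / max(1, sum(ep$n_recalls)),
    total_forgets = sum(x$forget_tally)
  )
}

#' Tidy an experiment result
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return The per-run tibble (one row per condition x seed).
#' @export
tidy.experiment_result <- function(x, ...) x$runs

#' Condition-level summary of an experiment result
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return One row per condition: mean and SD of normalised performance
#'   across seeds.
#' @export
glance.experiment_result <- function(x, ...) x$summary
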