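#' Define an experiment grid
#'
#' A condition grid over environments, encodings, capacity fractions and
#' forgetting rules, crossed with a set of seeds. The default capacity
#' ladder is `1.0, 0.9, 0.75, 0.6, 0.5, 0.25` and the default replicate
#' count is 6 seeds per condition. Duplicate axis values are dropped with a
#' warning.
#'
#' @param layouts Character vector of layout names.
#' @param encodings Character vector of encoding kinds.
#' @param fractions Numeric capacity fractions in `(0, 1]`.
#' @param rules Forgetting rules.
#' @param seeds Integer seeds (one run per condition x seed).
#' @param n_episodes Episodes per run.
#' @param gamma,sigma Shared model parameters.
#' @param snapshot_every,snapshot_final_window Snapshot cadence (defaults
#'   off for grid runs; see [simulation_config()]).
#' @return An `experiment_grid` list.
#' @export
experiment_grid <- function(layouts = "open_field",
                            encodings = c("onehot", "random", "place_cell",
                                          "successor"),
                            fractions = c(1.0, 0.9, 0.75, 0.6, 0.5, 0.25),
                            rules = "oldest",
                            seeds = 1:6,
                            n_episodes = 5000L,
                            gamma = 0.98, sigma = 0.05,
                            snapshot_every = 0L, snapshot_final_window = 0L) {
  dedup <- function(x, what) {
    if (anyDuplicated(x)) {
      warning("duplicate ", what, " values dropped", call. = FALSE)
      x <- unique(x)
    }
    x
  }
  layouts <- dedup(layouts, "layout")
  encodings <- dedup(encodings, "encoding")
  fractions <- dedup(fractions, "fraction")
  rules <- dedup(rules, "rule")
  seeds <- dedup(seeds, "seed")
  if (any(lengths(list(layouts, encodings, fractions, rules, seeds)) == 0L)) {
    stop("empty grid axis", call. = FALSE)
  }
  stopifnot(all(fractions > 0 & fractions <= 1))
  structure(list(layouts = layouts, encodings = encodings,
                 fractions = fractions, rules = rules, seeds = seeds,
                 n_episodes = as.integer(n_episodes), gamma = gamma,
                 sigma = sigma, snapshot_every = as.integer(snapshot_every),
                 snapshot_final_window = as.integer(snapshot_final_window)),
            class = "experiment_grid")
}

#' Expand an experiment grid into simulation configs
#'
#' Forms the Cartesian product of the grid axes in a stable, documented
#' order (layout, then encoding, fraction, rule, seed; seeds vary fastest).
#'
#' @param grid An [experiment_grid()].
#' @return A list of [simulation_config()] objects.
#' @export
expand_grid_configs <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- tidyr::expand_grid(
    layout = grid$layouts, encoding = grid$encodings,
    fraction = grid$fractions, rule = grid$rules, seed = grid$seeds
  )
  purrr::pmap(cells, function(layout, encoding, fraction, rule, seed) {
    simulation_config(
      layout = layout, encoding = encoding, capacity_fraction = fraction,
      forgetting_rule = rule, gamma = grid$gamma, sigma = grid$sigma,
      n_episodes = grid$n_episodes, seed = seed,
      snapshot_every = grid$snapshot_every,
      snapshot_final_window = grid$snapshot_final_window
    )
  })
}

#' Run every condition of an experiment grid
#'
#' Runs [run_simulation()] for each condition x seed cell, reusing the
#' environment and encoding-distance tables across runs that share them.
#' Per-run normalised performance is the simulation average; condition means
#' and SDs are taken over seeds, and each restricted-capacity condition is
#' compared against the unrestricted (fraction 1) condition of the same
#' layout x encoding x rule with Welch's two-tailed test, Bonferroni-corrected
#' for the number of such comparisons.
#'
#' @param grid An [experiment_grid()].
#' @param keep_logs Keep the full `simulation_log`s in the result (memory
#'   heavy for large grids).
#' @return An `experiment_result`: `runs` (one tibble row per run),
#'   `summary` (one row per condition), `comparisons` (Welch tests vs full
#'   capacity), and optionally `logs`.
#' @export
run_experiment <- function(grid, keep_logs = FALSE) {
  configs <- expand_grid_configs(grid)
  env_cache <- list()
  dist_cache <- list()
  logs <- list()
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    if (is.null(env_cache[[cf$layout]])) {
      env_cache[[cf$layout]] <- build_environment(cf$layout)
    }
    env <- env_cache[[cf$layout]]
    dist_key <- paste(cf$layout, cf$encoding,
                      if (cf$encoding == "random") cf$encoding_seed else "",
                      sep = "|")
    if (is.null(dist_cache[[dist_key]])) {
      enc <- make_encoding(env, cf$encoding, sigma = cf$sigma,
                           gamma = cf$gamma, seed = cf$encoding_seed)
      dist_cache[[dist_key]] <- encoding_distances(enc)
    }
    log <- run_simulation(cf, env = env, distances = dist_cache[[dist_key]])
    rows[[i]] <- tibble::tibble(
      layout = cf$layout, encoding = cf$encoding,
      fraction = cf$capacity_fraction, rule = cf$forgetting_rule,
      seed = cf$seed,
      mean_raw_score = mean(log$episodes$raw_score),
      normalized_performance = normalize_performance(log$episodes$raw_score,
                                                     env),
      success_rate = mean(log$episodes$success),
      total_forgets = sum(log$forget_tally)
    )
    if (keep_logs) logs[[i]] <- log
  }
  runs <- dplyr::bind_rows(rows)

  summary <- runs |>
    dplyr::group_by(.data$layout, .data$encoding, .data$fraction, .data$rule) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      mean_performance = mean(.data$normalized_performance),
      sd_performance = stats::sd(.data$normalized_performance),
      mean_success_rate = mean(.data$success_rate),
      total_forgets = sum(.data$total_forgets),
      .groups = "drop"
    )

  comparisons <- NULL
  if (1 %in% grid$fractions && length(grid$fractions) > 1 &&
      length(grid$seeds) >= 2) {
    restricted <- setdiff(grid$fractions, 1)
    m <- length(restricted) *
      length(grid$layouts) * length(grid$encodings) * length(grid$rules)
    comparisons <- purrr::pmap_dfr(
      tidyr::expand_grid(layout = grid$layouts, encoding = grid$encodings,
                         rule = grid$rules, fraction = restricted),
      function(layout, encoding, rule, fraction) {
        full <- runs$normalized_performance[
          runs$layout == layout & runs$encoding == encoding &
            runs$rule == rule & runs$fraction == 1]
        restr <- runs$normalized_performance[
          runs$layout == layout & runs$encoding == encoding &
            runs$rule == rule & runs$fraction == fraction]
        dplyr::bind_cols(
          tibble::tibble(layout = layout, encoding = encoding, rule = rule,
                         fraction = fraction),
          welch_test(restr, full, "two.sided", m_comparisons = m)
        )
      })
  }

  structure(list(runs = runs, summary = summary, comparisons = comparisons,
                 logs = if (keep_logs) logs else NULL, grid = grid),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", nrow(x$runs), "runs,", nrow(x$summary),
      "conditions\n")
  print(x$summary)
  invisible(x)
}
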