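#' Memory capacity from a capacity fraction
#'
#' Capacity is set as a fraction of the environment's available (non-obstacle)
#' states, rounded down: 75% of the 400 open-field states gives 300 entries,
#' 75% of the 365 four-rooms states gives 273. A fraction of 1 means every
#' state fits and no entry is ever overwritten.
#'
#' @param fraction Capacity fraction in `(0, 1]`.
#' @param n_available Number of available states.
#' @return Integer capacity `floor(fraction * n_available)`.
#' @export
capacity_for <- function(fraction, n_available) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (n_available < 1) stop("n_available must be positive", call. = FALSE)
  as.integer(floor(fraction * n_available))
}

#' Create an episodic memory bank
#'
#' The memory bank is a capacity-limited dictionary mapping state-encoding
#' keys to 4-slot arrays of observed returns (one slot per action) plus a
#' last-update timestamp. Keys are stored as indices into the encoding table,
#' which is exact because queries and keys are always rows of the same table;
#' `recall()` also accepts raw query vectors.
#'
#' The bank has reference semantics (it is an environment): `write_event()`
#' mutates it in place, which keeps multi-thousand-episode simulations cheap.
#' Use [bank_snapshot()] to take a value copy.
#'
#' Entries are kept in dictionary insertion order: forgetting removes the
#' victim from its position and the replacement is appended at the end, so
#' the "first minimal index" tie rule of [recall()] resolves to the
#' oldest-inserted of the tied entries.
#'
#' @param capacity Maximum number of entries (see [capacity_for()]).
#' @param encoding A `state_encoding` providing the key table.
#' @param forgetting_rule `"oldest"` (overwrite the least recently stamped
#'   entry; ties go to the lowest storage index) or `"random"` (uniform over
#'   entries, drawn from the active RNG stream).
#' @param forget_on `"update"` (default): timestamps are refreshed only when
#'   an entry is written. `"access"`: recalling an entry also refreshes its
#'   stamp, so the oldest rule becomes least-recently-*accessed*.
#' @param tie_break `"first"` (default): non-exact recall ties resolve to
#'   the first minimal entry in storage order; `"random"`: uniformly among
#'   the tied entries.
#' @param distances Optional precomputed [encoding_distances()] matrix; if
#'   omitted it is computed on first index-based recall.
#' @return An object of class `memory_bank`.
#' @export
memory_bank <- function(capacity, encoding,
                        forgetting_rule = c("oldest", "random"),
                        forget_on = c("update", "access"),
                        tie_break = c("first", "random"),
                        distances = NULL) {
  forgetting_rule <- match.arg(forgetting_rule)
  forget_on <- match.arg(forget_on)
  tie_break <- match.arg(tie_break)
  stopifnot(capacity >= 1)
  n_states <- nrow(encoding$table)
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$rule <- forgetting_rule
  e$forget_on <- forget_on
  e$tie_break <- tie_break
  e$encoding <- encoding
  e$dist <- distances
  e$n <- 0L
  e$sid <- integer(capacity)                    # state id of each entry
  e$val <- matrix(NA_real_, capacity, 4L)       # return slots (NA = empty)
  e$lu <- integer(capacity)                     # last-update event stamp
  e$pos <- integer(n_states)                    # state id -> entry index (0 = absent)
  e$counter <- 0L                               # write-event counter
  e$forget_tally <- integer(n_states)           # forgetting events by lost state
  class(e) <- "memory_bank"
  e
}

#' @export
print.memory_bank <- function(x, ...) {
  cat("<memory_bank>", x$n, "/", x$capacity, "entries | rule:", x$rule,
      "| encoding:", x$encoding$kind, "\n")
  invisible(x)
}

#' Number of entries currently stored
#' @param bank A `memory_bank`.
#' @export
bank_size <- function(bank) bank$n

ensure_bank_distances <- function(bank) {
  if (is.null(bank$dist)) bank$dist <- encoding_distances(bank$encoding)
  invisible(bank)
}

#' Recall the nearest memory to a query
#'
#' Finds the stored entry whose key minimises the Chebyshev distance to the
#' query. By default ties are broken by the first minimal entry in storage
#' (insertion) order and retrieval never modifies the bank; with the bank
#' options `tie_break = "random"` / `forget_on = "access"` ties are drawn
#' uniformly and the recalled entry's timestamp is refreshed.
#'
#' @param bank A non-empty `memory_bank`.
#' @param query A raw activity vector matching the encoding dimension, or
#'   `NULL` if `query_id` is given.
#' @param query_id A state id; uses the precomputed pairwise distance table.
#' @return A list: `index` (entry storage index), `state_id` (the key's
#'   state), `values` (the 4 return slots, `NA` where unvisited), `distance`,
#'   and `exact` (`TRUE` iff distance is exactly 0).
#' @export
recall <- function(bank, query = NULL, query_id = NULL) {
  n <- bank$n
  if (n == 0L) stop("recall from an empty memory bank", call. = FALSE)
  stored <- bank$sid[seq_len(n)]
  if (!is.null(query_id)) {
    j <- bank$pos[query_id]
    if (j > 0L) {
      d <- 0
      i <- j
    } else {
      ensure_bank_distances(bank)
      dc <- bank$dist[stored, query_id]
      i <- pick_min(dc, bank$tie_break)
      d <- dc[i]
    }
  } else {
    if (length(query) != ncol(bank$encoding$table)) {
      stop("query dimension does not match the encoding", call. = FALSE)
    }
    dc <- chebyshev_to_rows(bank$encoding$table[stored, , drop = FALSE], query)
    i <- pick_min(dc, bank$tie_break)
    d <- dc[i]
  }
  if (bank$forget_on == "access") {
    bank$counter <- bank$counter + 1L
    bank$lu[i] <- bank$counter
  }
  list(index = i, state_id = bank$sid[i], values = bank$val[i, ],
       distance = d, exact = d == 0)
}

pick_min <- function(d, tie_break = "first") {
  if (tie_break == "first") return(which.min(d))
  idx <- which(d == min(d))
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

#' Softmax policy from a memory value array
#'
#' Converts the 4 return slots of a recalled memory into an action
#' distribution via a unit-temperature softmax. Unvisited slots (`NA`) count
#' as a return of 0. Computed with max-subtraction, which is exact because
#' the softmax is shift-invariant.
#'
#' @param values Numeric vector of 4 return slots (`NA` allowed).
#' @return A probability vector over (Down, Up, Left, Right).
#' @examples
#' policy_from_values(c(9.79, 0, 0, 0)) # ~0.9998 on Down
#' @export
policy_from_values <- function(values) {
  stopifnot(length(values) == 4L)
  values[is.na(values)] <- 0
  if (any(!is.finite(values))) stop("non-finite return values", call. = FALSE)
  z <- exp(values - max(values))
  p <- z / sum(z)
  names(p) <- rownames(action_deltas())
  p
}

#' Choose which entry a full bank forgets
#'
#' Under `"oldest"` the entry with the minimal last-update stamp is selected
#' (ties broken by the lowest storage index); under `"random"` an entry is
#' drawn uniformly from the active RNG stream.
#'
#' @param bank A `memory_bank` at capacity.
#' @param rule Override of the bank's forgetting rule.
#' @return The storage index of the victim entry.
#' @export
select_forget_index <- function(bank, rule = bank$rule) {
  if (bank$n < bank$capacity) {
    stop("bank is not at capacity; nothing to forget", call. = FALSE)
  }
  switch(rule,
    oldest = which.min(bank$lu[seq_len(bank$n)]),
    random = sample.int(bank$n, 1L),
    stop("unknown forgetting rule: ", rule, call. = FALSE)
  )
}

#' Write one state-action-return event to the bank
#'
#' If the state is already stored, its slot for `action` is overwritten with
#' the new return and the entry's timestamp is refreshed (its storage
#' position is unchanged, as in a dictionary). A novel state is appended
#' while capacity remains; at capacity, a victim entry is forgotten (chosen
#' by the bank's forgetting rule, tallied by forgotten state), removed from
#' its position, and a fresh entry holding only this event is appended at
#' the end of storage order.
#'
#' @param bank A `memory_bank` (mutated in place).
#' @param state_id State id of the event (row of the encoding table).
#' @param action Action index 1..4.
#' @param return_value Observed Monte-Carlo return for the action.
#' @return The bank, invisibly.
#' @export
write_event <- function(bank, state_id, action, return_value) {
  stopifnot(action %in% 1:4, is.finite(return_value))
  bank$counter <- bank$counter + 1L
  j <- bank$pos[state_id]
  if (j > 0L) {
    bank$val[j, action] <- return_value
    bank$lu[j] <- bank$counter
  } else {
    n <- bank$n
    if (n < bank$capacity) {
      j <- n + 1L
      bank$n <- j
    } else {
      victim <- select_forget_index(bank)
      lost <- bank$sid[victim]
      bank$forget_tally[lost] <- bank$forget_tally[lost] + 1L
      bank$pos[lost] <- 0L
      if (victim < n) { # close the gap, preserving insertion order
        idx <- (victim + 1L):n
        bank$sid[idx - 1L] <- bank$sid[idx]
        bank$val[idx - 1L, ] <- bank$val[idx, ]
        bank$lu[idx - 1L] <- bank$lu[idx]
        moved <- bank$sid[idx - 1L]
        bank$pos[moved] <- bank$pos[moved] - 1L
      }
      j <- n
    }
    bank$sid[j] <- state_id
    v <- rep(NA_real_, 4L)
    v[action] <- return_value
    bank$val[j, ] <- v
    bank$lu[j] <- bank$counter
    bank$pos[state_id] <- j
  }
  invisible(bank)
}

#' Snapshot and restore memory banks
#'
#' `bank_snapshot()` takes a value copy of a bank's entries (state ids,
#' return slots, timestamps); `bank_from_snapshot()` reconstructs a live bank
#' from one, re-deriving the keys from the encoding table. Snapshots are what
#' the simulation logs at its snapshot cadence and what the trajectory and
#' policy-field analyses replay.
#'
#' @param bank A `memory_bank`.
#' @return `bank_snapshot()`: a list with `sid`, `values`, `last_update`,
#'   `n`, `capacity`.
#' @export
bank_snapshot <- function(bank) {
  n <- bank$n
  list(sid = bank$sid[seq_len(n)],
       values = bank$val[seq_len(n), , drop = FALSE],
       last_update = bank$lu[seq_len(n)],
       n = n, capacity = bank$capacity)
}

#' @rdname bank_snapshot
#' @param snapshot A snapshot produced by `bank_snapshot()`.
#' @param encoding The `state_encoding` whose table supplies the keys.
#' @param forgetting_rule,forget_on,tie_break,distances Passed to
#'   [memory_bank()].
#' @export
bank_from_snapshot <- function(snapshot, encoding,
                               forgetting_rule = "oldest",
                               forget_on = "update", tie_break = "first",
                               distances = NULL) {
  bank <- memory_bank(snapshot$capacity, encoding, forgetting_rule,
                      forget_on = forget_on, tie_break = tie_break,
                      distances = distances)
  n <- snapshot$n
  bank$n <- n
  bank$sid[seq_len(n)] <- snapshot$sid
  bank$val[seq_len(n), ] <- snapshot$values
  bank$lu[seq_len(n)] <- snapshot$last_update
  bank$pos[snapshot$sid] <- seq_len(n)
  bank$counter <- max(0L, snapshot$last_update)
  bank
}

#' Serialise a memory bank to JSON
#'
#' Entries are written as state coordinates, four return slots (`null` for
#' unvisited actions) and the last-update stamp; keys are reconstructed from
#' the encoding table on load.
#'
#' @param bank A `memory_bank`.
#' @param env The `gridworld` the bank's states index.
#' @param path File path; `NULL` returns the JSON string.
#' @export
bank_to_json <- function(bank, env, path = NULL) {
  snap <- bank_snapshot(bank)
  entries <- lapply(seq_len(snap$n), function(i) {
    sid <- snap$sid[i]
    list(state = c(env$states$x[sid], env$states$y[sid]),
         values = lapply(snap$values[i, ],
                         function(v) if (is.na(v)) NULL else v),
         last_update = snap$last_update[i])
  })
  obj <- list(capacity = snap$capacity, entries = entries)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
}

#' @rdname bank_to_json
#' @param json A JSON string or file path written by `bank_to_json()`.
#' @param encoding,forgetting_rule Passed to [bank_from_snapshot()].
#' @export
bank_from_json <- function(json, env, encoding, forgetting_rule = "oldest") {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  n <- length(obj$entries)
  sid <- integer(n)
  values <- matrix(NA_real_, n, 4L)
  lu <- integer(n)
  for (i in seq_len(n)) {
    en <- obj$entries[[i]]
    sid[i] <- state_id_at(env, c(en$state[[1]], en$state[[2]]))
    values[i, ] <- vapply(en$values,
                          function(v) if (is.null(v)) NA_real_ else v,
                          numeric(1))
    lu[i] <- en$last_update
  }
  bank_from_snapshot(list(sid = sid, values = values, last_update = lu,
                          n = n, capacity = obj$capacity),
                     encoding, forgetting_rule)
}
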