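open <- build_environment("open_field")
oh <- onehot_encoding(open)

test_that("capacity follows floor(fraction * available states)", {
  expect_identical(capacity_for(0.75, 400), 300L)
  expect_identical(capacity_for(0.75, 365), 273L) # floor of 273.75
  expect_identical(capacity_for(1.0, 365), 365L)
  expect_identical(capacity_for(0.25, 400), 100L)
  expect_error(capacity_for(0, 400))
  expect_error(capacity_for(1.2, 400))
})

test_that("softmax policy preserves return ordering and shift invariance", {
  expect_equal(unname(policy_from_values(c(0, 0, 0, 0))), rep(0.25, 4))
  p <- policy_from_values(c(9.79, 0, 0, 0))
  expect_equal(unname(p[1]), exp(9.79) / (exp(9.79) + 3), tolerance = 1e-12)
  # empty slots count as return 0
  expect_equal(policy_from_values(c(9.79, NA, NA, NA)),
               policy_from_values(c(9.79, 0, 0, 0)))
  # shift invariance
  v <- c(1.2, -0.3, 0.5, 2.0)
  expect_equal(policy_from_values(v), policy_from_values(v + 17.3))
  # larger return, larger probability
  expect_true(all(diff(policy_from_values(sort(v))) > 0))
  expect_error(policy_from_values(c(Inf, 0, 0, 0)))
})

test_that("recall returns the Chebyshev-nearest entry; exact iff distance 0", {
  enc <- random_encoding(open, seed = 2)
  bank <- filled_bank(enc, 50, state_ids = 1:50)
  # stored key -> exact, distance 0
  r <- recall(bank, query = enc$table[17, ])
  expect_true(r$exact)
  expect_equal(r$distance, 0)
  expect_equal(r$state_id, 17)
  # vector-query and index-query routes agree with a scalar-loop scan
  keys <- enc$table[1:50, ]
  set.seed(31)
  for (q in sample(51:400, 40)) {
    oracle <- scan_nearest(keys, enc$table[q, ])
    r_vec <- recall(bank, query = enc$table[q, ])
    r_id <- recall(bank, query_id = q)
    expect_equal(r_vec$index, oracle$index)
    expect_equal(r_vec$distance, oracle$distance)
    expect_equal(r_id$index, oracle$index)
    expect_equal(r_id$distance, oracle$distance)
  }
  expect_error(recall(memory_bank(10, enc), query_id = 1), "empty")
  expect_error(recall(bank, query = c(1, 2, 3)), "dimension")
})

test_that("onehot non-exact recall ties resolve to the first stored entry", {
  bank <- filled_bank(oh, 10, state_ids = c(30, 7, 12))
  r <- recall(bank, query_id = 200)
  expect_equal(r$distance, 1)
  expect_false(r$exact)
  expect_equal(r$index, 1L)
  expect_equal(r$state_id, 30) # first in storage order
})

test_that("random tie-breaking samples uniformly among tied entries", {
  bank <- memory_bank(4, oh, tie_break = "random")
  for (s in c(5, 6, 7, 8)) write_event(bank, s, 1L, 1)
  set.seed(1)
  picks <- replicate(4000, recall(bank, query_id = 300)$state_id)
  freq <- table(picks) / 4000
  expect_setequal(as.integer(names(freq)), c(5, 6, 7, 8))
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("writes update in place, append, then evict in insertion order", {
  enc <- random_encoding(open, seed = 4)
  bank <- memory_bank(3, enc)
  write_event(bank, 10, 1L, 0.5)
  write_event(bank, 20, 2L, 0.6)
  expect_equal(bank_size(bank), 2L)
  # revisit with the same action: most recent return wins, size unchanged
  write_event(bank, 10, 1L, 0.9)
  expect_equal(bank_size(bank), 2L)
  expect_equal(recall(bank, query_id = 10)$values, c(0.9, NA, NA, NA))
  # second action fills another slot of the same entry
  write_event(bank, 10, 3L, -0.2)
  expect_equal(recall(bank, query_id = 10)$values, c(0.9, NA, -0.2, NA))
  # fill to capacity, then a novel key evicts the least recently updated (20)
  write_event(bank, 30, 1L, 1)
  write_event(bank, 40, 1L, 2)
  expect_equal(bank_size(bank), 3L)
  expect_equal(sum(bank$forget_tally), 1L)
  expect_equal(bank$forget_tally[20], 1L)
  expect_false(recall(bank, query_id = 20)$exact) # forgotten: only inexact recall
  # survivors keep insertion order with the newcomer appended last
  expect_equal(bank$sid[seq_len(bank$n)], c(10L, 30L, 40L))
})

test_that("oldest-rule victim is the minimal timestamp, ties to lower index", {
  enc <- random_encoding(open, seed = 4)
  bank <- filled_bank(enc, 3, state_ids = c(1, 2, 3))
  bank$lu[1:3] <- c(5L, 2L, 9L)
  expect_equal(select_forget_index(bank), 2L)
  bank$lu[1:3] <- c(2L, 2L, 9L)
  expect_equal(select_forget_index(bank), 1L)
  expect_error(select_forget_index(filled_bank(enc, 3, 1:2)), "capacity")
})

test_that("random-rule victims are uniform over entries", {
  enc <- random_encoding(open, seed = 4)
  bank <- filled_bank(enc, 4, state_ids = c(1, 2, 3, 4), rule = "random")
  set.seed(8)
  picks <- replicate(1e4, select_forget_index(bank))
  freq <- tabulate(picks, 4) / 1e4
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("bank invariants survive random operation streams", {
  enc <- random_encoding(open, seed = 6)
  set.seed(77)
  for (cap in c(5L, 40L)) {
    bank <- memory_bank(cap, enc, sample(c("oldest", "random"), 1))
    for (op in 1:500) {
      write_event(bank, sample.int(400, 1), sample.int(4, 1), runif(1, -2.5, 10))
      expect_lte(bank$n, cap)
    }
    ids <- bank$sid[seq_len(bank$n)]
    expect_equal(anyDuplicated(ids), 0L)
    # pos index is consistent with storage
    expect_equal(bank$pos[ids], seq_len(bank$n))
    expect_true(all(bank$pos[-ids] == 0L))
    # every entry holds at least one observed value
    expect_true(all(rowSums(!is.na(bank$val[seq_len(bank$n), , drop = FALSE])) >= 1))
  }
})

test_that("at full capacity every state fits: all-exact recall, no forgetting", {
  enc <- random_encoding(open, seed = 11)
  bank <- memory_bank(400, enc)
  set.seed(12)
  for (op in 1:1200) {
    write_event(bank, sample.int(400, 1), sample.int(4, 1), runif(1))
  }
  stored <- bank$sid[seq_len(bank$n)]
  expect_equal(sum(bank$forget_tally), 0L)
  for (q in sample(stored, 30)) expect_true(recall(bank, query_id = q)$exact)
})

test_that("access-refresh mode spares recently recalled entries", {
  enc <- random_encoding(open, seed = 13)
  bank <- memory_bank(2, enc, forget_on = "access")
  write_event(bank, 1, 1L, 1) # oldest write
  write_event(bank, 2, 1L, 1)
  recall(bank, query_id = 1) # refreshes entry 1's stamp
  write_event(bank, 3, 1L, 1) # eviction should now hit state 2
  expect_equal(bank$forget_tally[2], 1L)
  expect_equal(bank$forget_tally[1], 0L)
  # default mode: retrieval does not touch timestamps
  bank2 <- memory_bank(2, enc)
  write_event(bank2, 1, 1L, 1)
  write_event(bank2, 2, 1L, 1)
  lu_before <- bank2$lu[1:2]
  recall(bank2, query_id = 1)
  expect_identical(bank2$lu[1:2], lu_before)
})

test_that("snapshots and JSON round-trip the bank", {
  enc <- random_encoding(open, seed = 14)
  bank <- memory_bank(5, enc)
  write_event(bank, 3, 2L, 1.5)
  write_event(bank, 9, 4L, -0.4)
  write_event(bank, 3, 1L, 2.5)
  snap <- bank_snapshot(bank)
  back <- bank_from_snapshot(snap, enc)
  expect_equal(back$sid[seq_len(back$n)], bank$sid[seq_len(bank$n)])
  expect_equal(back$val[seq_len(back$n), ], bank$val[seq_len(bank$n), ])
  expect_equal(back$lu[seq_len(back$n)], bank$lu[seq_len(bank$n)])

  js <- bank_to_json(bank, open)
  back2 <- bank_from_json(js, open, enc)
  expect_equal(back2$sid[seq_len(back2$n)], bank$sid[seq_len(bank$n)])
  expect_equal(back2$val[seq_len(back2$n), ], bank$val[seq_len(bank$n), ])
})
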