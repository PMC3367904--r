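spec <- design_spec(seed = 42L)
grid <- make_grid()

test_that("location sets partition the grid and counterbalance over 8 participants", {
  asg <- assign_location_sets(spec, participant = 1L)
  training <- unname(unlist(asg$sets))
  expect_length(asg$reserved, 16L)
  expect_length(training, 16L)
  expect_equal(sort(c(training, asg$reserved)), 0:31)
  expect_false(anyDuplicated(training) > 0)

  # across the 8-participant cycle each location serves each role exactly once
  for (role in c("fixed1", "fixed2", "random_setA", "random_setB")) {
    served <- unname(unlist(lapply(1:8, function(p) {
      assign_location_sets(spec, p)$sets[[role]]
    })))
    expect_equal(sort(served), 0:31)
  }
  # participant 9 wraps around to participant 1's assignment
  expect_identical(assign_location_sets(spec, 9L), asg)
})

test_that("fixed sequence ordering respects the adjacency constraint", {
  idx <- function(r, c) grid$cell_index[grid$row == r & grid$col == c]
  far <- c(idx(0, 1), idx(2, 3), idx(5, 1), idx(0, 4)) # mutually non-adjacent
  expect_equal(sort(make_fixed_sequence(far, seed = 1)), sort(far))

  # exactly one adjacent pair: exhaustive check that it is never consecutive
  one_pair <- c(idx(1, 1), idx(1, 2), idx(4, 4), idx(1, 5))
  for (s in 1:20) {
    sq <- make_fixed_sequence(one_pair, seed = s)
    pairs <- cbind(sq[-4], sq[-1])
    expect_false(any(is_adjacent(pairs[, 1], pairs[, 2])))
  }
  # a 2x2 square admits no valid ordering at all
  square <- c(idx(2, 2), idx(2, 3), idx(3, 2), idx(3, 3))
  expect_error(make_fixed_sequence(square, seed = 1), "no ordering")
})

test_that("training blocks have the stated composition and run cap", {
  seqs <- serialorder:::experiment_sequences(spec, 1L)
  blk <- make_training_block(spec, seqs, seed = 7L)
  expect_equal(nrow(blk), 96L)
  mb <- blk[blk$serial_position == 1L, ]
  expect_equal(as.integer(table(mb$sequence_role)[c("fixed1", "fixed2",
                                                "random_setA", "random_setB")]),
               c(8L, 8L, 4L, 4L))
  expect_lte(max(rle(mb$condition)$lengths), 3L)
  # fixed mini-blocks repeat their sequence verbatim
  for (i in mb$mini_block[mb$sequence_role == "fixed1"]) {
    expect_equal(blk$location[blk$mini_block == i], seqs$fixed1)
  }
  # random mini-blocks use their own 4 items
  for (i in mb$mini_block[mb$sequence_role == "random_setA"]) {
    expect_equal(sort(blk$location[blk$mini_block == i]),
                 sort(seqs$random_setA))
  }
})

test_that("ordinal-only mini-blocks isolate the position cue", {
  seqs <- serialorder:::experiment_sequences(spec, 1L)
  for (pos in 1:4) {
    mb <- make_ordinal_only_miniblock(seqs$fixed1, pos, seqs$reserved,
                                      seed = pos)
    expect_equal(mb$location[pos], seqs$fixed1[pos])
    expect_equal(mb$tag[pos], "ordinal_test")
    expect_equal(sum(mb$tag == "new_location"), 3L)
    expect_true(all(mb$location[-pos] %in% seqs$reserved))
    expect_false(serialorder:::has_adjacent_pair(mb$location))
  }
})

test_that("order-only mini-blocks preserve exactly one learned transition", {
  seqs <- serialorder:::experiment_sequences(spec, 1L)
  lk <- serialorder:::fixed_lookup(seqs$fixed1, seqs$fixed2)
  for (pi in 1:3) {
    mb <- make_order_only_miniblock(seqs$fixed1, seqs$fixed2, pair_index = pi,
                                    seed = pi)
    locs <- mb$location
    expect_true(all(locs %in% c(seqs$fixed1, seqs$fixed2)))
    # exactly one consecutive pair follows a learned transition
    preserved <- vapply(2:4, function(p) {
      pred <- lk$pred[[as.character(locs[p])]]
      !is.na(pred) && pred == locs[p - 1L]
    }, logical(1))
    expect_equal(sum(preserved), 1L)
    k <- which(preserved) + 1L
    expect_equal(mb$tag[k], "order_test")
    # the order-only test item sits at a wrong serial position
    expect_false(lk$pos[[as.character(locs[k])]] == k)
    expect_gte(sum(mb$tag == "control_test"), 1L)
    expect_false(any(mb$tag == "ordinal_test"))
    # one other-sequence item sits at its correct serial position
    other_at_pos <- vapply(1:4, function(p) {
      key <- as.character(locs[p])
      lk$role[[key]] == "fixed2" && lk$pos[[key]] == p
    }, logical(1))
    expect_equal(sum(other_at_pos), 1L)
  }
})

test_that("transfer blocks mix 8/8/8 mini-blocks and use every fixed item once as ordinal test", {
  seqs <- serialorder:::experiment_sequences(spec, 1L)
  blk <- make_transfer_block(spec, seqs, seed = 3L)
  expect_equal(nrow(blk), 96L)
  mb <- blk[blk$serial_position == 1L, ]
  expect_equal(as.integer(table(mb$condition)[c("order_only", "ordinal_only",
                                            "random_transfer")]),
               c(8L, 8L, 8L))
  expect_lte(max(rle(mb$condition)$lengths), 3L)
  tested <- blk$location[blk$tag == "ordinal_test"]
  expect_equal(sort(tested), sort(c(seqs$fixed1, seqs$fixed2)))
  # every ordinal test item appears at its learned serial position
  pos <- blk$serial_position[blk$tag == "ordinal_test"]
  learned <- ifelse(tested %in% seqs$fixed1, match(tested, seqs$fixed1),
                    match(tested, seqs$fixed2))
  expect_equal(pos[order(tested)], learned[order(tested)])
})

test_that("response sides balance to 48/48 per block", {
  ex <- full_experiment()
  counts <- table(ex$response_side, paste(ex$session, ex$block))
  expect_true(all(counts == 48L))
  expect_error(assign_response_sides(ex[1:3, ]), "odd")
})

test_that("the full experiment is reproducible and internally consistent", {
  ex <- full_experiment()
  expect_identical(ex, make_experiment(design_spec(seed = 42L), 1L))
  expect_false(identical(ex$location,
                         make_experiment(design_spec(seed = 43L), 1L)$location))

  # no grid-adjacent consecutive pair inside any mini-block, whole experiment
  bad <- vapply(miniblock_locations(ex), serialorder:::has_adjacent_pair,
                logical(1))
  expect_false(any(bad))

  # tag recomputation from first principles agrees everywhere
  expect_silent(reclassified <- classify_transfer_trials(ex))
  expect_identical(reclassified$tag, ex$tag)

  # a corrupted tag is caught and named
  broken <- ex
  i <- which(broken$tag == "ordinal_test")[1L]
  broken$tag[i] <- "order_test"
  expect_error(classify_transfer_trials(broken), "mismatch")
})

test_that("transfer tags only occur in transfer mini-blocks and never at impossible positions", {
  ex <- full_experiment()
  training <- ex$condition %in% c("fixed", "random")
  expect_true(all(ex$tag[training] == "plain"))
  expect_false(any(ex$tag == "order_test" & ex$serial_position == 1L))
  expect_false(any(ex$tag == "control_test" & ex$serial_position == 1L))
})
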