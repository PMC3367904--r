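#' Parameterization of the three-session derived-list SRT experiment
#'
#' Captures every structural constant of the design: a 32-location grid, two
#' fixed and two random four-item training sequences, 18 blocks of 24
#' four-trial mini-blocks per session over three sessions, transfer blocks at
#' positions 6/12/18 composed of 8 ordinal-only + 8 order-only + 8
#' random-transfer mini-blocks, a cap of three consecutive mini-blocks of the
#' same condition, a 400 ms response-stimulus interval and a 1000 ms fixation
#' between mini-blocks.
#'
#' @param seed Integer seed; fixes the location counterbalancing partition and
#'   (together with the participant index) every pseudo-random arrangement.
#' @param n_sessions,blocks_per_session,miniblocks_per_block Design constants.
#' @param transfer_block_positions Block positions (within session) of the
#'   transfer blocks.
#' @param fixed_miniblocks_per_training_block Number of fixed-sequence
#'   mini-blocks per training block (half per fixed sequence).
#' @param random_miniblocks_per_training_block Number of random mini-blocks
#'   per training block (half per random set).
#' @param transfer_composition Named counts of transfer mini-block types.
#' @param max_same_condition_run Longest admissible run of same-condition
#'   mini-blocks.
#' @param rsi_ms,fixation_ms Timing constants (ms); recorded, not simulated.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(seed = 1L,
                        n_sessions = 3L,
                        blocks_per_session = 18L,
                        miniblocks_per_block = 24L,
                        transfer_block_positions = c(6L, 12L, 18L),
                        fixed_miniblocks_per_training_block = 16L,
                        random_miniblocks_per_training_block = 8L,
                        transfer_composition = c(ordinal_only = 8L,
                                                 order_only = 8L,
                                                 random_transfer = 8L),
                        max_same_condition_run = 3L,
                        rsi_ms = 400,
                        fixation_ms = 1000) {
  stopifnot(
    fixed_miniblocks_per_training_block %% 2L == 0L,
    random_miniblocks_per_training_block %% 2L == 0L,
    fixed_miniblocks_per_training_block +
      random_miniblocks_per_training_block == miniblocks_per_block,
    sum(transfer_composition) == miniblocks_per_block,
    all(transfer_block_positions <= blocks_per_session)
  )
  structure(
    list(
      seed = as.integer(seed),
      n_sessions = as.integer(n_sessions),
      blocks_per_session = as.integer(blocks_per_session),
      miniblocks_per_block = as.integer(miniblocks_per_block),
      transfer_block_positions = as.integer(transfer_block_positions),
      fixed_miniblocks_per_training_block =
        as.integer(fixed_miniblocks_per_training_block),
      random_miniblocks_per_training_block =
        as.integer(random_miniblocks_per_training_block),
      transfer_composition = transfer_composition,
      max_same_condition_run = as.integer(max_same_condition_run),
      rsi_ms = rsi_ms,
      fixation_ms = fixation_ms
    ),
    class = "design_spec"
  )
}

# All permutations of 1..4 as a 24 x 4 matrix.
perms4 <- function() {
  out <- matrix(0L, 24L, 4L)
  i <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b))) {
    out[i, ] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
    i <- i + 1L
  }
  out
}

# Orderings of a 4-item location set with no grid-adjacent consecutive pair,
# as a matrix of locations (possibly 0 rows).
valid_orderings <- function(items, grid = make_grid()) {
  p <- perms4()
  cand <- matrix(items[p], nrow(p), 4L)
  ok <- !apply(cand, 1L, has_adjacent_pair, grid = grid)
  cand[ok, , drop = FALSE]
}

#' Counterbalanced assignment of locations to sequence roles
#'
#' The 32 grid locations are partitioned (by the spec seed) into eight groups
#' of four.  Each participant uses four groups as the fixed1, fixed2,
#' random-set-A and random-set-B items and holds the other sixteen locations
#' in reserve for transfer-block new-location trials.  Roles rotate over
#' groups with the participant index so that across a full eight-participant
#' counterbalancing cycle every location serves every role exactly once.
#' Groups are re-drawn until each admits at least one ordering without
#' grid-adjacent consecutive items, so that any group can serve as a fixed
#' sequence.
#'
#' @param spec A [design_spec()].
#' @param participant Participant index (1-based); role rotation is
#'   `(participant - 1) %% 8`.
#' @param grid The location grid.
#' @return A list with `sets` (named list of four 4-location vectors for
#'   roles `fixed1`, `fixed2`, `random_setA`, `random_setB`) and `reserved`
#'   (16 locations never used in training).
#' @export
assign_location_sets <- function(spec, participant = 1L, grid = make_grid()) {
  groups <- withr::with_seed(derive_seed(spec$seed, 0L), {
    for (try in 1:1000) {
      perm <- sample(grid$cell_index)
      g <- matrix(perm, nrow = 4L)
      if (all(apply(g, 2L, function(it) nrow(valid_orderings(it, grid)) > 0L))) {
        break
      }
      g <- NULL
    }
    if (is.null(g)) stop("could not partition grid into orderable groups")
    g
  })
  roles <- c("fixed1", "fixed2", "random_setA", "random_setB",
             rep("reserved", 4L))
  rot <- (as.integer(participant) - 1L) %% 8L
  role_of_group <- roles[((seq_len(8L) - 1L + rot) %% 8L) + 1L]
  sets <- lapply(c("fixed1", "fixed2", "random_setA", "random_setB"),
                 function(r) as.integer(groups[, role_of_group == r]))
  names(sets) <- c("fixed1", "fixed2", "random_setA", "random_setB")
  reserved <- as.integer(groups[, role_of_group == "reserved"])
  list(sets = sets, reserved = sort(reserved))
}

#' Order four items into a fixed training sequence
#'
#' Picks, uniformly at random among the admissible ones, an ordering of the
#' four items in which no two consecutive items occupy neighboring grid
#' cells.  The chosen ordering then repeats identically in every fixed
#' mini-block of that sequence.
#'
#' @param items Four distinct grid locations.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param grid The location grid.
#' @return Integer vector of 4 locations (the sequence in order).
#' @export
make_fixed_sequence <- function(items, seed = NULL, grid = make_grid()) {
  stopifnot(length(items) == 4L, !anyDuplicated(items))
  pick <- function() {
    ok <- valid_orderings(items, grid)
    if (nrow(ok) == 0L) {
      stop("no ordering of items {", paste(items, collapse = ", "),
           "} avoids grid-adjacent consecutive pairs")
    }
    as.integer(ok[sample.int(nrow(ok), 1L), ])
  }
  if (is.null(seed)) pick() else withr::with_seed(seed, pick())
}

# Ordered fixed sequences plus random sets and reserve for one participant.
experiment_sequences <- function(spec, participant = 1L, grid = make_grid()) {
  asg <- assign_location_sets(spec, participant, grid)
  seed1 <- derive_seed(spec$seed, 10L * participant + 1L)
  seed2 <- derive_seed(spec$seed, 10L * participant + 2L)
  list(
    fixed1 = make_fixed_sequence(asg$sets$fixed1, seed = seed1, grid = grid),
    fixed2 = make_fixed_sequence(asg$sets$fixed2, seed = seed2, grid = grid),
    random_setA = asg$sets$random_setA,
    random_setB = asg$sets$random_setB,
    reserved = asg$reserved
  )
}

# Tibble for one mini-block worth of trials.
mb_tibble <- function(mini_block, condition, sequence_role, locations, tags) {
  tibble::tibble(
    mini_block = as.integer(mini_block),
    serial_position = 1:4,
    condition = condition,
    sequence_role = sequence_role,
    location = as.integer(locations),
    tag = tags
  )
}

# Shuffle labels until no run of identical `cond[labels]` exceeds max_run.
shuffle_with_run_cap <- function(labels, cond, max_run, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    ord <- sample(labels)
    if (max(rle(cond[ord])$lengths) <= max_run) return(ord)
  }
  stop("could not interleave mini-block conditions within ", max_tries,
       " tries (run cap ", max_run, ")")
}

#' Generate one training block (24 mini-blocks, 96 trials)
#'
#' Eight mini-blocks of each fixed sequence and four of each random set are
#' interleaved in pseudo-random order with at most three consecutive
#' mini-blocks of the same condition (fixed vs. random).  Fixed mini-blocks
#' repeat their sequence verbatim; random mini-blocks draw a fresh ordering
#' of their four items (without replacement) that honors the adjacency
#' constraint.
#'
#' @param spec A [design_spec()].
#' @param sequences As returned by [experiment_sequences()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param grid The location grid.
#' @return Tibble of 96 trials.
#' @export
make_training_block <- function(spec, sequences, seed = NULL,
                                grid = make_grid()) {
  build <- function() {
    nf <- spec$fixed_miniblocks_per_training_block / 2L
    nr <- spec$random_miniblocks_per_training_block / 2L
    labels <- c(rep("fixed1", nf), rep("fixed2", nf),
                rep("random_setA", nr), rep("random_setB", nr))
    cond <- c(fixed1 = "fixed", fixed2 = "fixed",
              random_setA = "random", random_setB = "random")
    ord <- shuffle_with_run_cap(labels, cond, spec$max_same_condition_run)
    valid <- list(random_setA = valid_orderings(sequences$random_setA, grid),
                  random_setB = valid_orderings(sequences$random_setB, grid))
    mbs <- lapply(seq_along(ord), function(i) {
      role <- ord[i]
      if (cond[role] == "fixed") {
        locs <- sequences[[role]]
      } else {
        v <- valid[[role]]
        if (nrow(v) == 0L) stop("random set ", role, " admits no valid ordering")
        locs <- v[sample.int(nrow(v), 1L), ]
      }
      mb_tibble(i, unname(cond[role]), role, locs, rep("plain", 4L))
    })
    dplyr::bind_rows(mbs)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Lookup tables over the two fixed sequences: learned serial position,
# sequence role, and learned predecessor of each fixed-sequence location.
fixed_lookup <- function(fixed1, fixed2) {
  pos <- integer(0)
  role <- character(0)
  pred <- integer(0)
  for (r in c("fixed1", "fixed2")) {
    sq <- if (r == "fixed1") fixed1 else fixed2
    pos[as.character(sq)] <- 1:4
    role[as.character(sq)] <- r
    pred[as.character(sq)] <- c(NA_integer_, sq[-4L])
  }
  list(pos = pos, role = role, pred = pred)
}

# Classify the 4 trials of one transfer mini-block from first principles.
# `trained` is the set of all locations used in training blocks (fixed and
# random sets); locations outside it are new (reserved) locations.
classify_locs <- function(locs, lk, trained) {
  tags <- rep("plain", 4L)
  for (p in 1:4) {
    loc <- locs[p]
    key <- as.character(loc)
    if (!(loc %in% trained)) {
      tags[p] <- "new_location"
      next
    }
    if (is.na(lk$pos[key])) next # random-set item: no sequence structure
    learned_pos <- lk$pos[[key]]
    learned_pred <- lk$pred[[key]]
    prev <- if (p > 1L) locs[p - 1L] else NA_integer_
    prev_trained <- !is.na(prev) && prev %in% trained
    if (learned_pos == p) {
      if (p == 1L || !prev_trained) tags[p] <- "ordinal_test"
    } else if (p > 1L && !is.na(learned_pred) && !is.na(prev) &&
               prev == learned_pred) {
      tags[p] <- "order_test"
    } else if (p > 1L && prev_trained && !is.na(lk$role[as.character(prev)])) {
      tags[p] <- "control_test"
    }
  }
  tags
}

#' Build one ordinal-only transfer mini-block
#'
#' One fixed-sequence item is shown at its learned serial position (the
#' ordinal-only test trial); the remaining three trials use reserved,
#' never-trained locations (new-location trials).  Because the surrounding
#' items were never seen, no item-item association can cue the test item, so
#' any advantage on it isolates serial position-item knowledge.
#'
#' @param fixed Ordered 4-location fixed sequence the test item comes from.
#' @param test_position Learned serial position (1..4) of the test item; the
#'   item is shown at that same position.
#' @param reserved Pool of never-trained locations.
#' @param seed Optional seed.
#' @param grid The location grid.
#' @return Tibble of 4 trials with tags `ordinal_test` / `new_location`.
#' @export
make_ordinal_only_miniblock <- function(fixed, test_position, reserved,
                                        seed = NULL, grid = make_grid()) {
  stopifnot(test_position %in% 1:4, length(reserved) >= 3L)
  build <- function() {
    for (try in 1:1000) {
      locs <- integer(4L)
      locs[test_position] <- fixed[test_position]
      locs[-test_position] <- sample(reserved, 3L)
      if (!has_adjacent_pair(locs, grid)) {
        tags <- rep("new_location", 4L)
        tags[test_position] <- "ordinal_test"
        return(mb_tibble(1L, "ordinal_only", NA_character_, locs, tags))
      }
    }
    stop("could not build ordinal-only mini-block without adjacent pairs")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Build one order-only transfer mini-block
#'
#' The mini-block is assembled from trained fixed-sequence items only:
#' exactly one consecutive pair preserves a learned transition, with the
#' second pair member (the order-only test trial) at a wrong serial position,
#' so only an item-item association can cue it.  One item from the other
#' fixed sequence sits at its correct serial position (mirroring the
#' published construction), and the remaining same-sequence item sits at a
#' wrong position preceded by a trained non-predecessor, yielding at least
#' one control trial per mini-block.
#'
#' @param fixed_test Ordered fixed sequence supplying the preserved pair.
#' @param fixed_other The other ordered fixed sequence.
#' @param pair_index Which learned transition to preserve (1..3: item
#'   `pair_index` followed by item `pair_index + 1`).
#' @param seed Optional seed.
#' @param grid The location grid.
#' @return Tibble of 4 trials; tags include one `order_test` and at least one
#'   `control_test`.
#' @export
make_order_only_miniblock <- function(fixed_test, fixed_other,
                                      pair_index = NULL, seed = NULL,
                                      grid = make_grid()) {
  build <- function() {
    pis <- if (is.null(pair_index)) 1:3 else pair_index
    cand <- do.call(c, lapply(pis, function(pi) {
      order_only_assemblies(fixed_test, fixed_other, pi, grid)
    }))
    if (length(cand) == 0L) {
      stop("no valid order-only mini-block for pair index ",
           paste(pis, collapse = "/"), " of sequence {",
           paste(fixed_test, collapse = ", "), "}")
    }
    a <- cand[[sample.int(length(cand), 1L)]]
    mb_tibble(1L, "order_only", NA_character_, a$locs, a$tags)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Enumerate every admissible order-only assembly for one preserved
# transition: the pair at slots (j, j+1), one other-sequence item at its
# correct serial position, one same-sequence filler at a wrong position;
# accepted iff the adjacency constraint holds and classification yields
# exactly one order-only test, no ordinal test and at least one control.
order_only_assemblies <- function(fixed_test, fixed_other, pair_index, grid) {
  lk <- fixed_lookup(fixed_test, fixed_other)
  trained <- c(fixed_test, fixed_other)
  x <- fixed_test[pair_index]
  y <- fixed_test[pair_index + 1L]
  out <- list()
  for (j in setdiff(1:3, pair_index)) { # y must sit at a wrong position
    rem <- setdiff(1:4, c(j, j + 1L))
    for (k in setdiff(rem, 1L)) { # correct-position slot (never slot 1)
      m <- setdiff(rem, k)
      fillers <- setdiff(fixed_test, c(x, y))
      fillers <- fillers[match(fillers, fixed_test) != m]
      for (f in fillers) {
        locs <- integer(4L)
        locs[j] <- x
        locs[j + 1L] <- y
        locs[k] <- fixed_other[k]
        locs[m] <- f
        if (has_adjacent_pair(locs, grid)) next
        tags <- classify_locs(locs, lk, trained)
        if (sum(tags == "order_test") == 1L && tags[j + 1L] == "order_test" &&
            !any(tags == "ordinal_test") && any(tags == "control_test")) {
          out[[length(out) + 1L]] <- list(locs = locs, tags = tags)
        }
      }
    }
  }
  out
}

#' Generate one transfer block (24 mini-blocks, 96 trials)
#'
#' Eight ordinal-only, eight order-only and eight random-transfer mini-blocks
#' are interleaved pseudo-randomly with the same run cap as training blocks.
#' Over the eight ordinal-only mini-blocks each of the eight fixed-sequence
#' items serves as test item exactly once (at its learned position); the
#' order-only mini-blocks draw their preserved transition evenly from both
#' sequences.  Random-transfer mini-blocks reuse the random training sets in
#' fresh orders and are generated but not analyzed.
#'
#' @inheritParams make_training_block
#' @return Tibble of 96 trials.
#' @export
make_transfer_block <- function(spec, sequences, seed = NULL,
                                grid = make_grid()) {
  build <- function() {
    comp <- spec$transfer_composition
    labels <- rep(names(comp), times = comp)
    ord <- shuffle_with_run_cap(labels, setNames(names(comp), names(comp)),
                                spec$max_same_condition_run)

    # Ordinal-only: each fixed item once, at its learned position.
    ordinal_jobs <- data.frame(
      role = rep(c("fixed1", "fixed2"), each = 4L),
      position = rep(1:4, times = 2L)
    )
    ordinal_jobs <- ordinal_jobs[sample.int(nrow(ordinal_jobs)), ]
    # Order-only: 4 preserved transitions from each sequence, cycling evenly
    # through the pair indices that admit a valid assembly under adjacency.
    feasible <- lapply(c(fixed1 = "fixed1", fixed2 = "fixed2"), function(r) {
      other <- if (r == "fixed1") "fixed2" else "fixed1"
      ok <- vapply(1:3, function(pi) {
        length(order_only_assemblies(sequences[[r]], sequences[[other]],
                                     pi, grid)) > 0L
      }, logical(1))
      which(ok)
    })
    if (any(lengths(feasible) == 0L)) {
      stop("a fixed sequence admits no order-only mini-block at all")
    }
    order_jobs <- do.call(rbind, lapply(c("fixed1", "fixed2"), function(r) {
      data.frame(role = r, pair = sample(rep(feasible[[r]], length.out = 4L)))
    }))
    order_jobs <- order_jobs[sample.int(nrow(order_jobs)), ]
    random_roles <- sample(rep(c("random_setA", "random_setB"), each = 4L))
    valid <- list(random_setA = valid_orderings(sequences$random_setA, grid),
                  random_setB = valid_orderings(sequences$random_setB, grid))

    io <- 1L; ip <- 1L; ir <- 1L
    mbs <- vector("list", length(ord))
    for (i in seq_along(ord)) {
      type <- ord[i]
      if (type == "ordinal_only") {
        job <- ordinal_jobs[io, ]; io <- io + 1L
        mb <- make_ordinal_only_miniblock(sequences[[job$role]], job$position,
                                          sequences$reserved, grid = grid)
        mb$sequence_role <- job$role
      } else if (type == "order_only") {
        job <- order_jobs[ip, ]; ip <- ip + 1L
        other <- if (job$role == "fixed1") "fixed2" else "fixed1"
        mb <- make_order_only_miniblock(sequences[[job$role]],
                                        sequences[[other]],
                                        pair_index = job$pair, grid = grid)
        mb$sequence_role <- job$role
      } else {
        role <- random_roles[ir]; ir <- ir + 1L
        v <- valid[[role]]
        locs <- v[sample.int(nrow(v), 1L), ]
        mb <- mb_tibble(1L, "random_transfer", role, locs, rep("plain", 4L))
      }
      mb$mini_block <- i
      mbs[[i]] <- mb
    }
    dplyr::bind_rows(mbs)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Assign left/right responses within a block
#'
#' Response sides (the tilt of the target letter) are drawn so that each
#' 96-trial block contains exactly 48 left and 48 right responses; no balance
#' is enforced within mini-blocks.
#'
#' @param block Tibble of trials of one block (even row count).
#' @param seed Optional seed.
#' @return The block with a `response_side` column filled.
#' @export
assign_response_sides <- function(block, seed = NULL) {
  n <- nrow(block)
  if (n %% 2L != 0L) stop("block has an odd number of trials (", n, ")")
  draw <- function() sample(rep(c("left", "right"), n / 2L))
  block$response_side <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  block
}

#' Generate the full trial table for one participant
#'
#' Three sessions of 18 blocks (96 trials each); within each session blocks
#' 6, 12 and 18 are transfer blocks and the other 15 are training blocks, so
#' each fixed sequence is practiced 120 times and each random set 60 times
#' per session.  Regenerating with the same spec seed and participant index
#' yields a bit-identical table.
#'
#' @param spec A [design_spec()].
#' @param participant Participant index (1-based; role counterbalancing
#'   rotates over an 8-participant cycle).
#' @param grid The location grid.
#' @return Tibble with one row per trial (columns `participant`, `session`,
#'   `block`, `mini_block`, `serial_position`, `condition`, `sequence_role`,
#'   `location`, `tag`, `response_side`, `rt_ms`, `correct`), with the
#'   location assignment stored in `attr(, "sequences")` and the spec in
#'   `attr(, "spec")`.
#' @export
make_experiment <- function(spec = design_spec(), participant = 1L,
                            grid = make_grid()) {
  sequences <- experiment_sequences(spec, participant, grid)
  trials <- withr::with_seed(derive_seed(spec$seed, 1000L + participant), {
    sessions <- lapply(seq_len(spec$n_sessions), function(s) {
      blocks <- lapply(seq_len(spec$blocks_per_session), function(b) {
        blk <- if (b %in% spec$transfer_block_positions) {
          make_transfer_block(spec, sequences, grid = grid)
        } else {
          make_training_block(spec, sequences, grid = grid)
        }
        blk <- assign_response_sides(blk)
        blk$session <- s
        blk$block <- b
        blk
      })
      dplyr::bind_rows(blocks)
    })
    dplyr::bind_rows(sessions)
  })
  trials$participant <- as.integer(participant)
  trials$rt_ms <- NA_real_
  trials$correct <- NA
  trials <- trials[, c("participant", "session", "block", "mini_block",
                       "serial_position", "condition", "sequence_role",
                       "location", "tag", "response_side", "rt_ms", "correct")]
  attr(trials, "sequences") <- sequences
  attr(trials, "spec") <- spec
  trials
}

#' Recompute and verify transfer-trial tags from first principles
#'
#' Re-derives the analysis tag of every transfer-block trial from the trial
#' table alone: a never-trained location is `new_location`; a fixed-sequence
#' item at its learned position whose predecessor (if any) is untrained is
#' `ordinal_test`; a fixed-sequence item preceded by its learned predecessor
#' at a wrong position is `order_test`; a fixed-sequence item at a wrong
#' position preceded by a trained non-predecessor is `control_test`;
#' everything else is `plain`.  An error is raised if any recomputed tag
#' disagrees with the generator's tag.
#'
#' @param trials A trial table from [make_experiment()] (training blocks must
#'   be present unless `trained` is given).
#' @param fixed1,fixed2 Ordered fixed sequences; default taken from
#'   `attr(trials, "sequences")`.
#' @param trained All locations used during training; default inferred from
#'   the training-block rows.
#' @return `trials` with tags recomputed (identical to input if verification
#'   passes).
#' @export
classify_transfer_trials <- function(trials, fixed1 = NULL, fixed2 = NULL,
                                     trained = NULL) {
  seqs <- attr(trials, "sequences")
  if (is.null(fixed1)) fixed1 <- seqs$fixed1
  if (is.null(fixed2)) fixed2 <- seqs$fixed2
  if (is.null(fixed1) || is.null(fixed2)) {
    stop("fixed sequences not supplied and not stored on the trial table")
  }
  if (is.null(trained)) {
    trained <- unique(trials$location[trials$condition %in% c("fixed", "random")])
    if (length(trained) == 0L) stop("no training trials to infer trained locations")
  }
  lk <- fixed_lookup(fixed1, fixed2)
  transfer_conditions <- c("ordinal_only", "order_only", "random_transfer")
  idx <- which(trials$condition %in% transfer_conditions)
  if (length(idx) == 0L) stop("no transfer trials present")
  key <- paste(trials$participant[idx], trials$session[idx],
               trials$block[idx], trials$mini_block[idx])
  new_tags <- trials$tag
  for (mb in split(idx, key)) {
    ord <- mb[order(trials$serial_position[mb])]
    new_tags[ord] <- classify_locs(trials$location[ord], lk, trained)
  }
  bad <- which(new_tags != trials$tag)
  if (length(bad) > 0L) {
    b <- bad[1L]
    stop(sprintf(
      "tag mismatch at participant %s session %s block %s mini-block %s position %s: generated '%s', recomputed '%s'",
      trials$participant[b], trials$session[b], trials$block[b],
      trials$mini_block[b], trials$serial_position[b], trials$tag[b],
      new_tags[b]))
  }
  trials$tag <- new_tags
  trials
}
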