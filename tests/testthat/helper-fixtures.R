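# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Full three-session experiment for one participant (seed fixed).
full_experiment <- function() {
  if (is.null(fixture_env$experiment)) {
    fixture_env$experiment <- make_experiment(design_spec(seed = 42L),
                                              participant = 1L)
  }
  fixture_env$experiment
}

# Small cohort of deterministic designs, reused wherever a cohort is needed.
cohort_designs <- function(n = 6L) {
  key <- paste0("designs", n)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- lapply(seq_len(n), function(p) {
      make_experiment(design_spec(seed = 42L), participant = p)
    })
  }
  fixture_env[[key]]
}

# Mini-block-wise location lists of a trial table, in presentation order.
miniblock_locations <- function(trials) {
  key <- paste(trials$participant, trials$session, trials$block,
               trials$mini_block)
  lapply(split(seq_len(nrow(trials)), factor(key, levels = unique(key))),
         function(i) trials$location[i][order(trials$serial_position[i])])
}
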