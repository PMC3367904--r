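#' Parameters of the generative two-source RT model
#'
#' Reaction times arise from a shifted-lognormal visual-search baseline that
#' is shortened by retrieval from up to two learned association sources:
#' a serial position-item source that rises quickly to its asymptote and an
#' item-item (chaining) source that accumulates slowly over training.  The
#' two sources are expressed either through an independent race (the faster
#' noisy retrieval wins) or through coactivation (facilitations pool into a
#' single process, with an over-additive bonus when both cues are present).
#'
#' Default values state the world the analyses target: a ~1 s right-skewed
#' search baseline; a position-item asymptote of 88 ms reached within the
#' first session (rate 0.1 per exposure) and an item-item asymptote of 120 ms
#' still rising in session three (rate 0.004 per exposure), so that the
#' ordinal-only advantage is session-stable while the order-only advantage
#' grows; and a coactivation bonus of 66 ms, the observed excess of the
#' combined fixed-sequence advantage over the additive single-source
#' prediction.
#'
#' @param baseline_mu,baseline_sigma,baseline_shift Log-mean, log-SD and
#'   shift (ms) of the baseline RT distribution
#'   `shift + rlnorm(mu, sigma)`.
#' @param s_pos_asym,s_pos_rate Asymptote (ms) and exponential rate per
#'   exposure of the position-item learning curve.
#' @param s_item_asym,s_item_rate Same for the item-item curve.
#' @param architecture `"race"` or `"coactivation"`.
#' @param race_channel_sigma SD (ms) of per-cue retrieval-time noise in the
#'   race architecture.
#' @param coact_bonus Over-additive facilitation (ms) added under
#'   coactivation when both cues are available.
#' @param error_rate Probability of an erroneous response per trial.
#' @param n_participants Default cohort size (the analyzed sample size of the
#'   target experiment).
#' @param between_subject_sd Log-SD of the lognormal multiplicative
#'   heterogeneity applied to both asymptotes per participant.
#' @param seed Base seed for cohort simulation.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(baseline_mu = log(650), baseline_sigma = 0.35,
                       baseline_shift = 300,
                       s_pos_asym = 88, s_pos_rate = 0.1,
                       s_item_asym = 120, s_item_rate = 0.004,
                       architecture = c("race", "coactivation"),
                       race_channel_sigma = 30, coact_bonus = 66,
                       error_rate = 0.03, n_participants = 21L,
                       between_subject_sd = 0.2, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(s_pos_rate >= 0, s_item_rate >= 0, s_pos_asym >= 0,
            s_item_asym >= 0, error_rate >= 0, error_rate < 1,
            race_channel_sigma >= 0, coact_bonus >= 0,
            between_subject_sd >= 0)
  structure(
    list(baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
         baseline_shift = baseline_shift,
         s_pos_asym = s_pos_asym, s_pos_rate = s_pos_rate,
         s_item_asym = s_item_asym, s_item_rate = s_item_rate,
         architecture = architecture,
         race_channel_sigma = race_channel_sigma, coact_bonus = coact_bonus,
         error_rate = error_rate, n_participants = as.integer(n_participants),
         between_subject_sd = between_subject_sd, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Exponential practice curve
#'
#' Facilitation after `n` exposures: `asym * (1 - exp(-rate * n))`.  Zero at
#' `n = 0`, non-decreasing, bounded by the asymptote.
#'
#' @param n Exposure count(s), >= 0.
#' @param asym Asymptotic facilitation (ms), >= 0.
#' @param rate Learning rate per exposure, >= 0.
#' @return Facilitation in ms (vectorized over `n`).
#' @export
learning_curve <- function(n, asym, rate) {
  if (any(n < 0) || any(asym < 0) || any(rate < 0)) {
    stop("learning_curve() requires non-negative n, asym and rate")
  }
  asym * (1 - exp(-rate * n))
}

# Baseline RT draws.
baseline_draw <- function(n, params) {
  params$baseline_shift + rlnorm(n, params$baseline_mu, params$baseline_sigma)
}

#' Draw trial RTs given available association cues
#'
#' Under the race architecture each available cue contributes a noisy
#' facilitation draw (`s_cue + noise`, floored at 0) and the largest
#' facilitation wins, so the realized RT is the minimum of the per-channel
#' finishing times and satisfies the race model inequality by construction.
#' Under coactivation the available facilitations add deterministically and,
#' when both cues are present, an over-additive bonus is applied.  RTs are
#' floored at 100 ms.
#'
#' @param s_pos,s_item Current facilitation magnitudes (ms); scalars or
#'   length-`n` vectors.
#' @param cue_pos,cue_item Logical (scalar or length `n`): is the respective
#'   cue available on the trial?
#' @param params A [sim_params()].
#' @param n Number of draws.
#' @return Numeric vector of `n` RTs (ms).
#' @export
trial_rt <- function(s_pos, s_item, cue_pos, cue_item, params, n = 1L) {
  base <- baseline_draw(n, params)
  cue_pos <- rep_len(cue_pos, n)
  cue_item <- rep_len(cue_item, n)
  s_pos <- rep_len(s_pos, n)
  s_item <- rep_len(s_item, n)
  if (params$architecture == "race") {
    draw_pos <- ifelse(cue_pos,
                       pmax(s_pos + rnorm(n, 0, params$race_channel_sigma), 0),
                       0)
    draw_item <- ifelse(cue_item,
                        pmax(s_item + rnorm(n, 0, params$race_channel_sigma), 0),
                        0)
    facil <- pmax(draw_pos, draw_item)
  } else {
    facil <- ifelse(cue_pos, s_pos, 0) + ifelse(cue_item, s_item, 0) +
      ifelse(cue_pos & cue_item, params$coact_bonus, 0)
  }
  pmax(base - facil, 100)
}

# Cue availability by analysis tag/condition: fixed-sequence trials carry
# both cues, ordinal-only tests the position cue, order-only tests the item
# cue, everything else none.
cue_flags <- function(condition, tag) {
  list(pos = condition == "fixed" | tag == "ordinal_test",
       item = condition == "fixed" | tag == "order_test")
}

#' Simulate RTs and accuracy for one participant's trial table
#'
#' Exposure counters for each fixed sequence advance with every fixed
#' mini-block of that sequence (cumulatively across sessions); facilitation
#' on a trial follows the learning curves at the exposure count reached
#' before its mini-block.  Errors occur i.i.d. at `error_rate`; RTs on error
#' trials are drawn from the baseline distribution (no facilitation).
#' Asymptotes are scaled by a per-participant lognormal factor (mean 1).
#'
#' @param trials Trial table from [make_experiment()].
#' @param params A [sim_params()].
#' @param seed Seed for this participant's draws (deterministic given seed).
#' @param sequences Location assignment; default `attr(trials, "sequences")`.
#' @return `trials` with `rt_ms` and `correct` filled.
#' @export
simulate_participant <- function(trials, params = sim_params(),
                                 seed = params$seed,
                                 sequences = attr(trials, "sequences")) {
  if (is.null(sequences)) stop("trial table carries no sequence attribute")
  withr::with_seed(seed, {
    n <- nrow(trials)
    het <- rlnorm(1L, -params$between_subject_sd^2 / 2, params$between_subject_sd)

    # Exposure count of each fixed sequence before each trial's mini-block.
    mb_key <- paste(trials$session, trials$block, trials$mini_block)
    mb_id <- match(mb_key, unique(mb_key)) # unique() keeps presentation order
    exposures <- matrix(0, max(mb_id), 2L,
                        dimnames = list(NULL, c("fixed1", "fixed2")))
    first_row <- !duplicated(mb_id)
    for (r in c("fixed1", "fixed2")) {
      is_fixed_mb <- trials$condition[first_row] == "fixed" &
        trials$sequence_role[first_row] == r
      exposures[, r] <- cumsum(is_fixed_mb) - as.integer(is_fixed_mb)
    }

    # Sequence membership of each trial's item (for transfer test trials).
    role_of_item <- rep(NA_character_, 32L)
    role_of_item[sequences$fixed1 + 1L] <- "fixed1"
    role_of_item[sequences$fixed2 + 1L] <- "fixed2"
    src <- ifelse(trials$condition == "fixed", trials$sequence_role,
                  role_of_item[trials$location + 1L])

    expo <- rep(0, n)
    has_src <- !is.na(src)
    expo[has_src] <- exposures[cbind(mb_id[has_src],
                                     match(src[has_src], c("fixed1", "fixed2")))]

    s_pos <- learning_curve(expo, params$s_pos_asym * het, params$s_pos_rate)
    s_item <- learning_curve(expo, params$s_item_asym * het, params$s_item_rate)
    cues <- cue_flags(trials$condition, trials$tag)

    rt <- trial_rt(s_pos, s_item, cues$pos, cues$item, params, n = n)
    correct <- runif(n) >= params$error_rate
    rt[!correct] <- pmax(baseline_draw(sum(!correct), params), 100)
    trials$rt_ms <- rt
    trials$correct <- correct
    trials
  })
}

#' Simulate a cohort of participants
#'
#' Generates (or reuses) one design per participant and simulates RTs for
#' each.  Passing a pre-built list of designs skips the design generation,
#' which is useful when many cohorts share the same deterministic designs and
#' only the RT noise varies.
#'
#' @param spec A [design_spec()]; ignored when `designs` is supplied.
#' @param params A [sim_params()].
#' @param n_participants Number of participants; default `params$n_participants`.
#' @param designs Optional list of trial tables from [make_experiment()].
#' @param seed Base seed for the RT draws.
#' @return Combined trial tibble for the cohort.
#' @export
simulate_cohort <- function(spec = design_spec(), params = sim_params(),
                            n_participants = params$n_participants,
                            designs = NULL, seed = params$seed) {
  if (is.null(designs)) {
    designs <- lapply(seq_len(n_participants), function(p) {
      make_experiment(spec, participant = p)
    })
  }
  sims <- lapply(seq_along(designs), function(p) {
    simulate_participant(designs[[p]], params,
                         seed = derive_seed(seed, 5000L + p))
  })
  dplyr::bind_rows(sims)
}

#' Fast condition-level RT samples for race-model studies
#'
#' Draws per-participant RT samples for the three conditions entering the
#' race model inequality test -- fixed-sequence (both cues), ordinal-only
#' (position cue) and order-only (item cue) -- directly from the trial-level
#' RT model at asymptotic association strength, without generating a full
#' design.  This is the reduced-trial-count path used for large simulation
#' studies of the test's validity.
#'
#' @param params A [sim_params()].
#' @param n_participants Cohort size.
#' @param n_fixed,n_single Trials per participant in the fixed and in each
#'   single-cue condition.
#' @param seed Seed.
#' @return Tibble with columns `participant`, `condition`
#'   (`fixed`/`ordinal`/`order`) and `rt_ms`.
#' @export
simulate_condition_rts <- function(params = sim_params(),
                                   n_participants = params$n_participants,
                                   n_fixed = 240L, n_single = 60L,
                                   seed = params$seed) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_participants), function(p) {
      het <- rlnorm(1L, -params$between_subject_sd^2 / 2,
                    params$between_subject_sd)
      sp <- params$s_pos_asym * het
      si <- params$s_item_asym * het
      tibble::tibble(
        participant = p,
        condition = rep(c("fixed", "ordinal", "order"),
                        times = c(n_fixed, n_single, n_single)),
        rt_ms = c(trial_rt(sp, si, TRUE, TRUE, params, n = n_fixed),
                  trial_rt(sp, si, TRUE, FALSE, params, n = n_single),
                  trial_rt(sp, si, FALSE, TRUE, params, n = n_single))
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a post-experiment verbal report
#'
#' Each reported position reproduces the true item with probability `k`
#' (when still available) and is otherwise drawn uniformly from the
#' locations not yet reported, so `k = 0` reproduces the guessing null
#' exactly and `k = 1` reproduces the true sequence.
#'
#' @param truth Ordered vector of true locations (length 4).
#' @param k Knowledge level in \[0, 1\].
#' @param n_locations Size of the location pool.
#' @param seed Optional seed.
#' @return Integer vector: the reported ordered locations.
#' @export
simulate_report <- function(truth, k, n_locations = 32L, seed = NULL) {
  stopifnot(k >= 0, k <= 1, length(truth) <= n_locations)
  draw <- function() {
    available <- setdiff(seq_len(n_locations) - 1L, integer(0))
    report <- integer(length(truth))
    for (i in seq_along(truth)) {
      if (runif(1L) < k && truth[i] %in% available) {
        report[i] <- truth[i]
      } else {
        report[i] <- if (length(available) == 1L) available else sample(available, 1L)
      }
      available <- setdiff(available, report[i])
    }
    report
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
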