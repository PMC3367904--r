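#' Run the standard analysis pipeline on a simulated or observed cohort
#'
#' Applies the exclusion rules, computes per-block cell medians and returns
#' the condition difference scores together with session-level summaries of
#' the three transfer contrasts.
#'
#' @param data Cohort trial table with `rt_ms` and `correct` filled.
#' @return List with `medians`, `contrasts` (per participant x block) and
#'   `session_scores` (per participant x session means of each contrast).
#' @export
analyze_cohort <- function(data) {
  clean <- exclude_trials(data)
  medians <- cell_medians(clean)
  contrasts <- transfer_contrasts(medians)
  session_scores <- dplyr::summarise(
    dplyr::group_by(contrasts, .data$participant, .data$session, .data$contrast),
    value_ms = mean(.data$value_ms, na.rm = TRUE),
    .groups = "drop"
  )
  list(medians = medians, contrasts = contrasts,
       session_scores = session_scores)
}

#' Simulation study of the race model inequality test
#'
#' Repeatedly simulates cohorts from the trial-level RT model (via
#' [simulate_condition_rts()], the reduced-trial-count path) and records
#' whether [rmi_test()] declares a violation in each.  Under the race
#' architecture the violation rate estimates the test's type-I error; under
#' coactivation with a sizeable interaction bonus it estimates power.
#'
#' @param params A [sim_params()].
#' @param n_cohorts Number of simulated cohorts.
#' @param n_participants Participants per cohort.
#' @param n_fixed,n_single Trials per participant per condition.
#' @param restricted_levels,alpha Passed to [rmi_test()].
#' @param seed Base seed.
#' @return Logical vector of per-cohort violation decisions.
#' @export
rmi_simulation_study <- function(params, n_cohorts = 500L,
                                 n_participants = params$n_participants,
                                 n_fixed = 240L, n_single = 60L,
                                 restricted_levels = c(0.05, 0.15),
                                 alpha = 0.05, seed = params$seed) {
  vapply(seq_len(n_cohorts), function(i) {
    d <- simulate_condition_rts(params, n_participants, n_fixed, n_single,
                                seed = derive_seed(seed, 20000L + i))
    pcts <- rmi_percentiles(d)
    rmi_test(pcts, restricted_levels, alpha)$violation
  }, logical(1))
}
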