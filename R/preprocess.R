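#' Exclude error trials and trials following errors
#'
#' Removes every erroneous response and the response immediately following
#' it (within participant and session, across mini-block boundaries).  The
#' rule is idempotent: the follower of a removed error is removed once.
#'
#' @param data Trial table with `correct` logical and the standard index
#'   columns.
#' @return Filtered trial table.
#' @export
exclude_trials <- function(data) {
  if (!"correct" %in% names(data) || all(is.na(data$correct))) {
    stop("exclude_trials() needs a filled 'correct' column")
  }
  ord <- order(data$participant, data$session, data$block, data$mini_block,
               data$serial_position)
  data <- data[ord, ]
  grp <- paste(data$participant, data$session)
  err <- !data$correct
  prev_err <- c(FALSE, err[-length(err)])
  prev_err[!duplicated(grp)] <- FALSE # session boundary: no carry-over
  data[!(err | prev_err), ]
}

# Analysis cell of each trial: training trials by sequence condition,
# transfer trials by their test tag; other trials get NA and drop out.
analysis_cell <- function(condition, tag) {
  cell <- rep(NA_character_, length(condition))
  cell[condition == "fixed"] <- "fixed"
  cell[condition == "random"] <- "random"
  test <- tag %in% c("ordinal_test", "order_test", "control_test", "new_location")
  cell[test] <- tag[test]
  cell
}

#' Per-cell median RTs
#'
#' Computes the median RT per participant and factor cell (even-count
#' medians are the mean of the two central order statistics), recording the
#' number of contributing trials.  Apply [exclude_trials()] first; all
#' analyses are based on these medians to blunt the influence of RT
#' outliers.
#'
#' @param data Filtered trial table.
#' @param by Grouping columns; the special column `cell` (the analysis cell
#'   derived from condition and tag) is added automatically when requested.
#' @return Tibble with the grouping columns plus `median_rt_ms` and
#'   `n_trials`.
#' @export
cell_medians <- function(data,
                         by = c("participant", "session", "block", "cell")) {
  if ("cell" %in% by && !"cell" %in% names(data)) {
    data$cell <- analysis_cell(data$condition, data$tag)
    data <- data[!is.na(data$cell), ]
  }
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    median_rt_ms = median(.data$rt_ms),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Condition difference scores
#'
#' Computes, per participant, the contrasts used throughout the analyses.
#' Every value is `median(reference) - median(test)`, so a positive value
#' always means the *test* condition was faster than its reference:
#'
#' * `fixed_vs_random` (one per training block): random minus fixed.
#' * `ordinal_vs_new`, `order_vs_new`, `control_vs_new` (one per transfer
#'   block): new-location trials of the ordinal-only condition minus the
#'   respective test trials.
#' * `ordinal_vs_fixed`, `order_vs_fixed`, `control_vs_fixed`: the fixed
#'   sequence median of the immediately preceding training block minus the
#'   test trials (negative values mean the test trials were slower than
#'   intact fixed sequences).
#'
#' @param medians Output of [cell_medians()] grouped by participant, session,
#'   block and cell.
#' @return Tibble with columns `participant`, `session`, `block`, `contrast`,
#'   `value_ms`.
#' @export
transfer_contrasts <- function(medians) {
  need <- c("participant", "session", "block", "cell", "median_rt_ms")
  if (!all(need %in% names(medians))) {
    stop("medians must have columns ", paste(need, collapse = ", "))
  }
  wide <- medians |>
    dplyr::select(dplyr::all_of(c(need))) |>
    tidyr_pivot(names_from = "cell", values_from = "median_rt_ms")
  cells <- c("fixed", "random", "ordinal_test", "order_test", "control_test",
             "new_location")
  for (cc in setdiff(cells, names(wide))) wide[[cc]] <- NA_real_

  out <- list()
  # Training blocks: fixed vs random.
  train <- wide[!is.na(wide$fixed) & !is.na(wide$random), ]
  if (nrow(train) > 0L) {
    out$fvr <- tibble::tibble(
      participant = train$participant, session = train$session,
      block = train$block, contrast = "fixed_vs_random",
      value_ms = train$random - train$fixed
    )
  }
  # Transfer blocks: reference = new-location trials and the previous
  # training block's fixed-sequence median.
  transfer <- wide[!is.na(wide$new_location), ]
  if (nrow(transfer) > 0L) {
    prev_fixed <- wide[!is.na(wide$fixed), c("participant", "session", "block", "fixed")]
    key_prev <- paste(prev_fixed$participant, prev_fixed$session, prev_fixed$block)
    idx <- match(paste(transfer$participant, transfer$session, transfer$block - 1L),
                 key_prev)
    if (anyNA(idx)) {
      stop("missing fixed-sequence reference block before a transfer block")
    }
    fixed_ref <- prev_fixed$fixed[idx]
    mk <- function(test, contrast, ref) {
      tibble::tibble(participant = transfer$participant,
                     session = transfer$session, block = transfer$block,
                     contrast = contrast, value_ms = ref - test)
    }
    out$c1 <- mk(transfer$ordinal_test, "ordinal_vs_new", transfer$new_location)
    out$c2 <- mk(transfer$order_test, "order_vs_new", transfer$new_location)
    out$c3 <- mk(transfer$control_test, "control_vs_new", transfer$new_location)
    out$c4 <- mk(transfer$ordinal_test, "ordinal_vs_fixed", fixed_ref)
    out$c5 <- mk(transfer$order_test, "order_vs_fixed", fixed_ref)
    out$c6 <- mk(transfer$control_test, "control_vs_fixed", fixed_ref)
  }
  if (length(out) == 0L) stop("no analyzable cells in medians table")
  dplyr::bind_rows(out)
}

# Minimal long-to-wide reshape (avoids a tidyr dependency): one row per
# participant x session x block, one column per cell.
tidyr_pivot <- function(df, names_from, values_from) {
  keys <- setdiff(names(df), c(names_from, values_from))
  key <- do.call(paste, df[keys])
  ukey <- !duplicated(key)
  out <- df[ukey, keys]
  for (v in unique(df[[names_from]])) {
    sel <- df[[names_from]] == v
    out[[v]] <- df[[values_from]][sel][match(key[ukey], key[sel])]
  }
  out
}
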