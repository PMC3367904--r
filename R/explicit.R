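#' Count ordered hits of a reported sequence
#'
#' A hit is a reported location that matches the true sequence at the same
#' serial position; location identity alone does not count.
#'
#' @param report,truth Ordered location vectors of equal length with
#'   distinct entries.
#' @return Integer number of positions that match exactly.
#' @export
count_ordered_hits <- function(report, truth) {
  if (length(report) != length(truth)) {
    stop("report and truth must have the same length")
  }
  if (anyDuplicated(report) || anyDuplicated(truth)) {
    stop("report and truth entries must be distinct")
  }
  sum(report == truth)
}

#' Exact guessing-null distribution of ordered hits
#'
#' Distribution of the number of positional matches between a fixed target
#' sequence of `list_len` distinct locations and a uniformly random ordered
#' draw of `list_len` distinct locations from a pool of `n_locations`.
#' Computed either by exhaustive enumeration of all ordered draws (small
#' pools) or by a rencontres-style inclusion-exclusion sum; both agree
#' exactly.
#'
#' @param n_locations Pool size (default 32).
#' @param list_len Report length (default 4).
#' @param method `"auto"` (enumerate when feasible), `"enumerate"` or
#'   `"closed_form"`.
#' @return Named list with `p` (P(hits = k), k = 0..list_len) and `tail`
#'   (P(hits >= k)).
#' @export
exact_ordered_null <- function(n_locations = 32L, list_len = 4L,
                               method = c("auto", "enumerate", "closed_form")) {
  method <- match.arg(method)
  n <- as.integer(n_locations)
  m <- as.integer(list_len)
  if (m < 1L || n < m) stop("need 1 <= list_len <= n_locations")
  n_tuples <- prod(seq(n, n - m + 1L)) # falling factorial n_(m)
  if (method == "auto") {
    method <- if (n <= 12L && n_tuples <= 2e5) "enumerate" else "closed_form"
  }
  if (method == "enumerate") {
    if (n_tuples > 2e6) stop("enumeration infeasible for this pool size")
    truth <- seq_len(m)
    tuples <- ordered_tuples(n, m)
    hits <- rowSums(tuples == matrix(truth, nrow(tuples), m, byrow = TRUE))
    p <- tabulate(hits + 1L, nbins = m + 1L) / nrow(tuples)
  } else {
    # P(exactly k) = C(m,k) * sum_j (-1)^j C(m-k,j) * (n-k-j)_(m-k-j) / n_(m)
    falling <- function(a, b) if (b == 0L) 1 else prod(seq(a, a - b + 1L))
    p <- vapply(0:m, function(k) {
      j <- 0:(m - k)
      terms <- vapply(j, function(jj) {
        (-1)^jj * choose(m - k, jj) * falling(n - k - jj, m - k - jj)
      }, numeric(1))
      choose(m, k) * sum(terms) / n_tuples
    }, numeric(1))
  }
  names(p) <- 0:m
  list(p = p, tail = rev(cumsum(rev(p))))
}

# All ordered m-tuples of distinct elements of 1..n (rows).
ordered_tuples <- function(n, m) {
  out <- matrix(seq_len(n), ncol = 1L)
  for (i in seq_len(m - 1L)) {
    rows <- lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(out[r, ], length(rest), i, byrow = TRUE), rest)
    })
    out <- do.call(rbind, rows)
  }
  out
}

#' Monte-Carlo guessing null for ordered hits
#'
#' Estimates the tail probabilities P(hits >= k) by drawing `reps` uniformly
#' random ordered reports of `list_len` distinct locations and counting
#' positional matches against a fixed target sequence.  This mirrors the
#' published scoring procedure (10^7 draws); [exact_ordered_null()] is its
#' exact counterpart.
#'
#' @param n_locations Pool size.
#' @param list_len Report length.
#' @param reps Number of Monte-Carlo draws (>= 1).
#' @param seed Seed.
#' @return Named list with `p` (estimated P(hits = k)) and `tail`
#'   (P(hits >= k), k = 0..list_len).
#' @export
mc_ordered_null <- function(n_locations = 32L, list_len = 4L, reps = 1e5,
                            seed = 1L) {
  stopifnot(reps >= 1)
  n <- as.integer(n_locations)
  m <- as.integer(list_len)
  hits <- withr::with_seed(seed, {
    # rank trick: the first m order statistics of iid uniforms index a
    # uniformly random ordered m-subset
    u <- matrix(runif(reps * n), as.integer(reps), n)
    draws <- t(apply(u, 1L, function(r) order(r)[seq_len(m)]))
    rowSums(draws == matrix(seq_len(m), as.integer(reps), m, byrow = TRUE))
  })
  p <- tabulate(hits + 1L, nbins = m + 1L) / reps
  names(p) <- 0:m
  list(p = p, tail = rev(cumsum(rev(p))))
}

#' Upper-tail hypergeometric score for unordered reports
#'
#' For reports where order does not matter (random-sequence and rare-location
#' reports), the number of reported locations overlapping the true set is
#' scored by the probability of at least that much overlap under guessing:
#' `P(X >= k)` with `X ~ Hypergeometric(pool, truth_size, report_size)`.
#'
#' @param report_size Number of locations marked (m).
#' @param hits Observed overlap k (0 <= k <= min(m, truth_size)).
#' @param pool Total number of locations (default 32).
#' @param truth_size Size of the true set (default 4).
#' @return Upper-tail probability.
#' @export
unordered_score <- function(report_size, hits, pool = 32L, truth_size = 4L) {
  if (hits > min(report_size, truth_size) || hits < 0 ||
      report_size > pool || truth_size > pool) {
    stop("inconsistent counts for hypergeometric score")
  }
  phyper(hits - 1L, truth_size, pool - truth_size, report_size,
         lower.tail = FALSE)
}

#' Score one participant's verbal report against the guessing null
#'
#' Each of the two ordered fixed-sequence reports is scored by the tail
#' probability of its ordered-hit count under the guessing null and the two
#' probabilities are averaged (`p_fixed`).  A participant is classified as
#' holding explicit knowledge -- and excluded from implicit-learning
#' analyses -- when `p_fixed < threshold` (default 5%).  Unordered reports
#' of the random-set and rarely-used locations are scored by the
#' hypergeometric tail; the rare-location score is reported but never used
#' for exclusion.  A missing report is flagged, not excluded.
#'
#' @param report List with `fixed_reports` (list of two ordered location
#'   vectors, or `NULL` if lost), and optionally `random_report` and
#'   `rare_report` (unordered location vectors).
#' @param truths List with `fixed1`, `fixed2` (ordered true sequences),
#'   optionally `random_set` (true random-set locations, both sets combined
#'   or one set) and `rare_set`.
#' @param pool Total number of locations.
#' @param threshold Exclusion threshold on `p_fixed`.
#' @param null Guessing null to score against: `"exact"` (default) or a
#'   precomputed tail vector like `exact_ordered_null()$tail`.
#' @return Tibble with `p_fixed`, `p_random`, `p_rare`, `excluded`,
#'   `missing`.
#' @export
score_participant <- function(report, truths, pool = 32L, threshold = 0.05,
                              null = "exact") {
  list_len <- length(truths$fixed1)
  tail <- if (identical(null, "exact")) {
    exact_ordered_null(pool, list_len)$tail
  } else {
    null
  }
  missing <- is.null(report$fixed_reports)
  p_fixed <- NA_real_
  if (!missing) {
    hits <- c(count_ordered_hits(report$fixed_reports[[1L]], truths$fixed1),
              count_ordered_hits(report$fixed_reports[[2L]], truths$fixed2))
    p_fixed <- mean(tail[hits + 1L])
  }
  score_unordered <- function(rep_set, truth_set) {
    if (is.null(rep_set) || is.null(truth_set)) return(NA_real_)
    unordered_score(length(rep_set), length(intersect(rep_set, truth_set)),
                    pool = pool, truth_size = length(truth_set))
  }
  tibble::tibble(
    p_fixed = p_fixed,
    p_random = score_unordered(report$random_report, truths$random_set),
    p_rare = score_unordered(report$rare_report, truths$rare_set),
    excluded = !missing && !is.na(p_fixed) && p_fixed < threshold,
    missing = missing
  )
}
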