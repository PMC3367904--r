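#' Empirical CDF percentile points
#'
#' Estimates RT quantiles by linear interpolation of the order statistics at
#' plotting positions `(i - 0.5) / n`, clamped to the sample minimum and
#' maximum outside that range (the standard procedure for race-model-
#' inequality CDF estimation).  The default grid of ten levels
#' 0.05, 0.15, ..., 0.95 yields the ten percentile points per condition used
#' by the race model test.
#'
#' @param rts Numeric RT sample (non-empty).
#' @param levels Probability levels.
#' @return Numeric vector of RT values at `levels` (non-decreasing).
#' @export
percentile_points <- function(rts, levels = rmi_levels()) {
  rts <- rts[!is.na(rts)]
  if (length(rts) == 0L) stop("percentile_points() needs a non-empty sample")
  weighted_quantile(rts, rep(1 / length(rts), length(rts)), levels)
}

#' The default percentile grid
#' @return `seq(0.05, 0.95, by = 0.1)`.
#' @export
rmi_levels <- function() seq(0.05, 0.95, by = 0.1)

# Quantiles of a weighted sample: sorted values at cumulative midpoint
# positions cum(w) - w/2, linearly interpolated and clamped at the extremes.
# Equal weights reduce to plotting positions (i - 0.5)/n.
weighted_quantile <- function(x, w, levels) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  pp <- cumsum(w) - w / 2
  if (length(x) == 1L) return(rep(x, length(levels)))
  approx(pp, x, xout = levels, rule = 2, ties = "ordered")$y
}

#' Percentile points of the summed CDF of two conditions
#'
#' The race model inequality bounds the combined-condition CDF by the *sum*
#' of the two single-source CDFs, `F_order + F_ordinal`.  Each empirical CDF
#' is interpolated linearly through its order statistics at plotting
#' positions `(i - 0.5) / n` (0 below the sample minimum, 1 above the
#' maximum), the two are summed, and the sum is inverted at the requested
#' levels.  This equals the quantile, at level `p / 2`, of the equal-weight
#' mixture `(F_order + F_ordinal) / 2`, each condition contributing weight
#' 1/2 regardless of sample size; levels below the reachable range clamp to
#' the pooled minimum.
#'
#' @param order_rts,ordinal_rts RT samples of the two single-source
#'   conditions (non-empty).
#' @param levels Probability levels.
#' @return RT values of the summed CDF at `levels`.
#' @export
sum_cdf_percentiles <- function(order_rts, ordinal_rts, levels = rmi_levels()) {
  order_rts <- order_rts[!is.na(order_rts)]
  ordinal_rts <- ordinal_rts[!is.na(ordinal_rts)]
  if (length(order_rts) == 0L || length(ordinal_rts) == 0L) {
    stop("sum_cdf_percentiles() needs two non-empty samples")
  }
  knots <- sort(unique(c(order_rts, ordinal_rts)))
  s <- ecdf_at(order_rts, knots) + ecdf_at(ordinal_rts, knots)
  keep <- !duplicated(s) # flat stretches occur only at the extremes
  s <- s[keep]
  knots <- knots[keep]
  if (length(knots) == 1L) return(rep(knots, length(levels)))
  approx(s, knots, xout = levels, rule = 2, ties = "ordered")$y
}

# Interpolated empirical CDF (plotting positions (i - 0.5)/n) evaluated at t;
# 0 below the sample minimum, 1 above its maximum.
ecdf_at <- function(x, t) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(ifelse(t < x, 0, ifelse(t > x, 1, 0.5)))
  pp <- (seq_len(n) - 0.5) / n
  f <- approx(x, pp, xout = t, rule = 1, ties = max)$y
  f[t < x[1L]] <- 0
  f[t > x[n]] <- 1
  f
}

#' Per-participant CDF percentile points for the race model test
#'
#' Pools each participant's RTs across sessions (one CDF per condition) and
#' returns the percentile points for the fixed-sequence, ordinal-only and
#' order-only conditions plus the summed single-source CDF
#' `order + ordinal`.
#'
#' @param data Trial table with `rt_ms` filled; apply [exclude_trials()]
#'   first.
#' @param levels Probability levels.
#' @return Tibble with columns `participant`, `condition` (`fixed`, `ordinal`,
#'   `order`, `order_plus_ordinal`), `level`, `rt_ms`.
#' @export
rmi_percentiles <- function(data, levels = rmi_levels()) {
  if (!"cell" %in% names(data)) {
    if ("condition" %in% names(data) &&
        all(data$condition %in% c("fixed", "ordinal", "order"))) {
      data$cell <- data$condition # already condition-level samples
    } else {
      data$cell <- analysis_cell(data$condition, data$tag)
    }
  }
  per_part <- split(data, data$participant)
  rows <- lapply(per_part, function(d) {
    fixed <- d$rt_ms[d$cell == "fixed"]
    ordinal <- d$rt_ms[d$cell %in% c("ordinal_test", "ordinal")]
    ord <- d$rt_ms[d$cell %in% c("order_test", "order")]
    if (length(fixed) == 0L || length(ordinal) == 0L || length(ord) == 0L) {
      stop("participant ", d$participant[1L], " lacks RTs in a test condition")
    }
    tibble::tibble(
      participant = d$participant[1L],
      condition = rep(c("fixed", "ordinal", "order", "order_plus_ordinal"),
                      each = length(levels)),
      level = rep(levels, 4L),
      rt_ms = c(percentile_points(fixed, levels),
                percentile_points(ordinal, levels),
                percentile_points(ord, levels),
                sum_cdf_percentiles(ord, ordinal, levels))
    )
  })
  dplyr::bind_rows(rows)
}

#' Race model inequality test with restricted-range correction
#'
#' At each percentile level the mean fixed-sequence percentile point is
#' compared with the mean summed-CDF (`order + ordinal`) point by a paired
#' one-tailed t-test of `fixed < sum`; significantly faster fixed-sequence
#' RTs violate the race model inequality and indicate coactivation of the
#' two knowledge sources.  Because violations can only occur in the fastest
#' percentiles, p-values are Bonferroni-adjusted for the restricted range
#' only (default levels 0.05 and 0.15, i.e. the 5-20% range, factor 2), and
#' the violation decision considers only those levels.
#'
#' @param pcts Percentile table from [rmi_percentiles()] (conditions `fixed`
#'   and `order_plus_ordinal` required).
#' @param restricted_levels Levels entering the decision.
#' @param alpha Significance level.
#' @return An object of class `rmi_result`: list with `table` (per level:
#'   mean RTs, t, df, p, adjusted p, restricted flag), `violation`, `alpha`,
#'   `restricted_levels`.
#' @export
rmi_test <- function(pcts, restricted_levels = c(0.05, 0.15), alpha = 0.05) {
  fixed <- pcts[pcts$condition == "fixed", ]
  sums <- pcts[pcts$condition == "order_plus_ordinal", ]
  participants <- sort(unique(pcts$participant))
  if (length(participants) < 3L) {
    stop("rmi_test() needs at least 3 participants")
  }
  levels <- sort(unique(fixed$level))
  near <- function(a, b) any(abs(a - b) < 1e-8) # tolerant level matching
  n_restricted <- sum(vapply(restricted_levels, near, logical(1), b = levels))
  if (n_restricted == 0L) stop("no restricted levels present in the data")
  rows <- lapply(levels, function(l) {
    f <- fixed$rt_ms[fixed$level == l][match(participants,
                                             fixed$participant[fixed$level == l])]
    s <- sums$rt_ms[sums$level == l][match(participants,
                                           sums$participant[sums$level == l])]
    d <- f - s
    if (sd(d) == 0) {
      # degenerate case: constant difference decides the tail directly
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pval <- if (mean(d) < 0) 0 else 1
      return(tibble::tibble(level = l, mean_fixed = mean(f), mean_sum = mean(s),
                            t = tstat, df = length(d) - 1L, p = pval))
    }
    tt <- t.test(f, s, paired = TRUE, alternative = "less")
    tibble::tibble(level = l, mean_fixed = mean(f), mean_sum = mean(s),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  tab <- dplyr::bind_rows(rows)
  tab$restricted <- vapply(tab$level, near, logical(1), b = restricted_levels)
  tab$p_adj <- ifelse(tab$restricted, pmin(tab$p * n_restricted, 1), NA_real_)
  structure(
    list(table = tab,
         violation = any(tab$restricted & tab$p_adj < alpha),
         alpha = alpha, restricted_levels = restricted_levels,
         n_participants = length(participants)),
    class = "rmi_result"
  )
}

#' @export
print.rmi_result <- function(x, ...) {
  cat("Race model inequality test (", x$n_participants, " participants)\n",
      sep = "")
  cat("Restricted range:", paste(x$restricted_levels, collapse = ", "),
      "  alpha =", x$alpha, "\n")
  print(as.data.frame(x$table), digits = 4)
  cat(if (x$violation) "=> violation: evidence for coactivation\n"
      else "=> no violation: independent race not rejected\n")
  invisible(x)
}
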