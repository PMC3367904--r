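#' Two-way repeated-measures ANOVA
#'
#' Classical within-subjects sums-of-squares decomposition for a complete,
#' balanced subject x A x B design with one observation per cell.  Each
#' effect is tested against its own subject-interaction error term
#' (A against A x Subject, B against B x Subject, A x B against
#' A x B x Subject).  No sphericity correction is applied, so the degrees of
#' freedom are the uncorrected ones (e.g. 45 blocks x 21 subjects gives
#' F(44, 880) for the block effect).
#'
#' @param data Data frame of cell values.
#' @param dv,subject,a,b Column names of the dependent variable, subject
#'   identifier and the two within-subject factors.
#' @return Tibble with one row per effect (`a`, `b`, `a:b`): `df1`, `df2`,
#'   `ss`, `ms`, `ss_error`, `F`, `p`.
#' @export
rm_anova_2way <- function(data, dv = "value_ms", subject = "participant",
                          a = "session", b = "condition") {
  y <- data[[dv]]
  s <- factor(data[[subject]])
  fa <- factor(data[[a]])
  fb <- factor(data[[b]])
  if (anyNA(y)) stop("missing cells in repeated-measures ANOVA")
  n <- nlevels(s); p <- nlevels(fa); q <- nlevels(fb)
  if (length(y) != n * p * q || anyDuplicated(paste(s, fa, fb))) {
    stop("design must be complete and balanced with one observation per cell")
  }
  if (p < 2L || q < 2L) stop("both factors need at least 2 levels")

  grand <- mean(y)
  m_s <- tapply(y, s, mean)
  m_a <- tapply(y, fa, mean)
  m_b <- tapply(y, fb, mean)
  m_sa <- tapply(y, list(s, fa), mean)
  m_sb <- tapply(y, list(s, fb), mean)
  m_ab <- tapply(y, list(fa, fb), mean)

  ss_s <- p * q * sum((m_s - grand)^2)
  ss_a <- n * q * sum((m_a - grand)^2)
  ss_b <- n * p * sum((m_b - grand)^2)
  ss_sa <- q * sum((m_sa - outer(m_s, rep(1, p)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- p * sum((m_sb - outer(m_s, rep(1, q)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, q)) -
                      outer(rep(1, p), m_b) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_sa - ss_sb - ss_ab

  eff <- tibble::tibble(
    effect = c(a, b, paste0(a, ":", b)),
    df1 = c(p - 1L, q - 1L, (p - 1L) * (q - 1L)),
    df2 = c((p - 1L) * (n - 1L), (q - 1L) * (n - 1L),
            (p - 1L) * (q - 1L) * (n - 1L)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_sa, ss_sb, ss_sab)
  )
  eff$ms <- eff$ss / eff$df1
  eff$F <- ifelse(eff$ss == 0 & eff$ss_error == 0, 0, # degenerate 0/0 case
                  eff$ms / (eff$ss_error / eff$df2))
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff
}

#' Within-subject standard error from the interaction mean square
#'
#' Error bars appropriate for within-subject designs: the condition means
#' share a single standard error `sqrt(MS_{subject x condition} / n)`,
#' derived from the subject-by-condition interaction mean square after
#' removing subject and condition main effects (Loftus/Masson-style).
#'
#' @param data Data frame with one observation per subject x condition.
#' @param dv,subject,condition Column names.
#' @return List with `means` (named condition means), `se` (shared standard
#'   error), `ms_interaction`, `df`.
#' @export
within_subject_se <- function(data, dv = "value_ms", subject = "participant",
                              condition = "condition") {
  y <- data[[dv]]
  s <- factor(data[[subject]])
  cc <- factor(data[[condition]])
  n <- nlevels(s); k <- nlevels(cc)
  if (length(y) != n * k || anyDuplicated(paste(s, cc))) {
    stop("within_subject_se() needs one observation per subject x condition")
  }
  grand <- mean(y)
  m_s <- tapply(y, s, mean)
  m_c <- tapply(y, cc, mean)
  resid <- y - m_s[s] - m_c[cc] + grand
  df <- (n - 1L) * (k - 1L)
  ms_int <- sum(resid^2) / df
  list(means = m_c, se = sqrt(ms_int / n), ms_interaction = ms_int, df = df)
}

#' Linear regression of a difference score on session
#'
#' Ordinary least squares of the per-participant, per-transfer-block
#' difference score on the session index, over all participant x block
#' observations (21 participants x 9 transfer blocks = 189 observations give
#' t with 187 df).  The slope is reported standardized (both variables
#' z-scored).
#'
#' @param scores Data frame of difference scores.
#' @param dv,session Column names of score and session index.
#' @return List with `beta` (standardized slope), `t`, `df`, `p` (two-sided),
#'   `r_squared`, `n`.
#' @export
linreg_session <- function(scores, dv = "value_ms", session = "session") {
  y <- scores[[dv]]
  x <- scores[[session]]
  keep <- complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  if (length(unique(x)) < 2L) stop("session predictor is constant")
  fit <- lm(scale(y) ~ scale(x))
  sm <- summary(fit)
  list(beta = unname(coef(fit)[2L]),
       t = unname(sm$coefficients[2L, "t value"]),
       df = fit$df.residual,
       p = unname(sm$coefficients[2L, "Pr(>|t|)"]),
       r_squared = sm$r.squared,
       n = length(y))
}

#' Paired t-test
#'
#' Thin wrapper over the standard paired t-test with a choice of tail.
#'
#' @param x,y Paired samples of equal length (>= 2).
#' @param tail `"two.sided"`, `"less"` (x < y) or `"greater"`.
#' @return List with `t`, `df`, `p`, `mean_diff` (mean of x - y).
#' @export
paired_t <- function(x, y, tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("paired_t() needs two equal-length samples of size >= 2")
  }
  if (var(x - y) == 0) stop("zero variance of paired differences")
  tt <- t.test(x, y, paired = TRUE, alternative = tail)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(x - y))
}

#' Pearson or Spearman correlation with t-approximation p-value
#'
#' Computes the product-moment or rank correlation and its two-sided p-value
#' through the t transformation `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` df (for Pearson this is exact and identical to
#' `stats::cor.test()`; for Spearman it is the usual large-sample
#' approximation).
#'
#' @param x,y Samples of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `t`, `df`, `p`.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("correlations() needs two equal-length samples of size >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  r <- cor(x, y, method = method)
  n <- length(x)
  df <- n - 2L
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  }
  list(r = r, t = t, df = df, p = p)
}
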