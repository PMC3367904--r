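# Random but reproducible balanced within-subject data.
rm_fixture <- function(n = 6L, p = 3L, q = 2L, seed = 13L) {
  withr::with_seed(seed, {
    d <- expand.grid(participant = seq_len(n), session = seq_len(p),
                     condition = letters[seq_len(q)])
    d$value_ms <- 700 + 30 * d$session + 20 * (d$condition == "a") +
      rnorm(nrow(d), 0, 25) + rep(rnorm(n, 0, 40), times = p * q)
    d
  })
}

test_that("repeated-measures ANOVA matches the aov() Error-strata oracle", {
  d <- rm_fixture()
  res <- rm_anova_2way(d, dv = "value_ms", a = "session", b = "condition")
  oracle <- summary(stats::aov(
    value_ms ~ factor(session) * factor(condition) +
      Error(factor(participant) / (factor(session) * factor(condition))),
    data = d
  ))
  get <- function(stratum, row) {
    tab <- oracle[[stratum]][[1L]]
    c(F = tab[row, "F value"], p = tab[row, "Pr(>F)"],
      df1 = tab[row, "Df"], df2 = tab[nrow(tab), "Df"])
  }
  o_a <- get("Error: factor(participant):factor(session)", 1L)
  o_b <- get("Error: factor(participant):factor(condition)", 1L)
  o_ab <- get("Error: factor(participant):factor(session):factor(condition)", 1L)
  expect_equal(res$F, unname(c(o_a["F"], o_b["F"], o_ab["F"])), tolerance = 1e-10)
  expect_equal(res$p, unname(c(o_a["p"], o_b["p"], o_ab["p"])), tolerance = 1e-10)
  expect_equal(res$df1, unname(c(o_a["df1"], o_b["df1"], o_ab["df1"])))
  expect_equal(res$df2, unname(c(o_a["df2"], o_b["df2"], o_ab["df2"])))
})

test_that("ANOVA degrees of freedom reproduce the target design sizes", {
  # 45 training blocks x 2 sequence types x 21 participants
  d <- withr::with_seed(3, expand.grid(participant = 1:21, session = 1:45,
                                       condition = c("fixed", "random")))
  d$value_ms <- withr::with_seed(4, rnorm(nrow(d), 800, 50))
  res <- rm_anova_2way(d)
  expect_equal(res$df1, c(44L, 1L, 44L))
  expect_equal(res$df2, c(880L, 20L, 880L))
})

test_that("constant data yield F = 0 and missing cells error", {
  d <- rm_fixture()
  d$value_ms <- 500
  expect_equal(rm_anova_2way(d)$F, c(0, 0, 0))
  expect_error(rm_anova_2way(rm_fixture()[-1L, ]), "balanced")
})

test_that("a 2-level factor satisfies F = t^2 of the paired t-test", {
  d <- rm_fixture(n = 9L, p = 2L, q = 2L, seed = 5L)
  res <- rm_anova_2way(d, a = "session", b = "condition")
  # collapse over condition, pair sessions
  m <- tapply(d$value_ms, list(d$participant, d$session), mean)
  tt <- paired_t(m[, 1L], m[, 2L])
  expect_equal(res$F[1L], tt$t^2, tolerance = 1e-10)
  expect_equal(res$df2[1L], tt$df)
})

test_that("paired t matches the textbook formula on a 5-pair fixture", {
  x <- c(512, 480, 530, 476, 492)
  y <- c(470, 485, 463, 441, 460)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- paired_t(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE))
  one <- paired_t(y, x, tail = "less")
  expect_equal(one$p, pt(-t_hand, 4))
  expect_error(paired_t(x, x), "variance")
  # near-null data give a small t
  noise <- withr::with_seed(6, x + rnorm(5, 0, 1))
  expect_lt(abs(paired_t(x, noise)$t), 3)
})

test_that("correlations use the t approximation with n - 2 df", {
  withr::with_seed(11, {
    x <- rnorm(21)
    y <- 0.6 * x + rnorm(21, 0, 0.8)
  })
  res <- correlations(x, y)
  oracle <- stats::cor.test(x, y)
  expect_equal(res$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$df, 19L) # 21 pairs

  expect_equal(correlations(x, x)$r, 1)
  expect_equal(correlations(x, -x)$r, -1)
  expect_equal(correlations(x, -x)$p, 0)

  rs <- correlations(x, y, method = "spearman")
  r_hand <- cor(rank(x), rank(y))
  expect_equal(rs$r, r_hand, tolerance = 1e-12)
  expect_equal(rs$t, r_hand * sqrt(19 / (1 - r_hand^2)), tolerance = 1e-12)
  expect_error(correlations(x, rep(1, 21)), "variance")
})

test_that("regression of score on session reports standardized slope and df", {
  # perfectly linear scores
  d <- data.frame(session = rep(1:3, each = 4), value_ms = rep(1:3, each = 4) * 10)
  res <- suppressWarnings(linreg_session(d)) # perfect fit warns in summary.lm
  expect_equal(res$r_squared, 1)
  expect_equal(res$beta, 1)
  # 21 participants x 9 transfer blocks = 189 observations -> 187 df
  d2 <- withr::with_seed(8, data.frame(session = rep(rep(1:3, each = 3), 21),
                                       value_ms = rnorm(189)))
  res2 <- linreg_session(d2)
  expect_equal(res2$df, 187)
  expect_equal(res2$n, 189)
  # r^2 equals the squared correlation for a single predictor
  expect_equal(res2$r_squared, correlations(d2$session, d2$value_ms)$r^2,
               tolerance = 1e-12)
  expect_error(linreg_session(data.frame(session = rep(1, 5), value_ms = 1:5)),
               "constant")
})

test_that("null regression slopes are centered on zero", {
  slopes <- withr::with_seed(15, vapply(1:200, function(i) {
    d <- data.frame(session = rep(1:3, each = 21), value_ms = rnorm(63))
    linreg_session(d)$beta
  }, numeric(1)))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)) + 0.02)
})

test_that("within-subject SE derives from the interaction mean square", {
  d <- rm_fixture(n = 5L, p = 1L, q = 3L, seed = 9L)
  d$session <- NULL
  res <- within_subject_se(d, condition = "condition")
  # brute-force double-centered residuals
  y <- d$value_ms
  s <- factor(d$participant); cc <- factor(d$condition)
  resid <- y - tapply(y, s, mean)[s] - tapply(y, cc, mean)[cc] + mean(y)
  ms_hand <- sum(resid^2) / ((5 - 1) * (3 - 1))
  expect_equal(res$ms_interaction, ms_hand, tolerance = 1e-12)
  expect_equal(res$se, sqrt(ms_hand / 5), tolerance = 1e-12)

  # purely additive data have zero interaction SE
  add <- expand.grid(participant = 1:4, condition = c("a", "b"))
  add$value_ms <- as.integer(add$participant) * 10 + (add$condition == "a") * 5
  expect_equal(within_subject_se(add)$se, 0)

  # scaling the data scales the SE linearly
  d2 <- d; d2$value_ms <- d$value_ms * 3
  expect_equal(within_subject_se(d2, condition = "condition")$se,
               res$se * 3, tolerance = 1e-12)
})
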