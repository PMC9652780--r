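test_that("rm_anova reproduces F = t^2 on a two-level within design", {
  set.seed(14)
  n <- 12
  d <- data.frame(subject = rep(sprintf("S%02d", 1:n), 2),
                  cond = rep(c("a", "b"), each = n),
                  y = c(rnorm(n, 0), rnorm(n, 0.5)))
  res <- rm_anova(d, dv = "y", within = "cond")
  tt <- t.test(d$y[d$cond == "a"], d$y[d$cond == "b"], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p, tt$p.value, tolerance = 1e-8)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, n - 1)
})

test_that("rm_anova gives F = 0 when the level means are identical", {
  set.seed(13)
  d <- expand.grid(subject = sprintf("S%d", 1:6), cond = c("a", "b"))
  d$y <- rnorm(12)
  for (lv in c("a", "b"))   # remove the condition effect exactly
    d$y[d$cond == lv] <- d$y[d$cond == lv] - mean(d$y[d$cond == lv])
  res <- rm_anova(d, dv = "y", within = "cond")
  expect_equal(res$F, 0, tolerance = 1e-12)
})

test_that("rm_anova matches a brute-force cell-means SS computation", {
  # independent two-factor within-subject SS partition written from the
  # textbook cell-means formulas
  brute_rm <- function(d) {
    gm <- mean(d$y)
    A <- tapply(d$y, d$A, mean); B <- tapply(d$y, d$B, mean)
    S <- tapply(d$y, d$subject, mean)
    AB <- tapply(d$y, list(d$A, d$B), mean)
    AS <- tapply(d$y, list(d$A, d$subject), mean)
    BS <- tapply(d$y, list(d$B, d$subject), mean)
    a <- length(A); b <- length(B); s <- length(S)
    ssA <- b * s * sum((A - gm)^2)
    ssB <- a * s * sum((B - gm)^2)
    ssAB <- s * sum(sweep(sweep(AB, 1, A), 2, B) + gm)^0  # placeholder
    ssAB <- s * sum((AB - outer(A, rep(gm, b), "+") / 1 -
                       outer(rep(gm, a), B, "+") / 1 + 2 * gm + gm - gm)^2)
    ssAB <- s * sum((sweep(sweep(AB, 1, A, "-"), 2, B, "-") + gm)^2)
    ssAS <- b * sum((sweep(AS, 2, S, "-") - matrix(A - gm, a, s))^2)
    ssBS <- a * sum((sweep(BS, 2, S, "-") - matrix(B - gm, b, s))^2)
    cellASB <- tapply(d$y, list(d$A, d$B, d$subject), mean)
    resid <- cellASB
    for (i in 1:a) for (j in 1:b) for (k in 1:s)
      resid[i, j, k] <- cellASB[i, j, k] - AB[i, j] - AS[i, k] - BS[j, k] +
        A[i] + B[j] + S[k] - gm
    ssABS <- sum(resid^2)
    list(FA = (ssA / (a - 1)) / (ssAS / ((a - 1) * (s - 1))),
         FB = (ssB / (b - 1)) / (ssBS / ((b - 1) * (s - 1))),
         FAB = (ssAB / ((a - 1) * (b - 1))) / (ssABS / ((a - 1) * (b - 1) * (s - 1))))
  }
  set.seed(15)
  for (rep in 1:3) {
    d <- expand.grid(subject = sprintf("S%d", 1:4), A = c("a1", "a2"),
                     B = c("b1", "b2"))
    d$y <- rnorm(nrow(d))
    res <- rm_anova(d, dv = "y", within = c("A", "B"))
    bf <- brute_rm(d)
    expect_equal(res$F[res$effect == "A"], bf$FA, tolerance = 1e-8)
    expect_equal(res$F[res$effect == "B"], bf$FB, tolerance = 1e-8)
    expect_equal(res$F[res$effect == "A:B"], bf$FAB, tolerance = 1e-8)
  }
})

test_that("rm_anova rejects unbalanced or incomplete designs", {
  d <- expand.grid(subject = sprintf("S%d", 1:4), cond = c("a", "b"))
  d$y <- rnorm(8)
  expect_error(rm_anova(d[-1, ], dv = "y", within = "cond"), "balanced")
  d2 <- rbind(d, d[1, ])
  expect_error(rm_anova(d2, dv = "y", within = "cond"), "balanced")
})

test_that("Greenhouse-Geisser epsilon is 1 for two levels and <= 1 generally", {
  set.seed(16)
  d <- expand.grid(subject = sprintf("S%d", 1:8), cond = c("a", "b", "c"))
  d$y <- rnorm(nrow(d))
  res <- rm_anova(d, dv = "y", within = "cond", gg = TRUE)
  expect_lte(res$gg_eps, 1 + 1e-9)
  expect_gte(res$gg_eps, 1 / (3 - 1))
  d2 <- d[d$cond != "c", ]
  res2 <- rm_anova(droplevels(d2), dv = "y", within = "cond", gg = TRUE)
  expect_equal(res2$gg_eps, 1, tolerance = 1e-9)
})

test_that("paired_t handles ordinary and degenerate inputs", {
  a <- c(1, 2, 3, 4)
  res <- paired_t(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)

  res2 <- paired_t(a + 1, a)
  expect_true(res2$degenerate)
  expect_identical(res2$t, Inf)

  set.seed(17)
  x <- rnorm(10); y <- rnorm(10)
  res3 <- paired_t(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(res3$t, unname(tt$statistic))
  expect_equal(res3$p, tt$p.value)
})

test_that("null p-values are approximately uniform (small calibration)", {
  set.seed(18)
  p <- replicate(300, {
    d <- expand.grid(subject = sprintf("S%d", 1:8), cond = c("a", "b", "c"))
    d$y <- rnorm(nrow(d))
    rm_anova(d, dv = "y", within = "cond")$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
})

test_that("run_study reproduces null generators as null effects", {
  # no bilateral component and flat CDA amplitudes: both effects absent
  cfg <- gen_config(seed = 41, n_subjects = 6, trials_per_cell = 20,
                    capacity_sd = 0.2,
                    eeg = list(bilateral_effect_amp = 0,
                               cda_amp_by_load = c(`1` = -1, `3` = -1, `5` = -1),
                               noise_sd = 2, saccade_rate = 0, blink_rate = 0))
  st <- run_study(cfg, min_trials = 10, fit_models = FALSE)
  expect_gt(st$erp$cda_anova$p[st$erp$cda_anova$effect == "load"], 0.05)
  expect_gt(st$erp$contra_anova$p[st$erp$contra_anova$effect == "condition"], 0.05)
  expect_false(st$pattern$bilateral_homogeneity_effect)
})
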