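toy_table <- function(values) {
  d <- expand.grid(subject_id = sprintf("s%d", 1:3),
                   posture = c("sit", "swivel", "stand"),
                   stimulus_type = c("indoor", "outdoor"),
                   stringsAsFactors = FALSE)
  d$value <- values
  d
}

test_that("trial metrics aggregate to subject-cell means", {
  m <- data.frame(subject_id = "s1", posture = "sit",
                  stimulus_type = c("indoor", "indoor"), dist = c(40, 50))
  agg <- aggregate_metrics(m, "dist")
  expect_equal(agg$value, 45)

  m2 <- rbind(m, data.frame(subject_id = "s2", posture = "sit",
                            stimulus_type = "indoor", dist = 10))
  expect_silent(aggregate_metrics(m2, "dist"))
  m3 <- data.frame(subject_id = c("s1", "s1", "s2"),
                   posture = c("sit", "stand", "sit"),
                   stimulus_type = "indoor", dist = 1:3)
  expect_error(aggregate_metrics(m3, "dist"), "missing cells")

  # brute-force group-by oracle on random data
  set.seed(6)
  big <- expand.grid(subject_id = sprintf("s%d", 1:4),
                     posture = c("sit", "stand"),
                     stimulus_type = c("indoor", "outdoor"),
                     trial = 1:5, stringsAsFactors = FALSE)
  big$m <- rnorm(nrow(big))
  agg <- aggregate_metrics(big, "m")
  for (i in seq_len(nrow(agg))) {
    sel <- big$subject_id == agg$subject_id[i] &
      big$posture == agg$posture[i] &
      big$stimulus_type == agg$stimulus_type[i]
    expect_equal(agg$value[i], mean(big$m[sel]))
  }
})

test_that("one-way repeated-measures F matches the hand SS decomposition", {
  set.seed(12)
  mat <- matrix(rnorm(15), 5, 3) + outer(rep(0, 5), c(0, 1, 3))
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:5), 3),
                  posture = rep(c("a", "b", "c"), each = 5),
                  value = as.vector(mat))
  res <- rm_anova(d, within = "posture")
  oracle <- hand_rm_anova_1w(mat)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$etaG2, oracle$etaG2, tolerance = 1e-10)
  expect_equal(res$p_uncorrected,
               pf(oracle$F, oracle$df1, oracle$df2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("two-way within ANOVA matches aov error strata", {
  set.seed(33)
  d <- toy_table(rnorm(18) + rep(c(0, 2, 4), each = 3))
  res <- rm_anova(d)
  a <- summary(stats::aov(value ~ posture * stimulus_type +
                            Error(subject_id / (posture * stimulus_type)),
                          data = transform(d, subject_id = factor(subject_id),
                                           posture = factor(posture),
                                           stimulus_type = factor(stimulus_type))))
  f_post <- a[["Error: subject_id:posture"]][[1]]["posture", "F value"]
  f_stim <- a[["Error: subject_id:stimulus_type"]][[1]]["stimulus_type", "F value"]
  expect_equal(res$F[res$effect == "posture"], f_post, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "stimulus_type"], f_stim, tolerance = 1e-8)
  expect_true(all(res$etaG2 >= 0 & res$etaG2 <= 1))
})

test_that("ANOVA is invariant to adding a constant and flags degeneracy", {
  set.seed(44)
  d <- toy_table(rnorm(18))
  r1 <- rm_anova(d)
  d2 <- d; d2$value <- d2$value + 1000
  r2 <- rm_anova(d2)
  expect_equal(r1$F, r2$F, tolerance = 1e-6)
  dc <- d; dc$value <- 5
  expect_error(rm_anova(dc), "zero variance")
})

test_that("Greenhouse-Geisser correction applies only when sphericity fails", {
  set.seed(55)
  d <- toy_table(rnorm(18))
  res <- rm_anova(d)
  uncorr <- res[!res$corrected, ]
  expect_equal(uncorr$p, uncorr$p_uncorrected)
  corr <- res[res$corrected, ]
  if (nrow(corr)) {
    expect_true(all(corr$df1 < 2 + 1e-9))   # df shrink by epsilon
    expect_true(all(corr$epsilon < 1))
  }
})

test_that("Bonferroni post-hocs multiply paired-t p-values by m", {
  set.seed(66)
  base <- rnorm(6)
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:6), 3),
                  posture = rep(c("a", "b", "c"), each = 6),
                  value = c(base, base + rnorm(6, 2), base + rnorm(6, 4)))
  res <- bonferroni_pairwise(d, "posture")
  expect_equal(nrow(res), 3L)
  tt <- t.test(d$value[d$posture == "a"], d$value[d$posture == "b"],
               paired = TRUE)
  row <- res[res$level1 == "a" & res$level2 == "b", ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p_bonferroni, min(1, tt$p.value * 3), tolerance = 1e-12)

  same <- data.frame(subject_id = rep(sprintf("s%d", 1:4), 2),
                     posture = rep(c("a", "b"), each = 4),
                     value = c(1, 2, 3, 4, 1, 2, 3, 4) + 1e-9 * c(1:4, 4:1))
  expect_equal(bonferroni_pairwise(same, "posture")$p_bonferroni, 1,
               tolerance = 0.2)
})

test_that("one-sample bias test matches hand formulas and d = t/sqrt(n)", {
  x <- c(14, 16, 18, 15, 17)
  res <- one_sample_bias_test(x)
  expect_equal(res$t, mean(x) / (sd(x) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$d, mean(x) / sd(x), tolerance = 1e-12)
  expect_equal(res$d, res$t / sqrt(res$n), tolerance = 1e-12)
  expect_equal(res$p, t.test(x)$p.value, tolerance = 1e-12)

  expect_true(one_sample_bias_test(c(1, 1, 1))$zero_variance)

  # 27 subjects with mean 15.9 and the matching SD reproduce t ~ 23.5
  z <- scale(rnorm(27))[, 1]
  x27 <- 15.9 + (15.9 / 4.53) * z
  r27 <- one_sample_bias_test(x27)
  expect_equal(r27$t, 4.53 * sqrt(27), tolerance = 1e-6)
  expect_equal(r27$t, 23.5, tolerance = 0.1)
})
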