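# Mixed between-within ANOVA: identities, reductions, and the car::Anova
# multivariate oracle on random small designs.

make_long <- function(Y, group) {
  k <- ncol(Y)
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(nrow(Y))), k),
    level = rep(paste0("L", seq_len(k)), each = nrow(Y)),
    group = rep(group, k),
    value = as.vector(Y)
  )
}

test_that("two within levels force epsilon_hf = 1 and F = paired t^2 when merged", {
  set.seed(1)
  Y <- matrix(rnorm(24), 12, 2)
  fit <- mixed_anova(make_long(Y, rep("all", 12)), "value", "subject", "level")
  expect_equal(fit$epsilon_hf, 1)
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  Fw <- fit$table$F[fit$table$effect == "within"]
  expect_equal(Fw, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(fit$table$p[fit$table$effect == "within"], tt$p.value,
               tolerance = 1e-9)
})

test_that("identical within-level copies give interaction F = 0", {
  set.seed(2)
  y <- rnorm(10)
  Y <- cbind(y, y, y)
  colnames(Y) <- NULL
  grp <- rep(c("affected", "control"), 5)
  fit <- mixed_anova(make_long(Y, grp), "value", "subject", "level", "group")
  expect_equal(fit$table$F[fit$table$effect == "group:within"], 0,
               tolerance = 1e-20)
})

test_that("F, epsilon and partial eta squared match the car multivariate oracle", {
  skip_if_not_installed("car")
  set.seed(3)
  for (case in 1:12) {
    k <- sample(2:3, 1)
    n1 <- sample(4:8, 1)
    n2 <- sample(4:8, 1)
    Y <- matrix(rnorm((n1 + n2) * k, sd = runif(1, 0.5, 2)), n1 + n2, k)
    grp <- factor(c(rep("a", n1), rep("b", n2)))
    fit <- mixed_anova(make_long(Y, as.character(grp)),
                       "value", "subject", "level", "group")

    idata <- data.frame(level = factor(paste0("L", seq_len(k))))
    mlm <- lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
    av <- car::Anova(mlm, idata = idata, idesign = ~level, type = "III")
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    uni <- s$univariate.tests

    tb <- fit$table
    expect_equal(tb$F[tb$effect == "group"], uni["grp", "F value"],
                 tolerance = 1e-8)
    expect_equal(tb$F[tb$effect == "within"], uni["level", "F value"],
                 tolerance = 1e-8)
    expect_equal(tb$F[tb$effect == "group:within"],
                 uni["grp:level", "F value"], tolerance = 1e-8)
    expect_equal(tb$ss[tb$effect == "within"], uni["level", "Sum Sq"],
                 tolerance = 1e-8)
    if (k > 2) {
      pv <- s$pval.adjustments
      expect_equal(fit$epsilon_gg, unname(pv["level", "GG eps"]),
                   tolerance = 1e-8)
      expect_equal(fit$epsilon_hf_raw, unname(pv["level", "HF eps"]),
                   tolerance = 1e-8)
    }
    # partial eta^2 from the same sums of squares
    err_w <- uni["level", "Error SS"]
    expect_equal(tb$partial_eta_sq[tb$effect == "group:within"],
                 uni["grp:level", "Sum Sq"] /
                   (uni["grp:level", "Sum Sq"] + err_w),
                 tolerance = 1e-8)
    expect_true(all(tb$partial_eta_sq >= 0 & tb$partial_eta_sq <= 1))
  }
})

test_that("t^2 = F identity holds for a two-group one-way comparison", {
  set.seed(4)
  x <- rnorm(12, 1)
  y <- rnorm(9)
  t <- two_sample_t(summary_stats(mean(x), sd(x), 12, mean(y), sd(y), 9))$t
  f <- anova(lm(c(x, y) ~ rep(c("a", "b"), c(12, 9))))$`F value`[1]
  expect_equal(t^2, f, tolerance = 1e-9)
})

test_that("subjects missing a level are dropped listwise and reported", {
  set.seed(5)
  d <- make_long(matrix(rnorm(30), 10, 3), rep(c("affected", "control"), 5))
  d$value[d$subject == "S03" & d$level == "L3"] <- NA
  fit <- mixed_anova(d, "value", "subject", "level", "group")
  expect_equal(fit$dropped_subjects, "S03")
  expect_equal(fit$n, 9)
})

test_that("pairwise follow-ups carry Bonferroni-adjusted p-values", {
  set.seed(6)
  Y <- cbind(rnorm(12, 10), rnorm(12, 6), rnorm(12, 4))
  colnames(Y) <- NULL
  fit <- mixed_anova(make_long(Y, rep(c("affected", "control"), 6)),
                     "value", "subject", "level", "group")
  pw <- fit$pairwise
  expect_true(all(pw$p_adj >= pw$p))
  expect_true(all(pw$p_adj <= 1))
  within <- pw[pw$family == "level_within_group", ]
  expect_equal(nrow(within), 6)             # 3 level pairs x 2 groups
  # strong simulated level differences are detected in both groups
  l13 <- within[within$contrast == "L1 vs L3", ]
  expect_true(all(l13$p_adj < 0.05))
})
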