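# The normality-gated statistical battery.

test_that("significance tiers use strict thresholds", {
  expect_equal(significance_tier(c(0.049, 0.01, 0.0009, 0.05, 1, 0.001)),
               c("*", "*", "***", "ns", "ns", "**"))
})

test_that("the normality gate has the right level and power", {
  set.seed(51)
  par_rate <- mean(replicate(100, {
    normality_gate(list(rnorm(50), rnorm(50))) == "parametric"
  }))
  expect_gte(par_rate, 0.90)
  nonpar_rate <- mean(replicate(100, {
    normality_gate(rexp(50)) == "nonparametric"
  }))
  expect_gte(nonpar_rate, 0.95)
  expect_equal(normality_gate(rep(1, 10)), "nonparametric")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("paired comparison matches the closed-form t and degenerates
          gracefully", {
  # textbook pair set: t = mean(d) / (sd(d)/sqrt(n))
  pre <- c(1, 3, 4, 2, 5)
  post <- c(2, 5, 4, 6, 9)
  d <- post - pre
  res <- compare_paired(pre, post, branch = "parametric")
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(-abs(mean(d) / (sd(d) / sqrt(5))), 4),
               tolerance = 1e-12)

  same <- compare_paired(pre, pre)
  expect_equal(same$p_value, 1)
  expect_equal(same$tier, "ns")
  expect_error(compare_paired(1:4, 1:5), "lengths")
})

test_that("paired t power matches the noncentral-t value", {
  n <- 10
  shift <- 1  # one sigma
  crit <- qt(0.975, n - 1)
  power_theory <- 1 - pt(crit, n - 1, ncp = shift * sqrt(n)) +
    pt(-crit, n - 1, ncp = shift * sqrt(n))
  set.seed(52)
  rej <- mean(replicate(1000, {
    d <- rnorm(n, mean = shift)
    compare_paired(rep(0, n), d, branch = "parametric")$p_value < 0.05
  }))
  expect_equal(rej, power_theory, tolerance = 0.05)
})

test_that("group comparison matches Mann-Whitney brute force", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6), branch = "nonparametric")
  expect_equal(unname(res$statistic), 0)  # U: no a_i exceeds any b_j
  # exact p by enumeration of all 20 rank splits
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- 1:6
  us <- apply(combn(6, 3), 2, function(ix) u_stat(pool[ix], pool[-ix]))
  p_exact <- min(1, 2 * min(mean(us <= 0), mean(us >= 0)))
  expect_equal(res$p_value, p_exact)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), branch = "parametric")
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p_value, 1)
})

test_that("two-way ANOVA matches the hand decomposition and reductions", {
  # 2x2 balanced, additive + interaction by construction
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  A <- rep(c("a", "b"), each = 4)
  B <- rep(c("x", "x", "y", "y"), 2)
  res <- anova2(y, A, B)
  # hand decomposition: SS_A = 32, SS_B = 8, SS_AB = 0, SS_res = 2
  gm <- mean(y)
  ss_a <- 4 * sum((tapply(y, A, mean) - gm)^2)
  ss_b <- 4 * sum((tapply(y, B, mean) - gm)^2)
  cell <- tapply(y, list(A, B), mean)
  ss_ab <- 2 * sum((sweep(sweep(cell, 1, tapply(y, A, mean) - gm),
                          2, tapply(y, B, mean) - gm) - gm)^2)
  fitted <- cell[cbind(A, B)]
  ss_res <- sum((y - fitted)^2)
  expect_equal(res$effects$statistic[1], (ss_a / 1) / (ss_res / 4))
  expect_equal(res$effects$statistic[2], (ss_b / 1) / (ss_res / 4))
  expect_equal(res$effects$statistic[3], (ss_ab / 1) / (ss_res / 4),
               tolerance = 1e-10)

  # exactly additive cell means: interaction F = 0
  y2 <- c(0, 0.1, 1, 1.1, 2, 2.1, 3, 3.1)
  res2 <- anova2(y2, A, B)
  expect_lt(abs(res2$effects$statistic[3]), 1e-10)

  # single-level B reduces to the one-way ANOVA
  set.seed(53)
  y3 <- rnorm(12)
  g3 <- rep(c("a", "b", "c"), 4)
  res3 <- anova2(y3, g3, rep("only", 12))
  oneway <- summary(aov(y3 ~ factor(g3)))[[1]]
  expect_equal(res3$effects$statistic[1], oneway[1, "F value"])
  expect_equal(res3$effects$p_value[1], oneway[1, "Pr(>F)"])
  expect_error(anova2(y3[1:4], rep("a", 4), rep("x", 4)), "single level")
})

test_that("Scheirer-Ray-Hare reduces to Kruskal-Wallis and guards
          degeneracy", {
  set.seed(54)
  y <- rnorm(30)
  g <- rep(1:3, 10)
  srh <- scheirer_ray_hare(y, g, rep(1, 30))
  kw <- kruskal.test(y, factor(g))
  expect_equal(srh$effects$statistic[1], unname(kw$statistic),
               tolerance = 1e-12)
  expect_equal(srh$effects$p_value[1], kw$p.value, tolerance = 1e-12)
  # with ties
  yt <- round(y)
  srh_t <- scheirer_ray_hare(yt, g, rep(1, 30))
  kw_t <- kruskal.test(yt, factor(g))
  expect_equal(srh_t$effects$statistic[1], unname(kw_t$statistic),
               tolerance = 1e-12)

  const <- scheirer_ray_hare(rep(1, 16), rep(c("a", "b"), 8),
                             rep(c("x", "y"), each = 8))
  expect_true(all(const$effects$statistic == 0))
  expect_true(all(const$effects$p_value == 1))
  expect_error(scheirer_ray_hare(rnorm(4), c("a", "a", "b", "b"),
                                 c("x", "y", "x", "y")), NA)
  expect_error(scheirer_ray_hare(rnorm(4), c("a", "a", "a", "b"),
                                 c("x", "y", "x", "y")), "empty cell")
})

test_that("repeated-measures decomposition isolates the phase effect", {
  set.seed(55)
  pre <- rnorm(20)
  post <- pre + 2 + rnorm(20, sd = 0.05)
  g <- rep(c("WT", "AD"), each = 10)
  res <- rm_prepost(pre, post, g, branch = "parametric")
  eff <- res$effects
  expect_equal(eff$effect, c("group", "phase", "group:phase"))
  expect_lt(eff$p_value[eff$effect == "phase"], 1e-10)
  expect_gt(eff$p_value[eff$effect == "group"], 0.05)
  expect_gt(eff$p_value[eff$effect == "group:phase"], 0.05)
  # cross-check the phase F against the anova2 decomposition identity:
  # with a 2-level within factor, F(phase) equals the one-sample t^2 on
  # the pooled difference scores when groups are balanced
  d <- post - pre
  tt <- t.test(d)
  expect_equal(eff$statistic[eff$effect == "phase"],
               unname(tt$statistic)^2, tolerance = 0.15)

  expect_error(rm_prepost(pre[1:10], post[1:10], rep("WT", 10)),
               "two groups")

  # nonparametric branch structure
  resn <- rm_prepost(pre, post, g, branch = "nonparametric")
  expect_s3_class(resn, "rm_result")
  expect_equal(nrow(resn$within), 2)
  expect_equal(resn$between$test_name, "mann_whitney_u")
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(56)
  n <- 30
  x <- rnorm(n); z <- rnorm(n); y <- 0.5 * x + 0.3 * z + rnorm(n)
  pc <- partial_corr(x, y, z)
  oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
  expect_equal(pc$r, oracle, tolerance = 1e-10)
  expect_equal(pc$df, n - 3)
  # oracle p from the t transform of the residual correlation
  tstat <- oracle * sqrt((n - 3) / (1 - oracle^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tstat), n - 3), tolerance = 1e-10)

  # z orthogonal to x and y: partial equals the plain correlation
  zo <- resid(lm(rnorm(n) ~ x + y))
  expect_equal(partial_corr(x, y, zo)$r, cor(x, y), tolerance = 1e-10)
  # x = y gives r = 1
  expect_equal(partial_corr(x, x, z)$r, 1)
  expect_error(partial_corr(x, y, rep(1, n)), "constant")
  expect_error(partial_corr(x, y, 2 * x + 0), "collinear")
})
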