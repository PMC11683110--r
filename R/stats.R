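# Normality-gated statistical battery.
#
# Every comparison first tests normality (Shapiro-Wilk, alpha 0.05) and then
# branches: paired t vs Wilcoxon signed-rank, Welch t vs Mann-Whitney U,
# two-way ANOVA vs Scheirer-Ray-Hare, mixed (repeated-measures) ANOVA vs a
# within/between nonparametric decomposition. Significance tiers follow the
# strict 0.05 / 0.01 / 0.001 convention. Partial correlation removes a
# locomotion covariate from both variables.

#' Significance tier of a p value
#'
#' Strict inequalities: `* p < 0.05`, `** p < 0.01`, `*** p < 0.001`,
#' otherwise `ns`.
#'
#' @param p p value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  vapply(p, function(pi) {
    if (is.na(pi)) return("ns")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

# Shapiro-Wilk p value; degenerate (constant / too short) samples return 0
# so they route to the nonparametric branch rather than aborting a pipeline
.shapiro_p <- function(x) {
  if (length(unique(x)) < 3 || stats::sd(x) == 0) return(0)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Choose the parametric or nonparametric branch
#'
#' The branch is parametric iff every supplied sample passes Shapiro-Wilk
#' normality at `alpha`. Constant (degenerate) samples count as
#' non-normal.
#'
#' @param groups A numeric vector or list of numeric vectors.
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  if (!is.list(groups)) groups <- list(groups)
  ns <- lengths(groups)
  if (any(ns < 3)) stop("normality gate needs n >= 3 in every group")
  ps <- vapply(groups, .shapiro_p, numeric(1))
  if (all(ps >= alpha)) "parametric" else "nonparametric"
}

.test_result <- function(test_name, statistic, p_value, n, branch) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = p_value, n = n, branch = branch,
                 tier = significance_tier(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g [%s], n = %s\n",
              x$test_name, x$branch, x$statistic, x$p_value, x$tier,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Compare paired pre/post samples
#'
#' The normality gate is applied to the difference vector; the parametric
#' branch is the paired t test, the nonparametric branch the Wilcoxon
#' signed-rank test (zero differences dropped, ties mid-ranked). A
#' constant all-zero difference vector short-circuits to `ns` with p = 1.
#'
#' @param pre,post Equal-length numeric vectors (n >= 3).
#' @param branch `"auto"` (gate), `"parametric"` or `"nonparametric"`.
#' @param alpha Gate level.
#' @return A `test_result`.
#' @export
compare_paired <- function(pre, post, branch = c("auto", "parametric",
                                                 "nonparametric"),
                           alpha = 0.05) {
  branch <- match.arg(branch)
  if (length(pre) != length(post)) stop("pre and post lengths differ")
  if (length(pre) < 3) stop("need n >= 3 pairs")
  d <- post - pre
  if (all(d == 0))
    return(.test_result("wilcoxon_signed_rank", 0, 1, length(d),
                        "nonparametric"))
  if (branch == "auto") branch <- normality_gate(d, alpha)
  if (branch == "parametric") {
    ht <- stats::t.test(post, pre, paired = TRUE)
    .test_result("paired_t", ht$statistic, ht$p.value, length(d), branch)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
    .test_result("wilcoxon_signed_rank", ht$statistic, ht$p.value,
                 length(d), branch)
  }
}

#' Compare two independent groups
#'
#' Gate on each group separately; parametric branch is the Welch
#' (unequal-variance) t test, nonparametric the Mann-Whitney U test (exact
#' where R's implementation allows, normal approximation with tie
#' correction otherwise).
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param branch `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param alpha Gate level.
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @return A `test_result`.
#' @export
compare_groups <- function(a, b, branch = c("auto", "parametric",
                                            "nonparametric"),
                           alpha = 0.05, var_equal = FALSE) {
  branch <- match.arg(branch)
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (identical(a, b) && stats::sd(a) == 0)
    return(.test_result("mann_whitney_u", length(a) * length(b) / 2, 1,
                        c(length(a), length(b)), "nonparametric"))
  if (branch == "auto") branch <- normality_gate(list(a, b), alpha)
  if (branch == "parametric") {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    nm <- if (var_equal) "independent_t" else "welch_t"
    .test_result(nm, ht$statistic, ht$p.value, c(length(a), length(b)),
                 branch)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    .test_result("mann_whitney_u", ht$statistic, ht$p.value,
                 c(length(a), length(b)), branch)
  }
}

# residual sum of squares of a linear model
.rss <- function(formula, dat) {
  sum(stats::residuals(stats::lm(formula, data = dat))^2)
}

# Type II sums of squares for y ~ A*B on a prepared data.frame
.type2_ss <- function(dat) {
  ss_a <- .rss(y ~ B, dat) - .rss(y ~ A + B, dat)
  ss_b <- .rss(y ~ A, dat) - .rss(y ~ A + B, dat)
  full <- stats::lm(y ~ A * B, data = dat)
  rss_add <- .rss(y ~ A + B, dat)
  rss_full <- sum(stats::residuals(full)^2)
  list(ss = c(A = ss_a, B = ss_b, `A:B` = rss_add - rss_full),
       df = c(A = nlevels(dat$A) - 1, B = nlevels(dat$B) - 1,
              `A:B` = (nlevels(dat$A) - 1) * (nlevels(dat$B) - 1)),
       rss_full = rss_full, df_resid = stats::df.residual(full))
}

.two_way_frame <- function(values, factorA, factorB, factor_names) {
  dat <- data.frame(y = values, A = factor(factorA), B = factor(factorB))
  if (anyNA(dat)) stop("missing values in two-way data")
  tab <- table(dat$A, dat$B)
  if (any(tab == 0)) stop("empty cell(s) in the two-way design")
  attr(dat, "factor_names") <- factor_names
  dat
}

.two_way_result <- function(effects, method, factor_names) {
  effects$effect <- c(factor_names[1], factor_names[2],
                      paste(factor_names, collapse = ":"))[
                        seq_len(nrow(effects))]
  effects <- effects[, c("effect", "statistic", "df", "p_value")]
  effects$tier <- significance_tier(effects$p_value)
  structure(list(effects = effects, method = method), class = "two_way_result")
}

#' @export
print.two_way_result <- function(x, ...) {
  cat("Two-factor analysis (", x$method, "):\n", sep = "")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA (Type II sums of squares)
#'
#' Main and interaction F tests for two crossed factors; Type II sums of
#' squares so unbalanced group sizes are handled. With exactly one
#' observation per cell the interaction is not estimable and the additive
#' model's residual is used for the main effects (interaction reported NA).
#'
#' @param values Numeric response.
#' @param factorA,factorB Factor codings (coercible by `factor()`).
#' @param factor_names Labels used in the output (default `c("A", "B")`).
#' @return A `two_way_result` with per-effect F, df and p.
#' @export
anova2 <- function(values, factorA, factorB, factor_names = c("A", "B")) {
  dat <- .two_way_frame(values, factorA, factorB, factor_names)
  one_a <- nlevels(dat$A) < 2
  one_b <- nlevels(dat$B) < 2
  if (one_a && one_b) stop("both factors have a single level")
  if (one_a || one_b) {
    # single-level factor: reduces to one-way ANOVA on the other factor
    g <- if (one_a) dat$B else dat$A
    fit <- stats::aov(dat$y ~ g)
    tab <- summary(fit)[[1]]
    f <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]; dfe <- tab[1, "Df"]
    eff <- data.frame(statistic = c(if (one_a) NA else f,
                                    if (one_a) f else NA, NA),
                      df = c(if (one_a) NA else dfe,
                             if (one_a) dfe else NA, NA),
                      p_value = c(if (one_a) NA else p,
                                  if (one_a) p else NA, NA))
    return(.two_way_result(eff, "anova2", factor_names))
  }
  t2 <- .type2_ss(dat)
  if (t2$df_resid > 0) {
    ms_resid <- t2$rss_full / t2$df_resid
    f <- (t2$ss / t2$df) / ms_resid
    p <- stats::pf(f, t2$df, t2$df_resid, lower.tail = FALSE)
    df_out <- t2$df
  } else {
    # saturated: test main effects against the additive residual
    rss_add <- t2$rss_full + t2$ss[["A:B"]]
    df_add <- t2$df[["A:B"]]
    ms <- rss_add / df_add
    f <- c((t2$ss[1:2] / t2$df[1:2]) / ms, NA)
    p <- c(stats::pf(f[1:2], t2$df[1:2], df_add, lower.tail = FALSE), NA)
    df_out <- t2$df
  }
  .two_way_result(data.frame(statistic = unname(f), df = unname(df_out),
                             p_value = unname(p)),
                  "anova2", factor_names)
}

#' Scheirer-Ray-Hare rank two-way test
#'
#' Nonparametric analogue of the two-way ANOVA: all observations are
#' mid-ranked, Type II sums of squares are computed on the ranks, and each
#' effect's statistic `H = SS_effect / MS_total` is divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)` and referred to a chi-square
#' distribution with the effect's degrees of freedom. With a single-level
#' factor the test reduces exactly to Kruskal-Wallis on the other factor.
#'
#' @inheritParams anova2
#' @return A `two_way_result` with per-effect H, df and p.
#' @export
scheirer_ray_hare <- function(values, factorA, factorB,
                              factor_names = c("A", "B")) {
  dat <- data.frame(y = values, A = factor(factorA), B = factor(factorB))
  if (anyNA(dat)) stop("missing values in two-way data")
  if (any(table(dat$A, dat$B) == 0)) stop("empty cell(s) in the two-way design")
  n <- nrow(dat)
  r <- rank(dat$y)
  rdat <- dat; rdat$y <- r
  # MS_total of the midranks equals the no-tie value N(N+1)/12 times the
  # tie-correction divisor 1 - sum(t^3 - t)/(N^3 - N), so dividing each
  # effect's SS by it applies the tie correction
  ss_total <- sum((r - mean(r))^2)
  ms_total <- ss_total / (n - 1)
  one_a <- nlevels(dat$A) < 2
  one_b <- nlevels(dat$B) < 2
  if (one_a && one_b) stop("both factors have a single level")
  if (one_a || one_b) {
    # single-level factor: one-way reduction (Kruskal-Wallis)
    g <- if (one_a) rdat$B else rdat$A
    ss <- sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - mean(r))^2))
    dfe <- nlevels(g) - 1
    h <- if (ms_total > 0) ss / ms_total else 0
    p <- if (ms_total > 0) stats::pchisq(h, dfe, lower.tail = FALSE) else 1
    eff <- data.frame(statistic = c(if (one_a) NA else h,
                                    if (one_a) h else NA, NA),
                      df = c(if (one_a) NA else dfe,
                             if (one_a) dfe else NA, NA),
                      p_value = c(if (one_a) NA else p,
                                  if (one_a) p else NA, NA))
    return(.two_way_result(eff, "scheirer_ray_hare", factor_names))
  }
  t2 <- .type2_ss(rdat)
  if (ms_total > 0) {
    h <- t2$ss / ms_total
    p <- stats::pchisq(h, t2$df, lower.tail = FALSE)
  } else {
    h <- rep(0, 3); p <- rep(1, 3)
  }
  .two_way_result(data.frame(statistic = unname(h), df = unname(t2$df),
                             p_value = unname(p)),
                  "scheirer_ray_hare", factor_names)
}

#' Pre/post by group repeated-measures analysis
#'
#' Parametric branch: mixed two-way ANOVA with phase (pre/post) as a
#' two-level within-subject factor and group as a between-subject factor
#' (sphericity is trivially satisfied with two levels). Nonparametric
#' branch: Wilcoxon signed-rank within each group plus Mann-Whitney U on
#' the post-minus-pre differences between groups. The gate is applied to
#' each group's difference scores.
#'
#' @param pre,post Per-animal values, same order as `group_labels`.
#' @param group_labels Group assignment per animal (>= 2 groups, each
#'   n >= 3).
#' @param branch `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param alpha Gate level.
#' @return For the parametric branch a `two_way_result` (effects: group,
#'   phase, group:phase; method `"anova_rm"`). For the nonparametric
#'   branch a list of class `rm_result` with `$within` (one Wilcoxon row
#'   per group) and `$between` (Mann-Whitney on differences).
#' @export
rm_prepost <- function(pre, post, group_labels,
                       branch = c("auto", "parametric", "nonparametric"),
                       alpha = 0.05) {
  branch <- match.arg(branch)
  stopifnot(length(pre) == length(post),
            length(pre) == length(group_labels))
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("need at least two groups for the between effect")
  if (any(table(g) < 3)) stop("every group needs n >= 3")
  d <- post - pre
  if (branch == "auto")
    branch <- normality_gate(split(d, g), alpha)
  if (branch == "parametric") {
    n <- length(pre)
    long <- data.frame(y = c(pre, post),
                       phase = factor(rep(c("pre", "post"), each = n),
                                      levels = c("pre", "post")),
                       group = factor(rep(g, 2)),
                       animal = factor(rep(seq_len(n), 2)))
    fit <- stats::aov(y ~ group * phase + Error(animal), data = long)
    s <- summary(fit)
    betw <- s[["Error: animal"]][[1]]
    with_ <- s[["Error: Within"]][[1]]
    pick <- function(tab, row) {
      i <- which(trimws(rownames(tab)) == row)[1]
      c(statistic = tab[i, "F value"], df = tab[i, "Df"],
        p_value = tab[i, "Pr(>F)"])
    }
    eff <- rbind(pick(betw, "group"), pick(with_, "phase"),
                 pick(with_, "group:phase"))
    res <- .two_way_result(as.data.frame(eff), "anova_rm",
                           c("group", "phase"))
    res$branch <- "parametric"
    return(res)
  }
  within <- do.call(rbind, lapply(levels(g), function(lv) {
    tr <- compare_paired(pre[g == lv], post[g == lv],
                         branch = "nonparametric")
    data.frame(group = lv, test = tr$test_name, statistic = tr$statistic,
               p_value = tr$p_value, tier = tr$tier, n = tr$n)
  }))
  if (nlevels(g) == 2) {
    ds <- split(d, g)
    between <- compare_groups(ds[[1]], ds[[2]], branch = "nonparametric")
  } else {
    between <- scheirer_ray_hare(d, g, rep(1, length(d)),
                                 factor_names = c("group", "-"))
  }
  structure(list(within = within, between = between,
                 branch = "nonparametric", method = "wilcoxon_mw_decomposition"),
            class = "rm_result")
}

#' @export
print.rm_result <- function(x, ...) {
  cat("Repeated-measures decomposition (nonparametric):\nWithin groups:\n")
  print(x$within, row.names = FALSE)
  cat("Between groups (post - pre):\n")
  print(x$between)
  invisible(x)
}

#' First-order partial correlation with a covariate
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided p value from `t = r sqrt(df / (1 - r^2))` on `df = n - 3`
#' degrees of freedom.
#'
#' @param x,y Variables to correlate.
#' @param z Covariate to remove (here: change in locomotion).
#' @param covariate_name Label stored in the result.
#' @return A `partial_corr_result`: list with `r`, `df`, `p_value`, `n`,
#'   `covariate_name`, `tier`.
#' @export
partial_corr <- function(x, y, z, covariate_name = "locomotion_change") {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) stop("need n >= 4 for a first-order partial correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("constant input vector")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 || abs(ryz) >= 1)
    stop("covariate is collinear with x or y")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(max(r, -1), 1)
  df <- n - 3
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  structure(list(r = r, df = df, p_value = p, n = n,
                 covariate_name = covariate_name,
                 tier = significance_tier(p)),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf("Partial correlation (covariate %s): r = %.3f, df = %d, p = %.4g [%s]\n",
              x$covariate_name, x$r, x$df, x$p_value, x$tier))
  invisible(x)
}
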