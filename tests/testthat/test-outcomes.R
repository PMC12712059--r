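test_that("Kaplan-Meier estimate matches the product-limit formula", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  expect_equal(km$time, c(0, 1, 2, 3))
  # all censored: survival stays 1
  kmc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmc$survival == 1))
  # mixed fixture against the hand product-limit oracle
  time <- c(2, 3, 3, 5, 7, 11); event <- c(1, 0, 1, 1, 0, 1)
  km6 <- km_estimate(time, event)
  o <- oracle_km(time, event)
  expect_equal(km6$survival[match(o$time, km6$time)], o$survival)
  # non-increasing step function starting at 1
  expect_true(all(diff(km6$survival) <= 0))
  expect_equal(km6$survival[1], 1)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test agrees with the hypergeometric tabulation oracle", {
  # identical groups: statistic 0, p 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  r0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # 8-record two-group fixture vs oracle
  time <- c(1, 2, 4, 4, 5, 6, 8, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), 4)
  r <- logrank_test(time, event, grp)
  o <- oracle_logrank_2g(time, event, grp == "a")
  expect_equal(r$statistic, o$chisq, tolerance = 1e-9)
  expect_equal(r$df, 1L)
  # three groups: df = 2
  r3 <- logrank_test(c(time, 3, 7), c(event, 1, 1), c(grp, "c", "c"))
  expect_equal(r3$df, 2L)
  expect_error(logrank_test(time, event, rep("a", 8)), "2 groups")
  expect_error(logrank_test(time, rep(0, 8), grp), "1 event")
})

test_that("optimal cutpoint equals the exhaustive scan oracle", {
  # forced separation: low values die early
  time <- c(1, 1.5, 2, 9, 10, 11, 12, 13, 14, 15)
  event <- rep(1, 10)
  x <- c(0.1, 0.2, 0.3, 5.1, 5.2, 5.3, 5.4, 5.5, 5.6, 5.7)
  cp <- optimal_cutpoint(time, event, x)
  expect_gt(cp$cutpoint, 0.3)
  expect_lt(cp$cutpoint, 5.1)
  # random fixtures: exact agreement with the survdiff-based scan
  for (seed in 1:10) {
    f <- random_survival_fixture(40, seed)
    if (sum(f$event) < 2) next
    cp <- optimal_cutpoint(f$time, f$event, f$x)
    o <- oracle_cutpoint(f$time, f$event, f$x)
    expect_equal(cp$cutpoint, o$cutpoint, tolerance = 1e-12)
    expect_equal(cp$statistic, o$statistic, tolerance = 1e-9)
    # inside the minprop window
    q <- quantile(f$x, c(0.1, 0.9), names = FALSE)
    expect_gt(cp$cutpoint, q[1]); expect_lt(cp$cutpoint, q[2])
    # high group is the reference level
    expect_equal(levels(cp$group), c("high", "low"))
  }
  expect_error(optimal_cutpoint(c(1, 2, 3), c(1, 1, 1), c(2, 2, 2)), "constant")
})

test_that("Cox fit solves the partial-likelihood score equation", {
  # single binary covariate, 2 events, no ties: score equation gives
  # exp(beta)^2 = 2, i.e. beta = log(2)/2
  time <- c(1, 2, 3, 4); event <- c(1, 1, 0, 0); x <- c(1, 0, 1, 0)
  fit <- cox_fit(time, event, data.frame(x = x))
  expect_equal(fit$coef, log(2) / 2, tolerance = 1e-4)
  # separation-like input is flagged, not fatal
  ts <- c(1, 2, 3, 10, 11, 12); es <- c(1, 1, 1, 1, 1, 1)
  xs <- c(1, 1, 1, 0, 0, 0)
  fs <- cox_fit(ts, es, data.frame(x = xs))
  expect_true(attr(fs, "flagged"))
  expect_error(cox_fit(time, event, data.frame(x = rep(1, 4))), "constant")
  expect_error(cox_fit(time, c(1, 0, 0, 0), data.frame(x = x)), "more events")
})

test_that("chi-square association applies Yates only to 2x2 tables", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  r <- chisq_association(tab)
  expect_equal(r$statistic, 4 * (5 - 0.5)^2 / 15, tolerance = 1e-12)  # 5.4
  expect_equal(r$df, 1L)
  # table equal to its expected counts: statistic 0, p 1
  eq <- matrix(c(10, 10, 20, 20), 2)
  re <- chisq_association(eq)
  expect_equal(re$statistic, 0, tolerance = 1e-12)
  expect_equal(re$p_value, 1)
  # 3x2: plain Pearson, df 2
  t32 <- matrix(c(10, 5, 8, 12, 6, 9), 3)
  r32 <- chisq_association(t32)
  e32 <- outer(rowSums(t32), colSums(t32)) / sum(t32)
  expect_equal(r32$statistic, sum((t32 - e32)^2 / e32), tolerance = 1e-12)
  expect_equal(r32$df, 2L)
  expect_error(chisq_association(matrix(c(0, 0, 1, 2), 2)), "expected")
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(11)
  v <- rnorm(30); g <- rep(letters[1:3], 10)
  r <- anova_oneway(v, g)
  o <- oracle_anova(v, g)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-9)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
  # two groups: F equals the squared pooled t statistic
  v2 <- rnorm(20); g2 <- rep(c("a", "b"), 10)
  r2 <- anova_oneway(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_error(anova_oneway(rep(1, 6), rep(c("a", "b"), 3)), "variance")
})

test_that("pairwise Wilcoxon uses exact enumeration for small groups and BH adjustment", {
  # identical samples: p ~ 1
  v <- c(1, 2, 3, 4, 1, 2, 3, 4); g <- rep(c("a", "b"), each = 4)
  r <- wilcoxon_bh(v, g)
  expect_gt(r$p_value, 0.9)
  # 3 vs 3 exact p equals full enumeration over C(6,3) splits
  a <- c(1.2, 3.4, 5.1); b <- c(2.2, 6.3, 7.9)
  re <- wilcoxon_bh(c(a, b), rep(c("a", "b"), each = 3))
  expect_equal(re$p_value, oracle_wilcox_exact(a, b), tolerance = 1e-12)
  # BH across the family matches the step-up oracle
  set.seed(12)
  v3 <- c(rnorm(10), rnorm(10, 2), rnorm(10, 0.5))
  g3 <- rep(c("x", "y", "z"), each = 10)
  r3 <- wilcoxon_bh(v3, g3)
  expect_equal(r3$p_adjusted, oracle_bh(r3$p_value), tolerance = 1e-12)
  expect_true(all(r3$p_adjusted >= r3$p_value))
  expect_error(wilcoxon_bh(c(1, 2), c("a", "b")), "singleton")
})

test_that("the BH step-up oracle reproduces the worked adjustment", {
  expect_equal(oracle_bh(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  # and p.adjust agrees with the oracle on random vectors
  set.seed(13)
  for (i in 1:5) {
    p <- runif(sample(3:30, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("one-vs-rest logistic regression recovers the cross-product odds ratio", {
  # 2x2 fixture a=30 b=10 c=10 d=30: OR = 9
  grp <- c(rep("g1", 40), rep("g0", 40))
  lab <- c(rep("X", 30), rep("Y", 10), rep("X", 10), rep("Y", 30))
  ann <- data.frame(sample_id = sprintf("s%d", 1:80), grp = grp)
  r <- logistic_ovr(ann, lab, covariates = "grp", reference = list(grp = "g0"))
  orX <- r$or[r$phenotype == "X" & r$term == "grpg1"]
  expect_equal(orX, 9, tolerance = 1e-6)
  expect_true(all(r$ci_low <= r$or & r$or <= r$ci_high))
  # reference levels never appear as terms
  co <- generate_cohort(cohort_config(n_samples = 300, seed = 17))
  labs <- sample(c("Hot", "Moderate", "Cold"), 300, replace = TRUE)
  rr <- logistic_ovr(co$annotation, labs)
  expect_false(any(grepl("European|<40|LumA|stageI$", rr$term)))
  expect_true(any(grepl("ancestry", rr$term)))
  # null predictor: OR near 1 with covering CI for most terms
  expect_gt(mean(rr$ci_low <= 1 & 1 <= rr$ci_high), 0.8)
})

test_that("stratified balancing reduces every stratum to the minimum size", {
  ann <- data.frame(sample_id = sprintf("s%d", 1:140),
                    grp = c(rep("a", 100), rep("b", 20), rep("c", 20)))
  ids <- stratified_balance(ann, "grp", seed = 3)
  tab <- table(ann$grp[match(ids, ann$sample_id)])
  expect_true(all(tab == 20))
  expect_identical(ids, stratified_balance(ann, "grp", seed = 3))
  # already balanced: identity set
  ann2 <- ann[101:140, ]
  expect_setequal(stratified_balance(ann2, "grp", seed = 1), ann2$sample_id)
})
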