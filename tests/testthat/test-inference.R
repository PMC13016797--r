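test_that("one-sample t matches the textbook formula", {
  x <- c(-0.4, 0.4, -0.1, 0.1, -0.25, 0.25)
  sym <- one_sample_t(x)
  expect_equal(sym$mean, 0)
  expect_equal(sym$t, 0)

  set.seed(40)
  v <- rnorm(89, 0.05, 0.3)
  res <- one_sample_t(v)
  expect_equal(res$df, 88)                       # n = 89 trials
  expect_equal(res$t, mean(v) / (sd(v) / sqrt(89)), tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(abs(res$t), 88, lower.tail = FALSE), tolerance = 1e-12)

  const <- one_sample_t(c(0.1, 0.1, 0.1))
  expect_true(is.infinite(const$t))
  zero <- one_sample_t(c(0, 0, 0))
  expect_equal(zero$t, 0)
  expect_equal(zero$p_value, 1)
  expect_error(one_sample_t(0.2), "at least 2")
})

test_that("BH adjustment equals p.adjust and the threshold oracle", {
  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)
    adj <- bh_fdr(p)
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone non-decreasing in the raw p within the family
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
  # direct brute-force threshold oracle on a handful of families
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, NA)), "0, 1")
})

test_that("rank-sum statistics match the enumeration oracle", {
  # x = {1,2}, y = {3,4}: W at its minimum; two-sided exact p = 2/6
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$W, 0)
  expect_equal(rs$p_value, 2 / 6, tolerance = 1e-12)

  # invariant under strictly monotone transforms of the pooled data
  set.seed(43)
  x <- rnorm(15)
  y <- rnorm(12, 0.5)
  a <- rank_sum_test(x, y)
  b <- rank_sum_test(exp(x), exp(y))
  expect_equal(a$W, b$W)
  expect_equal(a$p_value, b$p_value)

  ident <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p_value, 0.9)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("Spearman consistency handles identity, reversal and the null", {
  a <- c(0.3, -0.2, 0.8, 0.1, -0.6)
  expect_equal(spearman_consistency(a, a)$rho, 1)
  expect_equal(spearman_consistency(a, -a)$rho, -1)

  set.seed(44)
  rhos <- vapply(1:300, function(i)
    spearman_consistency(rnorm(46), rnorm(46))$rho, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))

  # undefined scores drop pairwise
  b <- a
  b[2] <- NA
  expect_equal(spearman_consistency(a, b)$n, 4)
  expect_error(spearman_consistency(c(1, 2, NA), c(1, NA, 3)), ">= 3")
  expect_error(spearman_consistency(1:4, 1:5), "aligned")
})

test_that("a zero-variance grouping factor reduces the LMM to OLS", {
  set.seed(45)
  n <- 120
  dat <- data.frame(x = rnorm(n), g = factor(rep(letters[1:6], 20)))
  dat$y <- 1 + 0.5 * dat$x + rnorm(n, 0, 0.4)
  m <- suppressWarnings(fit_mixed_model(
    model_spec("y", "gaussian", "x", random = "g"), dat))
  ols <- coef(lm(y ~ x, dat))
  expect_equal(m$result$estimate, unname(ols), tolerance = 1e-4)
})

test_that("the NB GLMM recovers a known log rate ratio", {
  cc <- simulate_behavior_counts(behavior_sim_params(
    base_rate = 20, effect_relatedness = log(0.5), dispersion = 2,
    arena_sd = 0.3, n_arenas = 300, seed = 46))
  m <- fit_mixed_model(model_spec(
    "count", "negative-binomial", c("relatedness", "mating_status"),
    random = "arena_id"), cc)
  est <- m$result[m$result$term == "relatednessunrelated", ]
  expect_lt(abs(est$estimate - log(0.5)), 3 * est$se)
  expect_true(m$converged)
})

test_that("stepwise pruning removes null interactions and keeps structure", {
  set.seed(47)
  dat <- expand.grid(a = c("x", "y"), b = c("u", "v"),
                     g = paste0("g", 1:10), rep = 1:6)
  dat$y <- rnorm(nrow(dat)) + (dat$a == "y") * 1.5
  m <- suppressWarnings(fit_mixed_model(
    model_spec("y", "gaussian", c("a", "b"), random = "g"), dat))
  expect_true("a:b" %in% m$dropped)
  expect_false(any(grepl(":", m$result$term)))
  expect_true(all(c("conf_low", "conf_high") %in% names(m$result)))
  expect_true(all(m$result$conf_low <= m$result$estimate &
                    m$result$estimate <= m$result$conf_high))
})

test_that("rank-deficient designs are rejected naming the collinear term", {
  dat <- data.frame(y = rnorm(40), x1 = rnorm(40), g = gl(4, 10))
  dat$x2 <- dat$x1 * 2
  expect_error(fit_mixed_model(model_spec(
    "y", "gaussian", c("x1", "x2"), random = "g"), dat),
    "rank-deficient.*x2")
  expect_error(fit_mixed_model(model_spec(
    "y", "gaussian", "x1", random = "g"), dat[, c("y", "x1")]),
    "lacks columns")
})

test_that("LR chi-square agrees with the Wald z^2 asymptotically", {
  set.seed(48)
  n <- 10000
  dat <- data.frame(rel = rep(c("related", "unrelated"), each = n / 2),
                    g = factor(rep(1:20, n / 20)))
  mu <- exp(2 + 0.15 * (dat$rel == "unrelated"))
  dat$count <- rnbinom(n, mu = mu, size = 2)
  m <- fit_mixed_model(model_spec(
    "count", "negative-binomial", "rel", random = "g",
    max_interaction_order = 1), dat)
  lr <- likelihood_ratio_anova(m, "rel")
  z <- m$result$statistic[m$result$term == "relunrelated"]
  expect_equal(lr$df, 1)
  expect_lt(abs(lr$chisq - z^2) / z^2, 0.05)
  # and with the established Wald analysis-of-deviance implementation
  wald <- car::Anova(m$fit, type = "II")
  expect_lt(abs(lr$chisq - wald[["Chisq"]][1]) / wald[["Chisq"]][1], 0.05)
})

test_that("dropping a null predictor changes deviance by about chi-square df", {
  set.seed(49)
  dev <- vapply(1:60, function(i) {
    dat <- data.frame(x = rnorm(120), z = rnorm(120),
                      g = factor(rep(1:6, 20)))
    dat$y <- 1 + 0.8 * dat$z + rnorm(120)
    m <- suppressWarnings(fit_mixed_model(model_spec(
      "y", "gaussian", c("x", "z"), random = "g",
      max_interaction_order = 1), dat))
    suppressWarnings(likelihood_ratio_anova(m, "x"))$chisq
  }, numeric(1))
  dev <- dev[!is.na(dev)]
  expect_lt(abs(mean(dev) - 1), 3 * sd(dev) / sqrt(length(dev)))
})

test_that("Tukey contrasts cover all level pairs and are antisymmetric", {
  set.seed(50)
  dat <- data.frame(f = factor(rep(c("a", "b", "c"), each = 40)),
                    g = factor(rep(1:8, 15)))
  dat$y <- rnorm(120) + (dat$f == "c") * 2
  m <- suppressWarnings(fit_mixed_model(model_spec(
    "y", "gaussian", "f", random = "g"), dat))
  tk <- tukey_pairwise(m, "f")
  expect_equal(nrow(tk), 3)

  dat$f2 <- factor(dat$f, levels = c("c", "b", "a"))
  m2 <- suppressWarnings(fit_mixed_model(model_spec(
    "y", "gaussian", "f2", random = "g"), dat))
  tk2 <- tukey_pairwise(m2, "f2")
  ab <- tk$estimate[tk$contrast == "a - b"]
  ba <- tk2$estimate[tk2$contrast == "b - a"]
  expect_equal(ab, -ba, tolerance = 1e-6)

  expect_error(tukey_pairwise(m, "g2"), "not a model predictor")
  dat$two <- factor(rep(c("p", "q"), 60))
  m3 <- suppressWarnings(fit_mixed_model(model_spec(
    "y", "gaussian", "two", random = "g"), dat))
  expect_error(tukey_pairwise(m3, "two"), ">= 3")
})

test_that("identical levels rarely yield significant Tukey contrasts", {
  set.seed(51)
  ok <- vapply(1:50, function(i) {
    dat <- data.frame(f = factor(rep(c("a", "b", "c"), each = 20)),
                      g = factor(rep(1:6, 10)))
    dat$y <- rnorm(60) + (dat$f == "c") * 3   # a and b stay identical
    m <- suppressWarnings(fit_mixed_model(model_spec(
      "y", "gaussian", "f", random = "g"), dat))
    tk <- tukey_pairwise(m, "f")
    tk$p_adj[tk$contrast == "a - b"] > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.88)
})
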