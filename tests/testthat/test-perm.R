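test_that("exhaustive permutation p-values match brute-force enumeration", {
  designs <- list(
    list(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b")),
    list(v = c(5, 1, 4, 2, 8), g = c("a", "a", "b", "b", "b")),
    list(v = c(0.3, -1, 2, 2.5, 1.1, 0.7), g = rep(c("a", "b", "c"), each = 2)),
    list(v = c(4, 6, 1, 2, 9, 9, 3, 0), g = rep(c("a", "b"), each = 4))
  )
  for (d in designs) {
    res <- perm_anova(d$v, d$g)
    expect_equal(res$stopped_by, "exhaustive")
    expect_equal(res$p_hat, perm_oracle_linear(d$v, d$g))
  }
})

test_that("the two-group toy design gives the known exact p-value", {
  res <- perm_anova(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$p_hat, 2 / 6)
})

test_that("degenerate responses return p = 1 with a warning", {
  expect_warning(res <- perm_anova(rep(3, 8), rep(c("a", "b"), 4)),
                 "zero total variance")
  expect_equal(res$p_hat, 1)
  expect_warning(resb <- perm_anova_binomial(rep(1, 10), rep(c("a", "b"), 5)),
                 "degenerate")
  expect_equal(resb$p_hat, 1)
})

test_that("p is invariant to label renaming and location shifts", {
  set.seed(31)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  cfg <- perm_config(max_iter = 2000, min_iter = 2000, seed = 99)
  base <- perm_anova(v, g, cfg)
  renamed <- perm_anova(v, chartr("abc", "xyz", g), cfg)
  shifted <- perm_anova(v + 100, g, cfg)
  expect_equal(renamed$p_hat, base$p_hat)
  expect_equal(shifted$p_hat, base$p_hat)
})

test_that("Monte Carlo p-values agree with the exact enumeration", {
  v <- c(5, 1, 4, 2, 8, 3, 7, 6)
  g <- rep(c("a", "b"), each = 4)
  exact <- perm_anova(v, g)$p_hat
  cfg0 <- perm_config(max_iter = 4000, min_iter = 4000, exhaustive_limit = 1)
  hits <- vapply(1:60, function(s) {
    cfg0$seed <- s
    mc <- perm_anova(v, g, cfg0)
    abs(mc$p_hat - exact) < 3 * mc$se_p
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("binomial exhaustive p matches hypergeometric enumeration", {
  # total separation of two groups of 10: p = 2 / choose(20, 10)
  res <- perm_anova_binomial(c(rep(0, 10), rep(1, 10)),
                             rep(c("a", "b"), each = 10))
  expect_equal(res$stopped_by, "exhaustive")
  expect_equal(res$p_hat, 2 / choose(20, 10))
  # small case against the brute-force oracle
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(perm_anova_binomial(y, g)$p_hat, perm_oracle_binomial(y, g))
  # identical proportions: p near 1
  res2 <- perm_anova_binomial(rep(c(1, 0), 10), rep(c("a", "b"), each = 10))
  expect_gt(res2$p_hat, 0.9)
})

test_that("the sequential stopping rule is honoured or reported", {
  cfg <- perm_config(se_ratio = 0.2, max_iter = 5e4, min_iter = 1000,
                     exhaustive_limit = 1, seed = 5)
  set.seed(6)
  res <- perm_anova(rnorm(20), rep(c("a", "b"), 10), cfg)
  if (res$stopped_by == "se_rule") {
    expect_lt(res$se_p, res$p_hat * cfg$se_ratio)
    expect_lt(res$n_iter, cfg$max_iter)
  } else {
    expect_equal(res$n_iter, cfg$max_iter)
  }
})

test_that("Tukey HSD agrees with a direct studentized-range computation", {
  set.seed(8)
  v <- c(rnorm(5), rnorm(5) + 1.2, rnorm(5) + 2.5)
  g <- rep(c("g1", "g2", "g3"), each = 5)
  tk <- tukey_hsd(v, g)
  # manual computation: balanced design, k = 3, df = 12
  mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / 12
  means <- tapply(v, g, mean)
  man_p <- stats::ptukey(abs(means["g3"] - means["g1"]) / sqrt(mse / 5),
                         nmeans = 3, df = 12, lower.tail = FALSE)
  row <- tk[tk$group_a == "g3" & tk$group_b == "g1", ]
  expect_equal(row$p_adj, unname(man_p), tolerance = 1e-8)
  # decision boundary equals the textbook critical value q(0.05, 3, 12)
  expect_equal(stats::qtukey(0.95, 3, 12), 3.77, tolerance = 1e-3)
  expect_equal(row$significant,
               abs(means["g3"] - means["g1"]) / sqrt(mse / 5) >
                 stats::qtukey(0.95, 3, 12), ignore_attr = TRUE)
})

test_that("Tukey HSD handles identical groups and tiny groups", {
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  tk <- tukey_hsd(v, g)
  expect_equal(tk$diff, 0)
  expect_false(tk$significant)
  expect_warning(tukey_hsd(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "single observation")
  # direction relative to a designated control
  set.seed(9)
  v2 <- c(rnorm(5, 10), rnorm(5, 2))
  tk2 <- tukey_hsd(v2, rep(c("control", "high"), each = 5),
                   control = "control")
  expect_equal(tk2$direction, "Decrease")
})

test_that("the endpoint battery reports chance-expected counts", {
  expect_equal(expected_false_positives(28), 1.4)
  set.seed(12)
  n <- 40
  design <- tibble::tibble(
    subject_id = as.character(1:n), chemical = "PFOA",
    dose_ppm = rep(c(0, 188, 242, 294), each = 10),
    plate = "P1", well = "A1", breed = "B1",
    excluded = FALSE, exclusion_reason = NA_character_)
  ep <- tibble::tibble(
    subject_id = as.character(1:n),
    total_distance_mm = rnorm(n) + 3 * (design$dose_ppm > 0), # planted
    bouts_per_s = rnorm(n))                                   # null
  cfg <- perm_config(max_iter = 2000, min_iter = 2000, seed = 1)
  bat <- endpoint_battery(ep, design, cfg,
                          endpoint_cols = c("total_distance_mm",
                                            "bouts_per_s"))
  expect_equal(bat$n_tests, 2L)
  expect_equal(bat$expected_by_chance, 0.1)
  p_planted <- bat$anova$p[bat$anova$endpoint == "total_distance_mm"]
  p_null <- bat$anova$p[bat$anova$endpoint == "bouts_per_s"]
  expect_lt(p_planted, 0.01)
  expect_lt(p_planted, p_null)
  expect_error(endpoint_battery(ep, design[0, ], cfg), "empty")
})
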