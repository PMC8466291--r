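# Simulation scale note: the screening / selection operating-characteristic
# checks use a few hundred replicates at the study's n, which bounds the
# Monte-Carlo error on an empirical rate near 0.2 to about +/-1.8pp (1 SE).

test_that("univariable screening keeps a null covariate at about the 20% rate", {
  set.seed(11)
  n <- 271; reps <- 500
  hits <- 0L
  for (r in seq_len(reps)) {
    d <- data.frame(dlwg = rnorm(n), x = rnorm(n))
    p <- summary(lm(dlwg ~ x, data = d))$coefficients["x", 4]
    sp <- model_spec("dlwg", "x")
    scr <- univariable_screen(d, sp)
    expect_equal(scr$p_value, unname(p), tolerance = 1e-10)
    if (scr$kept) hits <- hits + 1L
  }
  expect_lt(abs(hits / reps - 0.20), 0.03)
})

test_that("screening has near-certain power for a strong effect", {
  set.seed(12)
  n <- 271; reps <- 200
  kept <- vapply(seq_len(reps), function(r) {
    x <- rnorm(n)
    d <- data.frame(x = x, dlwg = 0.5 * x + rnorm(n))
    univariable_screen(d, model_spec("dlwg", "x"))$kept
  }, logical(1))
  expect_gte(mean(kept), 0.99)
})

test_that("screening skips constant columns without touching the rest", {
  set.seed(13)
  d <- data.frame(dlwg = rnorm(60), x = rnorm(60), flat = 1)
  expect_warning(scr <- univariable_screen(d, model_spec("dlwg", c("flat", "x"))),
                 "constant")
  expect_false(scr$kept[scr$term == "flat"])
  expect_true(is.na(scr$p_value[scr$term == "flat"]))
  expect_false(is.na(scr$p_value[scr$term == "x"]))
})

test_that("backward selection retains active terms and only p<0.05 terms", {
  set.seed(21)
  n <- 271
  cat <- factor(sample(c("a", "b", "c", "d"), n, replace = TRUE),
                levels = c("a", "b", "c", "d"))
  bw <- rnorm(n, 43.2, 6.2)
  age <- sample(6:14, n, replace = TRUE)
  eff <- c(a = 0, b = -0.061, c = -0.157, d = -0.199)
  d <- data.frame(category = cat, birth_weight = bw, exit_age = age,
                  noise = rnorm(n))
  d$dlwg <- 0.537 + eff[cat] - 0.018 * bw + 0.028 * age + rnorm(n, 0, 0.30)
  sp <- model_spec("dlwg", c("category", "birth_weight", "exit_age", "noise"))
  res <- backward_select(d, sp$terms, sp)
  expect_true(all(c("category", "birth_weight", "exit_age") %in% res$terms))
  expect_true(all(res$term_p < 0.05))
  expect_lte(nrow(res$trace), length(sp$terms))
})

test_that("backward selection under the null reaches the intercept-only model", {
  set.seed(22)
  reps <- 200
  # one pure-noise covariate: the exact null retention rate is alpha = 5%
  single <- vapply(seq_len(reps), function(r) {
    d <- data.frame(dlwg = rnorm(100), x = rnorm(100))
    sp <- model_spec("dlwg", "x")
    length(backward_select(d, "x", sp)$terms) == 0
  }, logical(1))
  expect_lt(abs(mean(single) - 0.95), 0.04)
  # three independent noise covariates: null rate approx 0.95^3
  triple <- vapply(seq_len(reps), function(r) {
    d <- data.frame(dlwg = rnorm(100), x1 = rnorm(100), x2 = rnorm(100),
                    x3 = rnorm(100))
    sp <- model_spec("dlwg", c("x1", "x2", "x3"))
    length(backward_select(d, sp$terms, sp)$terms) == 0
  }, logical(1))
  expect_gte(mean(triple), 0.80)
})

test_that("a perfectly collinear duplicate is dropped deterministically", {
  set.seed(23)
  n <- 80
  x <- rnorm(n)
  d <- data.frame(dlwg = 1 + 0.8 * x + rnorm(n, 0, 0.3), x1 = x, x2 = x)
  sp <- model_spec("dlwg", c("x1", "x2"))
  res <- backward_select(d, c("x1", "x2"), sp)
  expect_equal(res$terms, "x1")             # the later duplicate goes first
  expect_equal(res$trace$term[1], "x2")
})

test_that("mixed and fixed-effect fits agree when random variances are zero", {
  set.seed(33)
  n <- 240
  d <- data.frame(
    x = rnorm(n),
    g = factor(rep(1:12, each = 20)),
    p = factor(rep(1:8, length.out = n))
  )
  d$dlwg <- 0.3 + 0.5 * d$x + rnorm(n, 0, 0.2)   # no group structure at all
  ols <- fit_growth_model(d, "dlwg", "x")
  lmm <- fit_growth_model(d, "dlwg", "x", random = c("g", "p"))
  expect_s4_class(lmm, "lmerMod")
  # the REML fit collapses both variance components onto the boundary ...
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(vc$vcov[vc$grp %in% c("g", "p")], c(0, 0), tolerance = 1e-12)
  # ... and there the mixed model is exactly generalised-least-squares = OLS
  expect_equal(unname(lme4::fixef(lmm)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("random-intercept variance is recovered when structure is present", {
  set.seed(32)
  reps <- 20
  est <- vapply(seq_len(reps), function(r) {
    g <- factor(rep(1:24, each = 10))
    u <- rnorm(24, 0, 0.05)
    d <- data.frame(g = g, x = rnorm(240))
    d$dlwg <- 0.2 + 0.3 * d$x + u[g] + rnorm(240, 0, 0.15)
    fit <- fit_growth_model(d, "dlwg", "x", random = "g")
    as.data.frame(lme4::VarCorr(fit))$vcov[1]
  }, numeric(1))
  truth <- 0.05^2
  expect_gt(mean(est), truth * 0.5)
  expect_lt(mean(est), truth * 2)
})

test_that("the mixed-model likelihood-ratio test holds its size", {
  set.seed(33)
  reps <- 150
  p <- vapply(seq_len(reps), function(r) {
    g <- factor(rep(1:10, each = 12))
    u <- rnorm(10, 0, 0.05)
    d <- data.frame(g = g, x = rnorm(120))
    d$dlwg <- 0.2 + u[g] + rnorm(120, 0, 0.2)    # x truly null
    calfclim:::term_pvalues(d, "dlwg", "x", random = "g")
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.10)
})

test_that("mixed fits are stable across optimiser starts", {
  set.seed(34)
  g <- factor(rep(1:18, each = 12))
  u <- rnorm(18, 0, 0.05)
  d <- data.frame(g = g, x = rnorm(216))
  d$dlwg <- 0.2 + 0.4 * d$x + u[g] + rnorm(216, 0, 0.15)
  f1 <- lmerTest::lmer(dlwg ~ x + (1 | g), data = d, REML = TRUE,
                       control = lme4::lmerControl(optimizer = "bobyqa"))
  f2 <- lmerTest::lmer(dlwg ~ x + (1 | g), data = d, REML = TRUE,
                       control = lme4::lmerControl(optimizer = "Nelder_Mead"))
  expect_equal(unname(lme4::fixef(f1)), unname(lme4::fixef(f2)),
               tolerance = 1e-4)
})

test_that("Tukey contrasts behave at the null and under the study pattern", {
  set.seed(41)
  n <- 400
  f <- factor(sample(letters[1:4], n, replace = TRUE))
  d <- data.frame(f = f, dlwg = 0.5 + rnorm(n, 0, 0.05))
  sp <- model_spec("dlwg", "f")
  fit <- fit_growth_model(d, "dlwg", "f")
  res <- calfclim:::model_result(fit, d, "f",
                                 calfclim:::term_pvalues(d, "dlwg", "f"), sp)
  tk <- tukey_posthoc(res, "f")
  expect_equal(nrow(tk), 6)
  expect_true(all(tk$p_adj > 0.05))

  # under the study's B2G category effects, the extreme-category contrast
  # is the most frequently significant pair
  eff <- c(a = 0, b = -0.061, c = -0.157, d = -0.199)
  hits <- matrix(0, nrow = 6, ncol = 1)
  labs <- NULL
  for (r in 1:40) {
    f <- factor(sample(letters[1:4], 271, replace = TRUE))
    d <- data.frame(f = f)
    d$dlwg <- 0.1 + eff[f] + rnorm(271, 0, 0.30)
    fit <- fit_growth_model(d, "dlwg", "f")
    tk <- tukey_posthoc(fit, "f")
    labs <- tk$contrast
    hits <- hits + (tk$p_adj < 0.05)
  }
  expect_equal(labs[which.max(hits)], "a - d")

  # two-level factor: the single contrast needs no adjustment
  f2 <- factor(sample(c("lo", "hi"), 200, replace = TRUE),
               levels = c("lo", "hi"))
  d2 <- data.frame(f = f2, dlwg = rnorm(200) + 0.3 * (f2 == "hi"))
  fit2 <- fit_growth_model(d2, "dlwg", "f")
  tk2 <- tukey_posthoc(fit2, "f")
  raw_p <- summary(fit2)$coefficients["fhi", 4]
  expect_equal(nrow(tk2), 1)
  expect_equal(tk2$p_adj, raw_p, tolerance = 1e-8)
})

test_that("tukey_posthoc refuses factors outside the final model", {
  set.seed(42)
  d <- data.frame(dlwg = rnorm(50), x = rnorm(50),
                  f = factor(sample(1:3, 50, replace = TRUE)))
  sp <- model_spec("dlwg", "x")
  res <- backward_select(d, "x", sp)
  expect_error(tukey_posthoc(res, "f"), "not in the final model")
})
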