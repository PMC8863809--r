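test_that("with a degenerate random effect the fixed estimates equal OLS", {
  set.seed(3)  # a draw whose group variance estimate sits exactly at zero
  n <- 120
  d <- data.frame(x = rnorm(n), g = sample(c("a", "b", "c"), n, TRUE))
  d$y <- 1 + 0.5 * d$x + rnorm(n)  # no group effect at all
  spec <- lmm_spec(fixed = "x", random = "g", control = NULL,
                   response = "y")
  fit <- fit_lmm(d, spec, method = "ML")
  ols <- coef(lm(y ~ x, data = d))
  expect_true(fit$singular)
  expect_equal(unname(lme4::fixef(fit$model)), unname(ols),
               tolerance = 1e-6)
})

test_that("balanced one-factor variance components match closed-form ANOVA", {
  set.seed(3)
  g <- gl(8, 12, labels = sprintf("s%d", 1:8))
  y <- rnorm(96, rep(rnorm(8, 0, 1.5), each = 12), 1)
  d <- data.frame(y = y, g = g)
  fit <- fit_lmm(d, lmm_spec(fixed = character(0), random = "g",
                             control = NULL, response = "y"),
                 method = "REML")
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  av <- anova(lm(y ~ g, data = d))
  msb <- av["g", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  expect_equal(vc$vcov[vc$grp == "g"], (msb - msw) / 12, tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], msw, tolerance = 1e-6)
})

test_that("a rank-deficient fixed design is an error naming the alias", {
  d <- data.frame(y = rnorm(40), x = rnorm(40),
                  g = sample(c("a", "b"), 40, TRUE))
  d$z <- 2 * d$x
  expect_error(
    fit_lmm(d, lmm_spec(fixed = c("x", "z"), random = "g", control = NULL,
                        response = "y"), "ML"),
    "rank-deficient.*z")
})

test_that("AICc follows its formula and approaches AIC for large n", {
  expect_equal(aicc(-7, k = 3, n = 10), 14 + 6 + 24 / 6)
  aic <- -2 * (-7) + 2 * 3
  expect_lt(abs(aicc(-7, k = 3, n = 1e7) - aic), 1e-5)
  expect_warning(val <- aicc(-7, k = 9, n = 10), "Inf")
  expect_identical(val, Inf)
})

test_that("AICc of nested fits uses each model's own parameter count", {
  set.seed(4)
  d <- data.frame(y = rnorm(60), x = rnorm(60),
                  g = sample(c("a", "b", "c"), 60, TRUE))
  f0 <- fit_lmm(d, lmm_spec(random = "g", control = NULL, response = "y"),
                "ML")
  f1 <- fit_lmm(d, lmm_spec(fixed = "x", random = "g", control = NULL,
                            response = "y"), "ML")
  expect_equal(f1$k, f0$k + 1)
  expect_equal(f1$aicc, aicc(f1$logLik, k = f1$k, n = f1$n))
})

test_that("dredge enumerates 2^m subsets and respects marginality", {
  set.seed(5)
  n <- 80
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n),
                  g = sample(c("u", "v", "w"), n, TRUE))
  base <- lmm_spec(random = "g", control = NULL, response = "y")
  sel <- dredge_select(d, base, c("a", "b", "c"))
  expect_equal(sel$n_models, 8L)
  # with an interaction, only marginality-respecting subsets appear
  sel2 <- dredge_select(d, base, c("a", "b", "a:b"))
  expect_equal(sel2$n_models, 5L)
  has_int <- grepl("a:b", sel2$table$terms, fixed = TRUE)
  for (t in sel2$table$terms[has_int]) {
    expect_match(t, "\\ba \\+"); expect_match(t, "\\bb\\b")
  }
  # empty candidate set returns the null model
  sel0 <- dredge_select(d, base, character(0))
  expect_equal(sel0$n_models, 1L)
  expect_length(sel0$best_spec$fixed, 0)
})

test_that("dredge ranking is invariant under candidate ordering", {
  set.seed(6)
  n <- 100
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n),
                  g = sample(c("u", "v", "w"), n, TRUE))
  d$y <- d$y + 0.8 * d$a
  base <- lmm_spec(random = "g", control = NULL, response = "y")
  s1 <- dredge_select(d, base, c("a", "b", "c"))
  s2 <- dredge_select(d, base, c("c", "b", "a"))
  expect_identical(s1$table$terms, s2$table$terms)
  expect_identical(s1$best_spec$fixed, s2$best_spec$fixed)
})

test_that("a strong planted effect is selected by dredge", {
  hits <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 300
    d <- data.frame(a = rbinom(n, 1, 0.5), b = rnorm(n),
                    g = sample(sprintf("s%d", 1:9), n, TRUE))
    d$y <- 0.1 * d$a + rnorm(9, 0, 0.1)[as.integer(factor(d$g))] +
      rnorm(n, 0, 0.15)
    base <- lmm_spec(random = "g", control = NULL, response = "y")
    sel <- dredge_select(d, base, c("a", "b"))
    "a" %in% sel$best_spec$fixed
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the LRT is zero for identical models and chi-square for nested", {
  set.seed(7)
  d <- data.frame(y = rnorm(80), x = rnorm(80),
                  g = sample(c("a", "b", "c"), 80, TRUE))
  f0 <- fit_lmm(d, lmm_spec(random = "g", control = NULL, response = "y"),
                "ML")
  expect_equal(lrt(f0, f0), list(chisq = 0, df = 0, p = 1))
  f1 <- fit_lmm(d, lmm_spec(fixed = "x", random = "g", control = NULL,
                            response = "y"), "ML")
  out <- lrt(f1, f0)
  expect_equal(out$df, 1)
  expect_equal(out$chisq, 2 * (f1$logLik - f0$logLik))
  expect_equal(out$p, pchisq(out$chisq, 1, lower.tail = FALSE))
  # cross-check against the generic likelihood-ratio machinery
  skip_if_not_installed("lmtest")
  lt <- lmtest::lrtest(f1$model, f0$model)
  expect_equal(out$chisq, lt$Chisq[2], tolerance = 1e-8)
})

test_that("non-nested or REML fits are rejected by the LRT", {
  set.seed(8)
  d <- data.frame(y = rnorm(60), x = rnorm(60), z = rnorm(60),
                  g = sample(c("a", "b"), 60, TRUE))
  fx <- fit_lmm(d, lmm_spec(fixed = "x", random = "g", control = NULL,
                            response = "y"), "ML")
  fz <- fit_lmm(d, lmm_spec(fixed = "z", random = "g", control = NULL,
                            response = "y"), "ML")
  expect_error(lrt(fx, fz), "not nested")
  fr <- fit_lmm(d, lmm_spec(random = "g", control = NULL, response = "y"),
                "REML")
  expect_error(lrt(fx, fr), "ML")
})

test_that("single-coefficient Wald chi-square equals (estimate/SE)^2", {
  set.seed(9)
  n <- 150
  d <- data.frame(x = rbinom(n, 1, 0.5),
                  g = sample(sprintf("s%d", 1:6), n, TRUE))
  d$y <- 0.4 * d$x + rnorm(6, 0, 0.3)[as.integer(factor(d$g))] + rnorm(n)
  fit <- fit_lmm(d, lmm_spec(fixed = "x", random = "g", control = NULL,
                             response = "y"), "REML")
  tc <- term_chisq(fit)
  sm <- summary(fit$model)$coefficients
  expect_equal(tc$chisq[tc$term == "x"],
               unname((sm["x", "Estimate"] / sm["x", "Std. Error"])^2),
               tolerance = 1e-8)
})

test_that("two-level contrasts equal the coefficient difference", {
  set.seed(10)
  n <- 120
  d <- data.frame(f = sample(c("lo", "hi"), n, TRUE),
                  g = sample(sprintf("s%d", 1:5), n, TRUE))
  d$y <- 0.5 * (d$f == "hi") + rnorm(5, 0, 0.2)[as.integer(factor(d$g))] +
    rnorm(n, 0, 0.4)
  fit <- fit_lmm(d, lmm_spec(fixed = "f", random = "g", control = NULL,
                             response = "y"), "REML")
  ct_t <- pairwise_contrasts(fit, "f", adjust = "tukey")
  ct_n <- pairwise_contrasts(fit, "f", adjust = "none")
  beta <- lme4::fixef(fit$model)[["flo"]]
  expect_equal(abs(ct_t$estimate), abs(beta), tolerance = 1e-8)
  # a single comparison: Tukey and unadjusted p agree
  expect_equal(ct_t$p_adj, ct_n$p_adj, tolerance = 1e-5)
  expect_equal(ct_t$df, fit$n - fit$k_fixed)
  expect_error(pairwise_contrasts(fit, "g"), "not a fixed term")
})

test_that("confound calibration flags the planted confounds only", {
  flags <- lapply(c(2, 5, 9), function(sd) {
    ds <- generate_dataset(generator_config(seed = sd, n_events_per_type = 1,
                                            n_baseline_events = 392))
    corr <- suppressWarnings(correct_thermal(ds$pictures))
    ev <- merge(ds$events, corr, by = "event_id")
    calibrate_confounds(ev[ev$event_type == "baseline", ])$flagged
  })
  hit <- vapply(flags, function(f)
    setequal(f, c("ambient_c", "movement")), logical(1))
  expect_gte(mean(hit), 2 / 3)
  expect_true(all(vapply(flags, function(f) "ambient_c" %in% f, logical(1))))
})

test_that("the centered ambient covariate has mean zero", {
  ds <- small_dataset(seed = 12)
  corr <- suppressWarnings(correct_thermal(ds$pictures))
  ev <- merge(ds$events, corr, by = "event_id")
  conf <- calibrate_confounds(ev[ev$event_type == "baseline", ])
  centered <- ev$ambient_c[ev$event_type == "baseline"] - conf$ambient_mean
  expect_lt(abs(mean(centered)), 1e-12)
})

test_that("a constant confound is skipped with a warning", {
  d <- data.frame(log_temp = rnorm(50, 3.5, 0.05),
                  subject_id = sample(c("a", "b", "c"), 50, TRUE),
                  ambient_c = rnorm(50, 25), humidity_pct = 60,
                  distance_m = runif(50, 7, 15),
                  movement = sample(c("no_movement", "steps"), 50, TRUE))
  expect_warning(conf <- calibrate_confounds(d), "humidity_pct")
  expect_false("humidity_pct" %in% conf$table$term)
})
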