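test_that("noiseless data are recovered exactly on the standardized scale", {
  spec <- path_spec(
    data.frame(from = c("x1", "x2", "x3"), to = "y",
               coef = c(0.4, -0.3, 0.1)),
    disturbance_sd = c(y = 0))
  s <- simulate_subjects(spec, 60, seed = 14)
  # zero residuals: summary.lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(fit_path_model(s, spec, standardize = FALSE))
  expect_equal(unname(coef(fit)[c("x1->y", "x2->y", "x3->y")]),
               c(0.4, -0.3, 0.1), tolerance = 1e-8)
  expect_equal(get_coefficient(fit, "x2", "y"), -0.3, tolerance = 1e-8)
})

test_that("a single-arc toy model reproduces the closed-form slope", {
  toy <- data.frame(x = c(0, 1, 2), y = c(0, 2, 4))
  fit <- suppressWarnings(fit_path_model(toy, data.frame(from = "x", to = "y"),
                                        standardize = FALSE))
  expect_equal(unname(coef(fit)["x->y"]), 2, tolerance = 1e-10)
  # independent per-equation least-squares oracle
  expect_equal(get_coefficient(fit, "x", "y"), unname(coef(lm(y ~ x, toy))["x"]),
               tolerance = 1e-12)
})

test_that("all nine published coefficients are recovered at n = 5000", {
  spec <- default_path_spec()
  s <- simulate_subjects(spec, 5000, seed = 1)
  fit <- fit_path_model(s, spec)
  truth <- c("em->psych_trait" = 0.310, "ex->psych_trait" = 0.156,
             "ag->psych_trait" = -0.250, "op->psych_trait" = -0.025,
             "co->psych_trait" = -0.298, "hh->psych_trait" = -0.263,
             "age->psych_trait" = -0.011, "sex->psych_trait" = -0.145,
             "demog->cw" = -0.938)
  est <- coef(fit)[names(truth)]
  expect_true(all(abs(est - truth) <= 0.05))
  expect_lt(fit$fit_stats$p_value, 1) # chi-square computed and proper
  expect_gte(fit$fit_stats$chisq, 0)
})

test_that("estimates concentrate and SEs shrink like 1/sqrt(n)", {
  spec <- default_path_spec()
  truth <- c(0.310, 0.156, -0.250, -0.025, -0.298, -0.263, -0.011, -0.145,
             -0.938)
  arcs9 <- c("em->psych_trait", "ex->psych_trait", "ag->psych_trait",
             "op->psych_trait", "co->psych_trait", "hh->psych_trait",
             "age->psych_trait", "sex->psych_trait", "demog->cw")
  res <- lapply(c(500, 2000, 5000), function(n) {
    fit <- fit_path_model(simulate_subjects(spec, n, seed = 77), spec)
    i <- match("em", fit$coefficients$from)
    list(mae = mean(abs(coef(fit)[arcs9] - truth)),
         se = fit$coefficients$se[i])
  })
  mae <- vapply(res, `[[`, numeric(1), "mae")
  expect_true(all(diff(mae) < 0))
  se <- vapply(res, `[[`, numeric(1), "se")
  expect_equal(se[1] / se[2], sqrt(2000 / 500), tolerance = 0.2)
  expect_equal(se[2] / se[3], sqrt(5000 / 2000), tolerance = 0.2)
})

test_that("reasoning-I summary echoes the fitted demographic arcs", {
  spec <- default_path_spec()
  spec$disturbance_sd[] <- 0
  s <- simulate_subjects(spec, 400, seed = 19)
  # put demographics on the scale the equations used, then fit on that scale:
  # with zero disturbances the generating values are echoed exactly
  s$age <- (s$age - 39.5) / sqrt((40^2 - 1) / 12)
  s$sex <- (s$sex - 0.5) / 0.5
  # zero residuals: summary.lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(fit_path_model(s, spec, standardize = FALSE))
  rs <- reasoning_I_summary(fit)
  expect_equal(rs$age, get_coefficient(fit, "age", "psych_trait"))
  expect_equal(rs$sex, get_coefficient(fit, "sex", "psych_trait"))
  expect_equal(rs$demographics_cw, get_coefficient(fit, "demog", "cw"))
  expect_equal(rs$age, -0.011, tolerance = 1e-8)
  expect_equal(rs$sex, -0.145, tolerance = 1e-8)
  expect_equal(rs$demographics_cw, -0.938, tolerance = 1e-8)

  arcs0 <- default_path_spec()$arcs
  arcs0$coef <- 0
  spec0 <- path_spec(arcs0, disturbance_sd = c(psych_trait = 1, demog = 1, cw = 1))
  null_fit <- fit_path_model(simulate_subjects(spec0, 2000, seed = 20), spec0)
  rs0 <- reasoning_I_summary(null_fit)
  expect_lt(max(abs(c(rs0$age, rs0$sex, rs0$demographics_cw))), 0.08)
})

test_that("errors and warnings: missing variables, unknown arcs, collinearity", {
  spec <- default_path_spec()
  s <- simulate_subjects(spec, 100, seed = 3)
  expect_error(fit_path_model(s[, -which(names(s) == "em")], spec), "missing")
  fit <- fit_path_model(s, spec)
  expect_error(get_coefficient(fit, "em", "cw"), "no arc")
  s2 <- data.frame(a = rnorm(50))
  s2$b <- s2$a + rnorm(50, 0, 1e-9)
  s2$y <- s2$a + rnorm(50)
  expect_warning(
    fit_path_model(s2, data.frame(from = c("a", "b"), to = "y")),
    "collinear")
})

test_that("path_fit methods: predict, residuals, simulate, round trip", {
  spec <- default_path_spec()
  s <- simulate_subjects(spec, 800, seed = 23)
  fit <- fit_path_model(s, spec)
  fitted_vals <- predict(fit)
  resid_vals <- residuals(fit)
  expect_identical(dim(fitted_vals), dim(resid_vals))
  z_psych <- (s$psych_trait - mean(s$psych_trait)) / sd(s$psych_trait)
  expect_equal(fitted_vals[, "psych_trait"] + resid_vals[, "psych_trait"],
               z_psych, tolerance = 1e-9, ignore_attr = TRUE)
  # generator/estimator round trip through as_path_spec
  spec2 <- as_path_spec(fit)
  s2 <- simulate_subjects(spec2, 5000, seed = 24)
  fit2 <- fit_path_model(s2, spec2)
  expect_equal(coef(fit2), coef(fit), tolerance = 0.08)
  sim <- simulate(fit, nsim = 10, seed = 2)
  expect_identical(nrow(sim), 10L)
  # coefficient CSV / fit JSON writers
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_path_fit(fit, f1, f2)
  tab <- read.csv(f1)
  expect_identical(names(tab), c("source", "target", "estimate", "se", "p_value"))
  rep <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(rep$n, 800)
})
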