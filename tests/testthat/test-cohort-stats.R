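test_that("group summaries use the sample SD and handle singletons", {
  tb <- tibble::tibble(g = c("a", "a", "a", "b"),
                       av3d_deg = c(1, 2, 3, 5))
  s <- cohort_summary(tb, group_by = "g", measures = "av3d_deg")
  a <- s[s$g == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  b <- s[s$g == "b", ]
  expect_true(is.na(b$sd))

  tb2 <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                        av3d_deg = rep(c(4, 5, 6), 2))
  s2 <- cohort_summary(tb2, "g", "av3d_deg")
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$sd[1], s2$sd[2])
})

test_that("independent t-test matches the closed-form pooled formula", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  tt <- t_test_independent(a, b, equal_variance = TRUE)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(tt$t, t_manual, tolerance = 1e-12)
  expect_equal(tt$df, 6)
  expect_equal(tt$p_value, 2 * pt(t_manual, 6), tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  t0 <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)

  # swapping samples negates t, preserves p
  tw <- t_test_independent(b, a, equal_variance = TRUE)
  expect_equal(tw$t, -tt$t, tolerance = 1e-12)
  expect_equal(tw$p_value, tt$p_value, tolerance = 1e-12)

  expect_error(t_test_independent(1, c(1, 2)), "n >= 2")
  expect_s3_class(tidy(tt), "tbl_df")
})

test_that("OLS matches the normal-equations oracle and flags rank deficiency", {
  # exact line
  df <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
  f <- suppressWarnings(fit_ols(df, "y", "x")) # exact fit by construction
  co <- tidy(f)
  expect_equal(co$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(glance(f)$r.squared, 1, tolerance = 1e-12)

  # seeded data vs brute-force normal equations
  set.seed(77)
  n <- 60
  d2 <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d2$y <- 1.5 - 2 * d2$x1 + 0.7 * d2$x2 + rnorm(n)
  f2 <- fit_ols(d2, "y", c("x1", "x2"), interactions = list(c("x1", "x2")))
  X <- cbind(1, d2$x1, d2$x2, d2$x1 * d2$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(tidy(f2)$estimate, drop(beta), tolerance = 1e-9,
               ignore_attr = TRUE)
  # residuals orthogonal to every design column
  resid <- d2$y - drop(X %*% beta)
  expect_lt(max(abs(t(X) %*% (d2$y - drop(X %*% tidy(f2)$estimate)))), 1e-8 * n)

  d2$x1_copy <- d2$x1
  expect_error(fit_ols(d2, "y", c("x1", "x1_copy")), "collinear.*x1_copy")
})

test_that("the interaction model never has lower R^2 than the nested model", {
  set.seed(5)
  for (rep in 1:5) {
    co <- make_cohort(n_subjects = 40, rng_seed = rep)
    co <- co[co$side == "right", ]
    co$delta_deg <- co$av3d_deg - co$av2d_deg
    main <- fit_ols(co, "delta_deg", c("lambda_deg", "rho_deg"))
    inter <- fit_ols(co, "delta_deg", c("lambda_deg", "rho_deg"),
                     interactions = list(c("lambda_deg", "rho_deg")))
    expect_gte(glance(inter)$r.squared, glance(main)$r.squared - 1e-12)
  }
})

test_that("bias analysis recovers a zero-noise linear pose bias exactly", {
  co <- make_cohort(n_subjects = 30,
                    bias_model = list(b0 = -36.643, b_lambda = 0.474,
                                      b_rho = -0.318, b_interaction = 0,
                                      noise_sd = 0),
                    rng_seed = 4)
  ba <- run_bias_analysis(co)
  for (sd_ in c("left", "right")) {
    est <- ba$regressions
    m <- est[est$side == sd_ & est$model == "multiple", ]
    expect_equal(m$estimate[m$term == "(Intercept)"], -36.643, tolerance = 1e-8)
    expect_equal(m$estimate[m$term == "lambda_deg"], 0.474, tolerance = 1e-9)
    expect_equal(m$estimate[m$term == "rho_deg"], -0.318, tolerance = 1e-9)
    expect_equal(ba$glances$r.squared[ba$glances$side == sd_ &
                                        ba$glances$model == "multiple"], 1,
                 tolerance = 1e-12)
  }
  # paired comparison is consistent with the generated bias direction
  expect_true(all(ba$paired$mean_delta < 0)) # 2D overestimates
})

test_that("bias analysis refuses degenerate inputs", {
  co <- make_cohort(n_subjects = 30, rng_seed = 9)
  expect_error(run_bias_analysis(co[1:8, ]), "fewer than 10")
  co$lambda_deg <- 50
  expect_error(run_bias_analysis(co), "collinear.*lambda")
})
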