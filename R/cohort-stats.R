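#' @title Cohort statistics
#' @name cohort_stats
#' @description Group summaries (mean and SD), independent-samples t-tests
#'   (Welch by default) and single / multiple / interaction ordinary
#'   least-squares regression of the 3D-2D anteversion discrepancy
#'   (delta = av3d - av2d) on the pelvic pose angles lambda and rho,
#'   per side -- the analysis layer applied to a measured or simulated
#'   cohort table.
NULL

#' Per-group mean and SD summaries
#'
#' @param table a data frame (e.g. an `av_cohort`).
#' @param group_by character vector of grouping columns.
#' @param measures character vector of numeric columns to summarise
#'   (default: the AV and pose columns present).
#' @return tibble with one row per group x measure: `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator; `NA` for singleton groups). Deterministic
#'   group ordering (sorted).
#' @export
cohort_summary <- function(table, group_by = "sex", measures = NULL) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (is.null(measures))
    measures <- intersect(c("av3d_deg", "av2d_deg", "lambda_deg", "rho_deg", "delta_deg"),
                          names(table))
  if (length(measures) == 0) stop("no measure columns found")
  tb <- tibble::as_tibble(table)
  if ("av3d_deg" %in% names(tb) && "av2d_deg" %in% names(tb))
    tb$delta_deg <- tb$av3d_deg - tb$av2d_deg # always recomputed, never stored
  measures <- intersect(unique(c(measures, "delta_deg")), names(tb))
  tb |>
    tidyr::pivot_longer(dplyr::all_of(measures),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "measure")))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_by, "measure"))))
}

#' Independent-samples t-test
#'
#' Welch's unequal-variance t-test by default; the pooled-variance Student
#' test with `equal_variance = TRUE`.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param equal_variance pool the variances (default `FALSE`).
#' @return An `av_ttest` (supports [generics::tidy()] / [generics::glance()]):
#'   `mean_diff`, `t`, `df`, `p_value`, per-group `mean`/`sd`/`n`.
#' @export
t_test_independent <- function(a, b, equal_variance = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = equal_variance)
  structure(list(mean_diff = mean(a) - mean(b),
                 t = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 group_a = list(n = length(a), mean = mean(a), sd = stats::sd(a)),
                 group_b = list(n = length(b), mean = mean(b), sd = stats::sd(b)),
                 equal_variance = equal_variance),
            class = "av_ttest")
}

#' @export
print.av_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: mean diff %.3f, t = %.3f, df = %.1f, p = %.4g\n",
              if (x$equal_variance) "Student" else "Welch",
              x$mean_diff, x$t, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.av_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$t, df = x$df,
                 p.value = x$p_value,
                 mean_a = x$group_a$mean, sd_a = x$group_a$sd, n_a = x$group_a$n,
                 mean_b = x$group_b$mean, sd_b = x$group_b$sd, n_b = x$group_b$n)
}

#' Ordinary least-squares regression with named predictors
#'
#' Thin, validated wrapper over a least-squares fit: checks the design for
#' full rank (naming the collinear columns on failure), forms interaction
#' columns as elementwise products, and packages coefficients, standard
#' errors, t statistics, two-sided p-values and R-squared.
#'
#' @param data data frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param interactions optional list of character pairs, each adding a
#'   product column (e.g. `list(c("lambda_deg", "rho_deg"))`).
#' @return An `av_ols` (supports `tidy()` / `glance()`).
#' @export
fit_ols <- function(data, response, predictors, interactions = NULL) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  df <- tibble::as_tibble(data[c(response, predictors)])
  terms <- predictors
  for (pr in interactions) {
    stopifnot(length(pr) == 2, all(pr %in% names(data)))
    nm <- paste0(pr[1], ":", pr[2])
    df[[nm]] <- data[[pr[1]]] * data[[pr[2]]]
    terms <- c(terms, nm)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(df[terms]))
  if (nrow(X) <= ncol(X))
    stop("not enough observations for ", ncol(X), " coefficients")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  names(df)[1] <- ".y"
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  structure(list(fit = fit, summary = sm, response = response, terms = terms,
                 n = nrow(df)),
            class = "av_ols")
}

#' @export
print.av_ols <- function(x, ...) {
  cat(sprintf("OLS of %s on %s  (n = %d, R^2 = %.4f)\n", x$response,
              paste(x$terms, collapse = " + "), x$n, x$summary$r.squared))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.av_ols <- function(x, ...) {
  ct <- x$summary$coefficients
  tibble::tibble(term = rownames(ct),
                 estimate = unname(ct[, 1]),
                 std.error = unname(ct[, 2]),
                 statistic = unname(ct[, 3]),
                 p.value = unname(ct[, 4]))
}

#' @export
glance.av_ols <- function(x, ...) {
  sm <- x$summary
  f <- sm$fstatistic
  tibble::tibble(r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma,
                 statistic = if (is.null(f)) NA_real_ else unname(f[1]),
                 p.value = if (is.null(f)) NA_real_ else
                   stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
                 df.residual = x$fit$df.residual,
                 nobs = x$n)
}

#' Confidence intervals for an OLS fit
#' @param object an `av_ols`. @param level confidence level. @param ... unused.
#' @return tibble with `term`, `conf.low`, `conf.high`.
#' @export
confint.av_ols <- function(object, ..., level = 0.95) {
  ci <- stats::confint(object$fit, level = level)
  tibble::tibble(term = rownames(ci), conf.low = ci[, 1], conf.high = ci[, 2])
}

#' Pose-bias analysis of a cohort
#'
#' The full statistics battery applied per side to a cohort table with
#' columns `av3d_deg`, `av2d_deg`, `lambda_deg`, `rho_deg`: single
#' regressions of delta = av3d - av2d on lambda and on rho, the multiple
#' main-effects regression, the interaction model (adding lambda x rho), and
#' the paired comparison of the two methods (mean difference, SD, paired
#' t-test).
#'
#' @param table cohort data frame (e.g. from [make_cohort()]); at least 10
#'   rows per side.
#' @return An `av_bias_analysis`: list with `regressions` (tibble of tidied
#'   coefficients per side x model), `model_fits` (named list of `av_ols`),
#'   `paired` (tibble per side), `glances` (model-level summaries).
#' @export
run_bias_analysis <- function(table) {
  req <- c("side", "av3d_deg", "av2d_deg", "lambda_deg", "rho_deg")
  stopifnot(is.data.frame(table), all(req %in% names(table)))
  tb <- tibble::as_tibble(table)
  tb$delta_deg <- tb$av3d_deg - tb$av2d_deg

  fits <- list()
  reg_rows <- list()
  glance_rows <- list()
  paired_rows <- list()
  for (sd_ in sort(unique(tb$side))) {
    dat <- tb[tb$side == sd_, ]
    if (nrow(dat) < 10)
      stop("refusing bias analysis: fewer than 10 hemipelvises on the ", sd_, " side")
    models <- list(
      single_lambda = list(p = "lambda_deg", i = NULL),
      single_rho = list(p = "rho_deg", i = NULL),
      multiple = list(p = c("lambda_deg", "rho_deg"), i = NULL),
      interaction = list(p = c("lambda_deg", "rho_deg"),
                         i = list(c("lambda_deg", "rho_deg")))
    )
    for (mn in names(models)) {
      f <- fit_ols(dat, "delta_deg", models[[mn]]$p, models[[mn]]$i)
      fits[[paste(sd_, mn, sep = ".")]] <- f
      reg_rows[[length(reg_rows) + 1]] <-
        dplyr::mutate(tidy(f), side = sd_, model = mn, .before = 1)
      glance_rows[[length(glance_rows) + 1]] <-
        dplyr::mutate(glance(f), side = sd_, model = mn, .before = 1)
    }
    pt <- stats::t.test(dat$av3d_deg, dat$av2d_deg, paired = TRUE)
    paired_rows[[length(paired_rows) + 1]] <- tibble::tibble(
      side = sd_,
      n = nrow(dat),
      mean_delta = mean(dat$delta_deg),
      sd_delta = stats::sd(dat$delta_deg),
      t = unname(pt$statistic),
      df = unname(pt$parameter),
      p_value = pt$p.value
    )
  }
  structure(list(regressions = dplyr::bind_rows(reg_rows),
                 glances = dplyr::bind_rows(glance_rows),
                 model_fits = fits,
                 paired = dplyr::bind_rows(paired_rows)),
            class = "av_bias_analysis")
}

#' @export
print.av_bias_analysis <- function(x, ...) {
  cat("Pose-bias analysis (delta = av3d - av2d)\n\nPaired 3D vs 2D:\n")
  print(x$paired)
  cat("\nRegression coefficients:\n")
  print(x$regressions, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
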